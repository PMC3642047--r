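Package: ESTforge
Title: EST Transcriptome Structure: Cluster-and-Merge Reconstruction,
    Alternative Splicing and Antisense Pair Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the structure of a transcriptome sampled by
    Sanger expressed sequence tags (ESTs) against a reference genome: read
    cleaning (quality trimming, vector/adaptor stripping, polyA/T removal,
    contamination screening), a lightweight anchored spliced aligner,
    genome-based cluster-and-merge reconstruction of non-redundant transcripts
    (ESTTranscripts) and loci (ESTGenes), detection and reliability filtering
    of cassette exons, consecutively skipped exon stretches, retained introns
    and alternative splice sites, the cassette-exon fraction under three
    counting policies with its intron-length linear-model expectation,
    classification of sense/cis-natural-antisense transcript pairs, and EST
    count over-representation tests (Monte-Carlo chi-square across culture
    stages, exact binomial between strains). A deterministic simulator
    generates toy genomes, planted isoforms and per-library EST reads with
    machine-readable truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    SummarizedExperiment,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: Transcriptomics, AlternativeSplicing, Alignment, Sequencing
RoxygenNote: 7.3.3
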