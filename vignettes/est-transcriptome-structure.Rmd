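---
title: "EST transcriptome structure: models, filters and design choices"
author: "ESTforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EST transcriptome structure: models, filters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ESTforge)
```

# The analysis in one paragraph

Sanger ESTs are single-pass reads of cDNA clones from non-normalized
libraries, so their counts track transcript abundance and their spliced
alignments to a reference genome reveal exon–intron structure.  ESTforge
cleans the reads, aligns them to the genome with introns, merges
splice-compatible alignments into non-redundant ESTTranscripts and groups
those into ESTGenes, detects and filters alternative-splicing events,
summarizes them as the cassette-exon fraction CE/(CE+RI) used to infer the
dominant splice-site recognition mode, classifies sense/antisense gene
pairs, and tests per-gene EST counts for over-representation across culture
stages and between strains.  A deterministic simulator plants all of these
structures with machine-readable truth, so every stage is testable without
any external data.

# Read cleaning

Cleaning runs in a fixed order: quality trim, vector/adaptor strip, polyA/T
removal, contamination screen, length filter.  Per-stage counts always sum
back to the input count, and rerunning the pipeline on its own output
changes nothing.

**Quality trimming** is specified as the maximum-scoring segment of
$\sum_i (c - p_i)$ over the per-base error probabilities $p_i$, with cutoff
$c = 0.01$ — the modified-Mott rule.  Ties go to the leftmost segment; a
read can trim to nothing.  This re-specifies chromatogram-based trimming in
terms of error probabilities, since base-calling itself is out of scope.

**Vector stripping** masks every occurrence of a vector or adaptor sequence
(either orientation) with at most 20% mismatches and keeps the longest
clean segment.  That single rule covers both situations of interest: a
terminal occurrence disappears with everything outward of it, and an
interior occurrence keeps the longer flank.

**PolyA/T removal** looks for runs of at least 10 A's (or T's) with at most
one interruption; the run *and every base between it and the nearer read
end* are removed — oligo-dT cloning leaves the tail at an end, so whatever
lies beyond it is artefactual.  When several runs qualify on one side the
cut is placed at the innermost one, which is what makes the operation
idempotent.  Both parameters are configurable; the defaults are a choice,
not a published value.

**Contamination screening** computes the best Smith–Waterman local
alignment (match +1, mismatch −2, gap open −5, extend −2) of the read
against each contaminant and discards when identity ≥ 0.90 (matches over
aligned columns, gaps included) *and* the Karlin–Altschul significance
$E = K m n e^{-\lambda S} \le 10^{-10}$, with fixed constants
$\lambda = 1.28$, $K = 0.46$ ($m$ = read length, $n$ = total contaminant
length).  The constants are held fixed so discard decisions are exactly
reproducible.

**Length filter**: reads of length ≥ 50 are kept.  The published account is
ambiguous between "longer than 50" and a reported minimum of 50; the
inclusive reading matches the reported range and is the package's choice.

# Spliced alignment

The aligner is deliberately minimal: exact k-mer anchors (k = 12) grouped
by diagonal, colinear chaining, and junction refinement that slides the
split point over a ±8-base window to minimize created mismatches, with a
bonus when the genomic gap's termini read GT..AG (or CT..AC on the forward
strand; minor sites get a smaller bonus).  Genomic gaps of 20–5000 bases
become introns — the 5000 ceiling leaves headroom over the observed
distribution, where almost all introns are under 2 kb.  Terminal query
overhangs of 6–59 bases that exactly match the genome immediately after a
canonical splice site at intron distance are recovered as an extra block
(with up to 3 bases of chance extension retracted first); shorter overhangs
carry no placeable signal and are clipped, exactly as production spliced
aligners do.  Both the read and its reverse complement are tried and the
better score wins, ties broken by the leftmost genome coordinate.  Identity
counts matching columns over all aligned columns including indel gaps;
coverage is aligned query bases over query length.  The mapping filter
keeps alignments with identity ≥ 0.90 *and* coverage ≥ 0.90, boundary
inclusive.

The aligner only has to be exact in the low-divergence simulated regime;
alignments from a production aligner can be imported from GFF3
(`importAlignments`), with donor/acceptor dinucleotides re-read from the
genome rather than trusted from the file.

# Cluster-and-merge

Two spliced alignments are *splice-compatible* iff (i) at least one intron
is identical in both — donor and acceptor coordinates exactly equal — and
(ii) over the genomic overlap of the two alignments the intron sets are
identical, so no intron of one intersects an exon of the other and no
intron is present on only one side of the shared region.  An alignment
containing a skipped exon the other one retains is therefore never merged.

Merging is greedy agglomeration to a fixpoint in a deterministic order
(descending intron count, then descending span, then EST id): a candidate
joins the first growing transcript whose *merged* structure it is
compatible with — transcript-level rather than pairwise-only, which
prevents conflicts from slipping in through an intermediary — and a final
pairwise pass merges transcripts until no pair can merge.  Because the
order is derived from the data, the result is invariant under permutations
of the input.  Two supporting reads of one transcript need not share a
junction with each other directly (they may chain through an intermediary);
what is guaranteed is that every member shares a junction with the merged
structure and no two members conflict over their shared region.

Unspliced alignments cannot prove splice structure, so they only *join* a
spliced transcript when their span fits inside one exon slot (terminal
exons may extend outward); leftovers merge among themselves into
single-exon transcripts of unknown strand.  This containment rule is a
package decision — the published procedure does not specify unspliced
handling — and can be switched off.

Transcript strand comes from the junction consensus: `+` if all introns
read like a forward-strand site pair, `-` if all read like the reverse,
unknown otherwise.  `inferStrand` defaults to the GT..AG consensus alone;
the merge pipeline passes the full canonical set (GT:AG, GC:AG, AT:AC) so
that a transcript with one minor-site intron is not orphaned from its
locus.  ESTGenes are the connected components of the same-strand overlap
graph; unknown-strand transcripts group only among themselves and never
bridge the two strands.

# Splice events and reliability filters

Within each multi-transcript ESTGene, for every ordered transcript pair:

- **CE/CSE** — a consecutive internal exon block of transcript A is absent
  from B, and B carries a single intron whose donor equals the donor of A's
  upstream flanking intron and whose acceptor equals the acceptor of A's
  downstream flanking intron.  One exon is a CE; a stretch of $k$ exons is
  a CSE with `exon_count` $k$.
- **RI** — an intron of A is fully covered by an exon of B, with both of
  A's flanking exon boundaries strictly inside B's exon.
- **ALT5/ALT3** — two introns share exactly one splice site; the label
  follows the gene strand (donor-side variation is ALT5).  An intron pair
  that is really a skipping event (the longer intron fully covers an exon
  of the other transcript) is excluded here, since it is already reported
  as CE/CSE.

Duplicate calls (same type and coordinates) are reported once per gene, and
events whose support fails the filters are reported with their flags set to
false rather than dropped.

The reliability filters replace the study's manual curation:
`canonical_sites` requires every intron of every supporting alignment to
belong to the canonical set — default GT:AG, GC:AG, AT:AC; the published
methods list "CG:AG", which is presumably a transposition of the standard
minor site GC:AG, so the literal set is available as
`filterSpec(literal_minor_sites = TRUE)` without asserting either reading.
`indel_ok` requires every indel run outside introns to be strictly shorter
than 9 bases.  `flank_matches` requires at least 3 consecutive exactly
matching aligned bases immediately inside each boundary of the candidate
region, in at least one supporting alignment per side — the per-boundary,
any-alignment reading; requiring all alignments to qualify is a stricter
configuration left to the user.

# CE fraction, its expectation, and the VE index

The CE fraction CE/(CE+RI) discriminates exon definition (ED) from intron
definition (ID): a splice-site mutation under ID tends to retain the
intron, under ED to skip the exon.  How a CSE stretch enters the CE count
matters, so three policies are computed side by side:

| policy | CE count | worked example |
|---|---|---|
| `each_exon` | every skipped exon counts | 26/(26+246) → displays 0.10 |
| `stretch_as_one` | a stretch counts once | 16/(16+246) → displays 0.061 |
| `exclude_cse` | stretches dropped | 15/(15+246) → displays 0.057 |

The counts are monotone by construction, so the fractions are too.  Display
rounding mirrors convention (two decimals for the first policy, three for
the others); full precision is always retained.  The cross-species
expectation is the linear model $y = 0.84x$, $x$ being the fraction of
predicted-gene introns longer than 200 bases — computed over annotation
introns, not EST-observed intron calls.  The published deviation statement
("more than 2 standard errors") depends on the original regression
internals, which are not recoverable; the package reports the deviation in
standard-error units only if the user supplies a standard error.  The VE
index divides the number of splice-variant genes by the number of ESTs to
compare alternative-splicing yield across projects of different depth.

# Antisense pairs

SCP candidates are all (+, −) ESTGene pairs with a non-empty span
intersection in which both members carry at least one canonical GT-AG
junction — the junction confirmation guards against wrong strand calls.
Orientation: containment (either span covering the other) is evaluated
first, since fully-covering pairs are reported as their own class;
otherwise a pair is convergent (tail-to-tail) when the overlap holds both
3′ termini, else divergent.  Coding classification needs CDS annotation
(ORF calling is out of scope): pure-3′-UTR iff the overlap misses both CDS
*and* lies 3′ of each CDS in that gene's own orientation; a missing CDS
gives the explicit class `undetermined`.  Gene spans and CDS are union
hulls over member transcripts.

# Over-representation tests

Counts live in a `SummarizedExperiment` (genes × libraries, library
metadata in `colData`).  The stage test is the Monte-Carlo chi-square:
statistic $\sum_l (O_l - E_l)^2/E_l$ with $E_l$ proportional to the library
totals, null replicates drawn multinomially, and
$p = (1 + \#\{T^* \ge T\})/(B+1)$ — R's own simulated-p-value chi-square,
seeded for determinism.  Library totals are the natural exposure; the
published expected values are unstated, and whether the test spanned all
five libraries or the dikaryon stages only is likewise unstated, so the
default uses all libraries with a configurable subset.  The strain test is
the exact two-sided binomial (minimum-likelihood method) of a gene's
monokaryon count against the monokaryon share of all mapped ESTs.  Both
default to the raw 1e−5 flagging threshold used in the study;
Benjamini–Hochberg columns are reported but never drive the flags.  The
default $B = 200{,}000$ with the $+1$ correction makes $p < 10^{-5}$
attainable.  The "over-represented" listing itself is simply row sums ≥ 50.

# The simulator and what passing tests mean

The generator's defaults are the study conditions: five libraries in the
published 1,001 : 6,848 : 21,547 : 11,059 : 6,830 proportions (scaled to
~4,700 reads by default); EST lengths drawn from the published quantiles
(min 50, Q1 593, median 729, Q3 793, max 949); intron lengths log-normal
with median 280 clipped to [24, 2000]; a 2% minor-splice-site fraction
(GC:AG and AT:AC; the literal published listing is available as a preset);
log-normal expression skew (σ = 1) with per-library jitter (σ = 0.2) so a
non-normalized count skew emerges; at most one planted splicing event per
gene (CE 10%, CSE 5% with stretches of 2–4 exons, RI 20%, ALT5/ALT3 5%
each); antisense pairs at 8% of placements in a 60/15/25
convergent/divergent/contained mix with 60% of convergent pairs pure
3′-UTR; four stage-over-represented genes (8-fold in the 18-day dikaryon
library) and two strain-skewed genes (monokaryon weight divided by 8).

Reads model cDNA clones: the insert is anchored at the transcript 3′ end
(oligo-dT priming) and occasionally 5′-truncated (30% of inserts, geometric
decay), and each clone is sequenced from either end with equal probability
— 5′ reads carry vector remnants, 3′ reads reaching the transcript end
carry polyA tails.  Without the 5′ reads, events near the 5′ end of longer
transcripts would be systematically invisible, which no analysis could
repair.  Retained introns are planted only in genes with at least two
introns so the retaining isoform remains junction-confirmed.  Alternative
sites are planted only on canonical introns, keeping the shifted boundary's
dinucleotide unambiguous.  Planted antisense pairs use canonical junctions
throughout (the SCP analysis conditions on them) with the overlap confined
to terminal exons, so opposite-strand splice sites never collide; pair
genes' abundance is floored at 1.5× the mean weight, because an unexpressed
planted pair is vacuous as a test target.

**Fixture sizing.**  One hundred genes with median-280 introns and
600–900-base spliced transcripts need roughly 1.9 kb of genome per locus,
so the default genome is four 65-kb contigs; about 5,000 reads give ~47
reads per gene, enough to saturate most junctions while leaving a realistic
tail of shallowly sampled genes.  Recovery metrics in the tests are
therefore conditioned the way the merge example frames it: an isoform
counts as recoverable when each of its junctions is covered by ≥ 3 reads,
and an event when both isoforms are spanned by ≥ 3 spliced reads — a
structure nobody sequenced cannot be reconstructed by any method.

What passing does *not* show: the simulator has uniform base composition,
no repeats or paralogy (beyond chance k-mer collisions), clean splice-site
dinucleotides, no chimeric clones, and error processes far simpler than
real chromatogram artefacts.  Results on real data depend on the external
aligner's behaviour in repetitive regions and on curation quality in ways
these tests cannot certify.

# Numerical and degenerate-input conventions

Coordinates are 1-based inclusive everywhere (the native convention of
Biostrings/IRanges and of GFF3), with a single representation from
simulator to report.  Zero-intron inputs give `unknown` strands, empty
event lists and flagged-undefined statistics rather than errors; empty SCP
sets summarize to zero counts with `NA` percentages; a zero denominator
flags the CE fraction as undefined.  Intron summaries count identical
contig/coordinate calls once.  Ties are broken deterministically
throughout: leftmost for trimming segments and genome placements,
lexicographic ids in merge ordering.  All randomness flows from a single
integer seed per configuration; identical configurations produce
byte-identical outputs.

# Known limitations

The aligner is not meant for real genomes (no repeat masking, no affine
model across junctions, no splice-site scoring beyond dinucleotides).
Unspliced-EST housing follows a containment rule the study never specified.
The deviation of the observed CE fraction from the linear model cannot be
given in standard errors without the original regression data.  Single-exon
genes and isoforms are invisible to junction-based strand inference, and
retained introns in single-intron genes cannot be junction-confirmed —
both are properties of the method, not of the implementation.
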