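# Shared fixtures, built once per test run and cached.  The "small" fixture
# is a compact noise-free data set used by several module tests; heavier
# fixtures live in the tests that need them.

.fixture_cache <- new.env(parent = emptyenv())

smallFixture <- function() {
  if (!is.null(.fixture_cache$small)) return(.fixture_cache$small)
  cfg <- simConfig(seed = 42, n_genes = 25, n_contigs = 1,
                   contig_length = 60000,
                   libraries = table1Libraries(0.015))
  truth <- simulateGenome(cfg)
  reads <- sampleESTs(truth, cfg)
  gi <- genomeIndex(truthContigs(truth))
  aln <- alignESTs(reads, index = gi)
  .fixture_cache$small <- list(cfg = cfg, truth = truth, reads = reads,
                               index = gi, aln = aln)
  .fixture_cache$small
}

# Reads with planted preprocessing artifacts (tails, vector remnants,
# low-quality ends, contaminants) on a small gene set.
artifactFixture <- function() {
  if (!is.null(.fixture_cache$artifact)) return(.fixture_cache$artifact)
  cfg <- simConfig(seed = 77, n_genes = 12, n_contigs = 1,
                   contig_length = 30000,
                   libraries = table1Libraries(0.008),
                   polya = list(rate = 0.6, meanlog = log(18), sdlog = 0.3,
                                max = 40),
                   vector_rate = 0.3,
                   contamination_fraction = 0.05,
                   quality = list(baseline = 0.001, bad_end_rate = 0.15,
                                  bad_end_len = c(8, 30),
                                  bad_end_err = c(0.1, 0.4)))
  truth <- simulateGenome(cfg)
  reads <- sampleESTs(truth, cfg)
  .fixture_cache$artifact <- list(cfg = cfg, truth = truth, reads = reads)
  .fixture_cache$artifact
}

# Build an alignment structure (for the merge operations) from an intron
# table; used to express merge/compatibility cases compactly.
alnStruct <- function(id, start, end, introns = NULL, contig = "c1") {
  if (is.null(introns))
    introns <- data.frame(start = numeric(0), end = numeric(0),
                          donor = character(0), acceptor = character(0),
                          stringsAsFactors = FALSE)
  # exons are the complement of the introns within [start, end]
  bounds <- c(start, as.vector(t(cbind(introns$start - 1, introns$end + 1))),
              end)
  ex <- matrix(bounds, ncol = 2, byrow = TRUE)
  list(est_id = id, contig = contig, start = start, end = end,
       introns = introns, exons = ex)
}

intronsDF <- function(starts, ends, donor = "GT", acceptor = "AG") {
  data.frame(start = starts, end = ends,
             donor = rep_len(donor, length(starts)),
             acceptor = rep_len(acceptor, length(starts)),
             stringsAsFactors = FALSE)
}

# Wrap transcript structures into the S4 set (mirrors the pipeline path).
toTranscriptSet <- function(trs) ESTforge:::.asTranscriptSet(trs)

# Build an ESTGeneSet from explicit transcript structures.
toGeneSet <- function(trs) {
  groupESTGenes(ESTforge:::.asTranscriptSet(
    trs, strand_sites = list(c("GT", "AG"), c("GC", "AG"), c("AT", "AC"))))
}
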