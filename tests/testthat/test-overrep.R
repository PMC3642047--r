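# Count matrices and the over-representation tests: accounting, histograms
# against the published bins, Monte-Carlo chi-square vs exhaustive
# enumeration, the exact binomial vs direct mass enumeration, and pathway
# subsetting.

test_that("count matrices are built exactly and guard against double assignment", {
  libs <- table1Libraries(1)
  # no assignments: a valid all-zero matrix
  se0 <- buildCounts(data.frame(est_id = character(0),
                                library = character(0),
                                gene_id = character(0)), libs)
  expect_equal(dim(SummarizedExperiment::assay(se0)), c(0L, 5L))
  # 10 ESTs, one gene, one library
  sup <- data.frame(est_id = sprintf("e%02d", 1:10),
                    library = "18D_36123", gene_id = "g1")
  se <- buildCounts(sup, libs)
  expect_equal(SummarizedExperiment::assay(se)["g1", "18D_36123"], 10L)
  expect_equal(sum(SummarizedExperiment::assay(se)), 10L)
  # duplicate EST assignment is an integrity error
  expect_error(buildCounts(rbind(sup, sup[1, ]), libs), "integrity")
  # pipeline conservation on the simulated fixture
  fx <- smallFixture()
  flt <- filterMapped(fx$aln$alignments)
  mg <- mergeAlignments(flt$kept)
  tset <- geneTranscripts(mg$genes)
  tm <- transcriptMeta(tset)
  gene_of_tr <- rep(geneMeta(mg$genes)$gene_id,
                    lengths(geneMembers(mg$genes)))
  names(gene_of_tr) <- unlist(geneMembers(mg$genes))
  sup2 <- do.call(rbind, lapply(seq_len(nrow(tm)), function(i)
    data.frame(est_id = transcriptSupport(tset)[[i]],
               gene_id = gene_of_tr[[tm$transcript_id[i]]])))
  m <- alignmentMeta(flt$kept)
  sup2$library <- m$library[match(sup2$est_id, m$est_id)]
  se2 <- buildCounts(sup2, fx$cfg$libraries)
  expect_equal(sum(SummarizedExperiment::assay(se2)), length(flt$kept))
})

test_that("support histograms bin row sums and match the published table", {
  bins <- geneSupportBins()
  # the published binning: 108 genes at or above 50 supporting ESTs
  expect_equal(sum(bins$n_genes[bins$from >= 50]), 108)
  # reconstruct a matrix with those row sums and recompute the histogram
  rs <- rep(c(0, 1, 50, 100, 150, 200, 350, 579),
            c(6912, 7033, 85, 13, 5, 2, 2, 1))
  m <- cbind(rs)
  colnames(m) <- "L1"; rownames(m) <- sprintf("g%05d", seq_along(rs))
  h <- supportHistogram(m, bin_edges = c(0, 1, 50, 100, 150, 200, 250,
                                         300, 350, 400))
  expect_equal(h$genes_at_or_above, 108)
  expect_equal(h$bins$n_genes[1:2], c(6912L, 7033L))
  # brute-force row-sum binning oracle on a random matrix
  set.seed(601)
  mm <- matrix(rpois(300, 8), 60, 5,
               dimnames = list(sprintf("g%02d", 1:60), paste0("L", 1:5)))
  edges <- c(0, 10, 25, 50)
  h2 <- supportHistogram(mm, bin_edges = edges, min_support = 25)
  rs2 <- rowSums(mm)
  expect_equal(h2$bins$n_genes,
               c(sum(rs2 < 10), sum(rs2 >= 10 & rs2 < 25),
                 sum(rs2 >= 25 & rs2 < 50), sum(rs2 >= 50)))
  expect_equal(h2$genes_at_or_above, sum(rs2 >= 25))
  expect_error(supportHistogram(mm, bin_edges = c(10, 5)), "increasing")
  expect_error(supportHistogram(mm, bin_edges = c(min(rs2) + 1, 100)),
               "partition")
})

test_that("the Monte-Carlo chi-square test matches exact enumeration", {
  totals <- c(300, 500, 200)
  props <- totals / sum(totals)
  # counts exactly proportional to the totals: statistic 0, p = 1
  r <- chisqStageTest(c(30, 50, 20), totals, B = 500, seed = 1)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  # zero rows are skipped with a reason
  expect_true(is.na(chisqStageTest(c(0, 0, 0), totals)$p_value))
  # exhaustive enumeration oracle for row totals <= 8 over 3 libraries
  enum_p <- function(x, props) {
    n <- sum(x)
    E <- n * props
    stat <- sum((x - E)^2 / E)
    tot <- 0
    for (a in 0:n) for (b in 0:(n - a)) {
      y <- c(a, b, n - a - b)
      s <- sum((y - E)^2 / E)
      if (s >= stat - 1e-9) tot <- tot + dmultinom(y, prob = props)
    }
    tot
  }
  set.seed(602)
  for (rep in 1:6) {
    n <- sample(3:8, 1)
    x <- as.vector(rmultinom(1, n, c(0.2, 0.5, 0.3)))
    p_exact <- enum_p(x, props)
    B <- 20000
    r <- chisqStageTest(x, totals, B = B, seed = rep)
    mc_se <- sqrt(p_exact * (1 - p_exact) / B)
    expect_lt(abs(r$p_value - p_exact), 4 * mc_se + 2 / B)
  }
})

test_that("the exact binomial test matches direct mass enumeration", {
  expect_equal(binomStrainTest(1, 2, 0.5)$p_value, 1)
  expect_equal(binomStrainTest(0, 10, 0.5)$p_value, 2 / 1024)
  expect_error(binomStrainTest(11, 10, 0.5), "k must")
  enum_binom <- function(k, n, p) {
    pk <- dbinom(k, n, p)
    sum(dbinom(0:n, n, p)[dbinom(0:n, n, p) <= pk * (1 + 1e-7)])
  }
  set.seed(603)
  for (rep in 1:25) {
    n <- sample(1:20, 1)
    k <- sample(0:n, 1)
    p0 <- runif(1, 0.1, 0.9)
    expect_equal(binomStrainTest(k, n, p0)$p_value, enum_binom(k, n, p0),
                 tolerance = 1e-9)
  }
})

test_that("planted over-represented genes are flagged and nulls are not", {
  # full-depth libraries; the count matrix comes straight from the truth
  # assignments (the tests operate on counts, not alignments)
  cfg <- simConfig(seed = 8)
  truth <- simulateGenome(cfg)
  reads <- sampleESTs(truth, cfg)
  sup <- data.frame(est_id = reads$est_id, library = reads$library,
                    gene_id = reads$gene_id)[!reads$contaminant, ]
  se <- buildCounts(sup, cfg$libraries)
  res <- overrepTests(se, B = 10000, alpha = 1e-3, seed = 9, min_total = 5)
  planted <- plantedOverrep(truth)
  stage <- planted$gene_id[planted$kind == "stage"]
  strain <- planted$gene_id[planted$kind == "strain"]
  # planted genes with the support level the analysis targets are flagged
  rs <- res$row_total[match(stage, res$gene_id)]
  expect_true(all(res$chisq_flagged[match(stage, res$gene_id)][rs >= 50]))
  expect_gte(sum(rs >= 50), 1)
  expect_true(all(res$binom_flagged[match(strain, res$gene_id)]))
  # (null calibration under an exact multinomial null is asserted in the
  # acceptance suite; simulated libraries carry deliberate per-library
  # jitter, so raw nulls here are overdispersed)
  # p-value validity: MC p bounded below by 1/(B+1), binomial p in (0,1]
  expect_true(all(res$chisq_p >= 1 / 10001))
  expect_true(all(res$binom_p > 0 & res$binom_p <= 1))
})

test_that("pathway subsetting reproduces the published 12-of-224 split", {
  tt <- triterpenoidCounts()
  m <- as.matrix(tt[, c("5D_36123", "14D_36123", "18D_36123", "18D_37180",
                        "30D_36123")])
  rownames(m) <- tt$gene_id
  backbone <- tt$gene_id[tt$description != "squalene synthase"]
  pc <- pathwayCounts(m, backbone, c("5D_36123", "14D_36123"))
  expect_equal(unname(pc["subset_sum"]), 12)
  expect_equal(unname(pc["total_sum"]), 224)
  # trivial and error cases
  expect_equal(unname(pathwayCounts(m, character(0), "5D_36123")),
               c(0, 0))
  expect_error(pathwayCounts(m, "nope", "5D_36123"), "unknown gene")
  # brute-force cell addition oracle on random matrices
  set.seed(604)
  mm <- matrix(rpois(40, 5), 8, 5,
               dimnames = list(paste0("g", 1:8), paste0("L", 1:5)))
  gs <- sample(rownames(mm), 4); ls <- sample(colnames(mm), 2)
  pc2 <- pathwayCounts(mm, gs, ls)
  expect_equal(unname(pc2["subset_sum"]), sum(mm[gs, ls]))
  expect_equal(unname(pc2["total_sum"]), sum(mm[gs, ]))
})

test_that("library accounting reproduces the published totals and shares", {
  acc <- libraryAccounting(estLibraryCounts())
  expect_equal(acc$total_filtered, 47285)
  expect_equal(acc$total_mapped, 46153)
  expect_equal(acc$total_spliced, 38395)
  expect_equal(acc$pct_mapped, 98)
  expect_equal(acc$pct_spliced, 83)
})
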