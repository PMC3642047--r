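# EST cleaning: quality trim vs brute-force max-subarray oracle, vector
# stripping, polyA/T flank rule, contamination screen vs full DP oracle, and
# whole-pipeline accounting/idempotence on planted artifacts.

# O(n^2) oracle: best interval score by scanning all intervals.
bruteTrimScore <- function(q, cutoff) {
  s <- cutoff - q
  best <- 0
  for (i in seq_along(s)) for (j in i:length(s))
    best <- max(best, sum(s[i:j]))
  best
}

test_that("quality trim is the maximum-scoring segment", {
  expect_equal(qualityTrim(qualities = rep(0.001, 30), cutoff = 0.01),
               c(1L, 30L))
  expect_equal(qualityTrim(qualities = rep(0.5, 30), cutoff = 0.01),
               c(0L, -1L))
  expect_error(qualityTrim("ACGT", rep(0.01, 3)), "lengths differ")
  set.seed(101)
  for (rep in 1:40) {
    n <- sample(5:60, 1)
    q <- runif(n, 0, 0.08)
    iv <- qualityTrim(qualities = q, cutoff = 0.01)
    got <- if (iv[2] >= iv[1]) sum(0.01 - q[iv[1]:iv[2]]) else 0
    expect_equal(got, bruteTrimScore(q, 0.01), tolerance = 1e-10)
  }
})

test_that("vector stripping removes terminal occurrences and keeps the longest clean segment", {
  vec <- "ACGTACGTGGCCAAGGTTCC"
  spec <- trimSpec(vector_seqs = vec)
  expect_equal(stripVector("TTTTGGGGCCCCAAAA", spec)$sequence,
               "TTTTGGGGCCCCAAAA")
  read <- paste0(vec, "TTGACCTGATTGACCGTAGGAC")
  expect_equal(stripVector(read, spec)$sequence, "TTGACCTGATTGACCGTAGGAC")
  # interior hit: the longer flank is retained
  read2 <- paste0("AAAACCCC", vec, strrep("TGCA", 8))
  expect_equal(stripVector(read2, spec)$sequence, strrep("TGCA", 8))
  # a 15% mismatched occurrence is still removed (20% allowance)
  vm <- vec
  substr(vm, 3, 3) <- "T"; substr(vm, 9, 9) <- "A"; substr(vm, 15, 15) <- "C"
  expect_equal(stripVector(paste0(vm, "GACCTGATCAGGATCCTGAC"), spec)$sequence,
               "GACCTGATCAGGATCCTGAC")
})

test_that("planted 5' vector remnants are removed at the planted boundary", {
  fx <- artifactFixture()
  reads <- fx$reads
  spec <- trimSpec(vector_seqs = fx$cfg$vector_seq)
  withv <- which(reads$vec5_len > 0 & !reads$contaminant)
  hits <- 0
  for (i in withv) {
    sv <- stripVector(reads$sequence[i], spec)
    if (sv$kept[1] == reads$vec5_len[i] + 1) hits <- hits + 1
  }
  expect_gte(hits / length(withv), 0.95)
})

test_that("polyA/T runs are trimmed together with the proximal flank", {
  spec <- trimSpec()
  expect_equal(trimPolyAT("ACGTTGCACGTTGCA", spec)$sequence,
               "ACGTTGCACGTTGCA")
  expect_equal(trimPolyAT(paste0("ACGTACGT", strrep("A", 20), "GG"),
                          spec)$sequence, "ACGTACGT")
  # T-run at the 5' end, with one interruption tolerated
  expect_equal(trimPolyAT(paste0("GG", strrep("T", 6), "C", strrep("T", 6),
                                 "ACGTCCGTAGGT"), spec)$sequence,
               "ACGTCCGTAGGT")
  # planted tails: removal boundary equals the planted boundary.  Only
  # tails long enough to qualify (>= min_run + 2) and untouched by a
  # low-quality 3' segment are informative; the boundary may shift by the
  # few genuine A's the transcript happens to end with.
  fx <- artifactFixture()
  reads <- fx$reads
  witht <- which(reads$tail_len >= 12 & reads$vec5_len == 0 &
                   !reads$contaminant)
  ok <- 0; n <- 0
  for (i in witht) {
    q <- reads$quality[[i]]
    tail_q <- q[(reads$insert_end[i] + 1):length(q)]
    if (any(tail_q > 0.01)) next    # tail corrupted by a bad-quality end
    n <- n + 1
    pt <- trimPolyAT(reads$sequence[i], spec)
    if (abs(pt$kept[2] - reads$insert_end[i]) <= 3) ok <- ok + 1
  }
  expect_gte(ok / n, 0.95)
})

# Plain Smith-Waterman DP, linear gap penalty per run via affine recursion.
bruteLocalAlign <- function(a, b, match = 1, mismatch = -2, gap_open = -5,
                            gap_ext = -2) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1, m + 1); E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    E[i, j] <- max(E[i, j - 1] + gap_ext, H[i, j - 1] + gap_open)
    F[i, j] <- max(F[i - 1, j] + gap_ext, H[i - 1, j] + gap_open)
    sub <- H[i - 1, j - 1] + if (A[i - 1] == B[j - 1]) match else mismatch
    H[i, j] <- max(0, sub, E[i, j], F[i, j])
    best <- max(best, H[i, j])
  }
  best
}

test_that("contamination screen matches a full local-alignment DP oracle", {
  set.seed(202)
  contam <- paste(sample(c("A", "C", "G", "T"), 900, TRUE), collapse = "")
  spec <- screenSpec(contaminant_seqs = c(ec = contam))
  # read equal to a contaminant substring of length >= 60: discard, id 1.0
  r1 <- substr(contam, 101, 220)
  s1 <- screenContamination(r1, spec)
  expect_false(s1$keep)
  expect_equal(s1$identity, 1.0)
  # unrelated random 200-mer: keep
  r2 <- paste(sample(c("A", "C", "G", "T"), 200, TRUE), collapse = "")
  expect_true(screenContamination(r2, spec)$keep)
  # empty contaminant set: always keep
  expect_true(screenContamination(r1, screenSpec())$keep)
  # best-hit score agrees with the DP oracle on small instances
  for (rep in 1:6) {
    n <- sample(60:150, 1)
    read <- if (rep %% 2 == 0) {
      # mutated contaminant fragment
      x <- strsplit(substr(contam, 300, 300 + n - 1), "")[[1]]
      mut <- sample(n, ceiling(n * 0.08))
      for (k in mut) x[k] <- sample(setdiff(c("A", "C", "G", "T"), x[k]), 1)
      paste(x, collapse = "")
    } else paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
    sub <- substr(contam, 1, 300)
    spec2 <- screenSpec(contaminant_seqs = c(ec = sub))
    got <- Biostrings::score(Biostrings::pairwiseAlignment(
      read, sub, type = "local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(1, -2),
      gapOpening = 5, gapExtension = 2))
    expect_equal(got, bruteLocalAlign(read, sub), tolerance = 1e-9)
  }
})

test_that("the full pipeline conserves counts and is idempotent", {
  fx <- artifactFixture()
  reads <- fx$reads
  trim <- trimSpec(vector_seqs = fx$cfg$vector_seq)
  screen <- screenSpec(contaminant_seqs = fx$cfg$contaminant_seqs)
  res <- runPreprocess(reads, trim, screen)
  rep <- res$report
  # conservation: input = survivors + all discards
  expect_equal(rep$input[1],
               rep$surviving[4] + sum(rep$discarded))
  # planted contaminants are discarded by the contamination stage
  n_cont <- sum(reads$contaminant)
  expect_gte(sum(res$discard_reason == "contamination", na.rm = TRUE),
             ceiling(0.9 * n_cont))
  # survivors keep an interval that reproduces the sequence
  expect_true(all(nchar(res$clean$sequence) >= 50))
  # idempotence: a second run changes nothing
  res2 <- runPreprocess(res$clean, trim, screen)
  expect_equal(res2$clean$sequence, res$clean$sequence)
  expect_equal(nrow(res2$clean), nrow(res$clean))
  expect_equal(sum(res2$report$discarded), 0)
  # base-level artifact recall and precision over surviving reads: artifact
  # bases (vector remnant, polyA tail) should be removed, and removed bases
  # should be artifact or low-quality
  art_total <- 0; art_removed <- 0; removed_total <- 0; false_removed <- 0
  for (i in which(!reads$contaminant)) {
    k <- match(reads$est_id[i], res$clean$est_id)
    if (is.na(k)) next
    n <- nchar(reads$sequence[i])
    kept <- rep(FALSE, n)
    kept[res$clean$kept_start[k]:res$clean$kept_end[k]] <- TRUE
    is_art <- rep(FALSE, n)
    if (reads$vec5_len[i] > 0) is_art[1:reads$vec5_len[i]] <- TRUE
    if (reads$insert_end[i] < n) is_art[(reads$insert_end[i] + 1):n] <- TRUE
    lowq <- reads$quality[[i]] > 0.01
    art_total <- art_total + sum(is_art)
    art_removed <- art_removed + sum(is_art & !kept)
    removed_total <- removed_total + sum(!kept)
    false_removed <- false_removed + sum(!kept & !is_art & !lowq)
  }
  expect_gte(art_removed / art_total, 0.95)          # recall
  expect_gte(1 - false_removed / removed_total, 0.95)  # precision
})

test_that("noise-free artifact-free reads pass every stage untouched", {
  fx <- smallFixture()
  reads <- fx$reads[1:100, ]
  res <- runPreprocess(reads, trimSpec(vector_seqs = fx$cfg$vector_seq),
                       screenSpec(contaminant_seqs =
                                    fx$cfg$contaminant_seqs))
  expect_equal(nrow(res$clean), 100L)
  expect_equal(sum(res$report$discarded), 0)
  expect_equal(res$clean$sequence, reads$sequence)
})
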