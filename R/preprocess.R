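# EST cleaning: quality trimming (maximum-scoring segment), vector/adaptor
# stripping, polyA/T removal with the proximal flank, contamination screening
# by local alignment, and the length filter — applied in that order, with a
# per-stage accounting report.

#' Trimming specification
#'
#' @param quality_error_cutoff per-base error-probability cutoff for the
#'   maximum-scoring-segment quality trim (default 0.01).
#' @param vector_seqs character vector of vector/adaptor sequences.
#' @param max_vector_mismatch maximum mismatch fraction for a vector
#'   occurrence (default 0.20).
#' @param polyat_min_run minimum number of A (or T) bases in a qualifying
#'   homopolymer run (default 10).
#' @param polyat_max_mismatch maximum interruptions tolerated inside a run
#'   (default 1).
#' @param min_length minimum length of a kept EST (default 50, inclusive).
#' @return a validated \code{TrimSpec} list.
#' @export
trimSpec <- function(quality_error_cutoff = 0.01, vector_seqs = character(0),
                     max_vector_mismatch = 0.20, polyat_min_run = 10L,
                     polyat_max_mismatch = 1L, min_length = 50L) {
  stopifnot(quality_error_cutoff > 0, quality_error_cutoff < 1,
            max_vector_mismatch >= 0, max_vector_mismatch < 1,
            min_length >= 1)
  structure(list(quality_error_cutoff = quality_error_cutoff,
                 vector_seqs = vector_seqs,
                 max_vector_mismatch = max_vector_mismatch,
                 polyat_min_run = as.integer(polyat_min_run),
                 polyat_max_mismatch = as.integer(polyat_max_mismatch),
                 min_length = as.integer(min_length)),
            class = "TrimSpec")
}

#' Contamination screening specification
#'
#' Reads are compared to the contaminant set by Smith-Waterman local
#' alignment; a read is discarded when the best hit reaches both the identity
#' and the significance threshold.  Significance uses the Karlin-Altschul
#' form \eqn{E = K m n e^{-\lambda S}} with fixed, documented constants so
#' discard decisions are reproducible.
#'
#' @param contaminant_seqs named character vector of contaminant sequences.
#' @param min_identity identity threshold over aligned columns, gaps included
#'   (default 0.90).
#' @param max_evalue significance threshold (default 1e-10).
#' @param match,mismatch,gap_open,gap_ext local-alignment scoring.
#' @param lambda,K constants of the significance approximation.
#' @return a validated \code{ScreenSpec} list.
#' @export
screenSpec <- function(contaminant_seqs = character(0), min_identity = 0.90,
                       max_evalue = 1e-10, match = 1, mismatch = -2,
                       gap_open = -5, gap_ext = -2, lambda = 1.28, K = 0.46) {
  stopifnot(min_identity > 0, min_identity <= 1, max_evalue > 0)
  structure(list(contaminant_seqs = contaminant_seqs,
                 min_identity = min_identity, max_evalue = max_evalue,
                 match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_ext = gap_ext, lambda = lambda, K = K),
            class = "ScreenSpec")
}

#' Quality trim by maximum-scoring segment
#'
#' Returns the contiguous interval maximizing \eqn{\sum (cutoff - p_{err})}
#' over its bases (modified-Mott trimming).  Ties are broken by the leftmost
#' interval; if no base scores positive the interval is empty.
#'
#' @param sequence the read (only its length is used; may be \code{NULL}).
#' @param qualities numeric vector of per-base error probabilities.
#' @param cutoff error-probability cutoff (default 0.01).
#' @return integer vector \code{c(start, end)}, 1-based inclusive, or
#'   \code{c(0L, -1L)} for an empty interval.
#' @examples
#' qualityTrim(qualities = c(.5, .001, .001, .001, .5), cutoff = 0.01)
#' @export
qualityTrim <- function(sequence = NULL, qualities, cutoff = 0.01) {
  if (!is.null(sequence) && nchar(sequence) != length(qualities))
    stop("sequence and qualities lengths differ")
  s <- cutoff - qualities
  best <- 0; bs <- 0L; be <- -1L
  cur <- 0; cs <- 1L
  for (i in seq_along(s)) {
    if (cur <= 0) { cur <- s[i]; cs <- i } else cur <- cur + s[i]
    if (cur > best + 1e-12) { best <- cur; bs <- cs; be <- i }
  }
  c(as.integer(bs), as.integer(be))
}

# All occurrences of `pattern` in `subject` with mismatch fraction below the
# spec (full-length, ungapped), as a 2-column matrix of start/end.
.vectorHits <- function(subject, pattern, max_mm_frac) {
  maxmm <- floor(max_mm_frac * nchar(pattern))
  if (nchar(subject) < nchar(pattern)) return(matrix(numeric(0), ncol = 2))
  m <- Biostrings::matchPattern(pattern, Biostrings::DNAString(subject),
                                max.mismatch = maxmm, with.indels = FALSE)
  if (length(m) == 0) return(matrix(numeric(0), ncol = 2))
  cbind(BiocGenerics::start(m), BiocGenerics::end(m))
}

#' Strip vector and adaptor occurrences
#'
#' Occurrences of any vector/adaptor sequence (either orientation) with a
#' per-occurrence mismatch fraction at or below the threshold are masked and
#' the longest clean segment is kept: a terminal occurrence is removed with
#' everything outward of it, and for an interior occurrence the longer flank
#' is retained.
#'
#' @param sequence the read.
#' @param spec a \code{\link{trimSpec}} carrying \code{vector_seqs} and
#'   \code{max_vector_mismatch}.
#' @return list with \code{sequence} (kept substring), \code{kept}
#'   (\code{c(start, end)} in input coordinates) and \code{hits} (matrix of
#'   masked intervals).
#' @export
stripVector <- function(sequence, spec) {
  n <- nchar(sequence)
  hits <- matrix(numeric(0), ncol = 2)
  for (v in spec$vector_seqs) {
    hits <- rbind(hits, .vectorHits(sequence, v, spec$max_vector_mismatch))
    hits <- rbind(hits, .vectorHits(sequence, .revcomp(v),
                                    spec$max_vector_mismatch))
  }
  if (nrow(hits) == 0)
    return(list(sequence = sequence, kept = c(1L, n), hits = hits))
  hits <- .unionIntervals(hits)
  # clean segments between masked intervals; keep the longest (leftmost tie)
  bounds <- c(0, as.vector(t(hits)), n + 1)
  segs <- matrix(bounds, ncol = 2, byrow = TRUE)  # (end_prev, start_next)
  segs <- cbind(segs[, 1] + 1, segs[, 2] - 1)
  segs <- segs[segs[, 2] >= segs[, 1], , drop = FALSE]
  if (nrow(segs) == 0)
    return(list(sequence = "", kept = c(0L, -1L), hits = hits))
  w <- segs[, 2] - segs[, 1] + 1
  k <- which.max(w)
  kept <- c(as.integer(segs[k, 1]), as.integer(segs[k, 2]))
  list(sequence = substr(sequence, kept[1], kept[2]), kept = kept,
       hits = hits)
}

# Maximal runs of base `b` containing at least min_run copies of `b` with at
# most max_mm interruptions, as a 2-column matrix (start, end of the run's
# `b` extent).
.polyRuns <- function(ch, b, min_run, max_mm) {
  idx <- which(ch == b)
  if (length(idx) < min_run) return(matrix(numeric(0), ncol = 2))
  runs <- NULL
  i <- 1
  n <- length(idx)
  while (i <= n) {
    j <- i
    mm <- 0
    # extend while gaps between consecutive b's stay within the budget
    while (j < n && mm + (idx[j + 1] - idx[j] - 1) <= max_mm) {
      mm <- mm + (idx[j + 1] - idx[j] - 1)
      j <- j + 1
    }
    if (j - i + 1 >= min_run) runs <- rbind(runs, c(idx[i], idx[j]))
    i <- j + 1
  }
  if (is.null(runs)) matrix(numeric(0), ncol = 2) else runs
}

#' Trim polyA/T tracks with their proximal flank
#'
#' If a run of at least \code{polyat_min_run} A's (or T's) with at most
#' \code{polyat_max_mismatch} interruptions occurs, the run and every base
#' between it and the nearer read end are removed.  At most one removal is
#' applied per end; when several runs qualify on a side the cut is placed at
#' the innermost one, so the result carries no further qualifying runs.
#'
#' @param sequence the read.
#' @param spec a \code{\link{trimSpec}}.
#' @return list with \code{sequence} and \code{kept} interval in input
#'   coordinates.
#' @examples
#' trimPolyAT(paste0("ACGTACGT", strrep("A", 20), "GG"), trimSpec())$sequence
#' @export
trimPolyAT <- function(sequence, spec) {
  n <- nchar(sequence)
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  runs <- rbind(.polyRuns(ch, "A", spec$polyat_min_run,
                          spec$polyat_max_mismatch),
                .polyRuns(ch, "T", spec$polyat_min_run,
                          spec$polyat_max_mismatch))
  lo <- 1L; hi <- n
  if (nrow(runs)) {
    mid <- (runs[, 1] + runs[, 2]) / 2
    left <- runs[mid <= (n + 1) / 2, , drop = FALSE]
    right <- runs[mid > (n + 1) / 2, , drop = FALSE]
    if (nrow(left)) lo <- as.integer(max(lo, max(left[, 2]) + 1))
    if (nrow(right)) hi <- as.integer(min(hi, min(right[, 1]) - 1))
  }
  if (lo > hi) return(list(sequence = "", kept = c(0L, -1L)))
  list(sequence = substr(sequence, lo, hi), kept = c(lo, hi))
}

#' Screen one EST against a contaminant set
#'
#' The best local alignment of the read against each contaminant is computed;
#' the read is discarded when the best hit has identity at or above
#' \code{min_identity} (matches over aligned columns, gaps included) and a
#' significance at or below \code{max_evalue} under the Karlin-Altschul
#' approximation \eqn{E = K m n e^{-\lambda S}}, with \eqn{m} the read
#' length and \eqn{n} the total contaminant length.
#'
#' @param sequence the read.
#' @param spec a \code{\link{screenSpec}}.
#' @return list with \code{keep} (logical), \code{identity}, \code{evalue}
#'   and \code{hit} (contaminant name of the best hit or \code{NA}).
#' @export
screenContamination <- function(sequence, spec) {
  if (length(spec$contaminant_seqs) == 0 || nchar(sequence) == 0)
    return(list(keep = TRUE, identity = NA_real_, evalue = NA_real_,
                hit = NA_character_))
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = spec$match, mismatch = spec$mismatch, baseOnly = FALSE)
  best <- list(score = -Inf, identity = 0, name = NA_character_)
  for (nm in names(spec$contaminant_seqs)) {
    aln <- Biostrings::pairwiseAlignment(
      sequence, spec$contaminant_seqs[[nm]], type = "local",
      substitutionMatrix = mat, gapOpening = -spec$gap_open,
      gapExtension = -spec$gap_ext)
    sc <- Biostrings::score(aln)
    if (sc > best$score) {
      ncol_aln <- nchar(as.character(Biostrings::alignedPattern(aln)))
      ident <- Biostrings::nmatch(aln) / ncol_aln
      best <- list(score = sc, identity = ident, name = nm)
    }
  }
  m <- nchar(sequence)
  n <- sum(nchar(spec$contaminant_seqs))
  evalue <- spec$K * m * n * exp(-spec$lambda * best$score)
  discard <- best$identity >= spec$min_identity && evalue <= spec$max_evalue
  list(keep = !discard, identity = best$identity, evalue = evalue,
       hit = best$name)
}

#' Run the full EST cleaning pipeline
#'
#' Applies, in order: quality trimming, vector/adaptor stripping, polyA/T
#' removal, contamination screening, and the length filter (keep length >=
#' \code{min_length}).  Per-stage input/surviving counts are reported and
#' conserve the input total exactly.
#'
#' @param reads read table with columns \code{est_id}, \code{sequence} and a
#'   list column \code{quality} (as from \code{\link{sampleESTs}} or
#'   \code{\link{readSimulatedReads}}).  A missing \code{quality} column
#'   skips the quality stage.
#' @param trim a \code{\link{trimSpec}}.
#' @param screen a \code{\link{screenSpec}}.
#' @return list with \code{clean} (data.frame: \code{est_id},
#'   \code{sequence}, \code{kept_start}, \code{kept_end}, list columns
#'   \code{quality} and \code{stage_log}) and \code{report} (data.frame:
#'   \code{stage}, \code{input}, \code{surviving}, \code{discarded}).
#' @export
runPreprocess <- function(reads, trim = trimSpec(), screen = screenSpec()) {
  n0 <- nrow(reads)
  have_q <- "quality" %in% names(reads)
  seqs <- reads$sequence
  quals <- if (have_q) reads$quality else
    lapply(nchar(seqs), function(n) rep(0.001, n))
  kept_s <- rep(1L, n0)
  kept_e <- nchar(seqs)
  logs <- replicate(n0, character(0), simplify = FALSE)
  discard_reason <- rep(NA_character_, n0)

  # stage 1: quality
  for (i in seq_len(n0)) {
    iv <- qualityTrim(seqs[i], quals[[i]], trim$quality_error_cutoff)
    if (iv[2] < iv[1]) {
      seqs[i] <- ""; quals[[i]] <- numeric(0)
      kept_s[i] <- 0L; kept_e[i] <- -1L
      logs[[i]] <- c(logs[[i]], "quality:empty")
    } else {
      if (iv[1] > 1 || iv[2] < nchar(seqs[i]))
        logs[[i]] <- c(logs[[i]], sprintf("quality:%d-%d", iv[1], iv[2]))
      quals[[i]] <- quals[[i]][iv[1]:iv[2]]
      kept_s[i] <- kept_s[i] + iv[1] - 1L
      kept_e[i] <- kept_s[i] + (iv[2] - iv[1])
      seqs[i] <- substr(seqs[i], iv[1], iv[2])
    }
  }
  # stage 2: vector strip
  if (length(trim$vector_seqs)) {
    for (i in seq_len(n0)) {
      if (nchar(seqs[i]) == 0) next
      sv <- stripVector(seqs[i], trim)
      if (nrow(sv$hits)) {
        logs[[i]] <- c(logs[[i]], sprintf("vector:%d hit(s)", nrow(sv$hits)))
        if (sv$kept[2] < sv$kept[1]) {
          seqs[i] <- ""; quals[[i]] <- numeric(0)
        } else {
          quals[[i]] <- quals[[i]][sv$kept[1]:sv$kept[2]]
          kept_s[i] <- kept_s[i] + sv$kept[1] - 1L
          kept_e[i] <- kept_s[i] + (sv$kept[2] - sv$kept[1])
          seqs[i] <- sv$sequence
        }
      }
    }
  }
  # stage 3: polyA/T
  for (i in seq_len(n0)) {
    if (nchar(seqs[i]) == 0) next
    pt <- trimPolyAT(seqs[i], trim)
    if (pt$kept[1] != 1 || pt$kept[2] != nchar(seqs[i])) {
      logs[[i]] <- c(logs[[i]], "polyat:trimmed")
      if (pt$kept[2] < pt$kept[1]) {
        seqs[i] <- ""; quals[[i]] <- numeric(0)
      } else {
        quals[[i]] <- quals[[i]][pt$kept[1]:pt$kept[2]]
        kept_s[i] <- kept_s[i] + pt$kept[1] - 1L
        kept_e[i] <- kept_s[i] + (pt$kept[2] - pt$kept[1])
        seqs[i] <- pt$sequence
      }
    }
  }
  # stage 4: contamination
  for (i in seq_len(n0)) {
    if (nchar(seqs[i]) == 0) next
    sc <- screenContamination(seqs[i], screen)
    if (!sc$keep) {
      discard_reason[i] <- "contamination"
      logs[[i]] <- c(logs[[i]], sprintf("contamination:%s id=%.3f", sc$hit,
                                        sc$identity))
    }
  }
  # stage 5: length
  short <- is.na(discard_reason) & nchar(seqs) < trim$min_length
  discard_reason[short] <- "length"

  keep <- is.na(discard_reason)
  report <- data.frame(
    stage = c("input", "contamination", "length", "clean"),
    input = c(n0, n0, n0 - sum(discard_reason == "contamination",
                               na.rm = TRUE), NA),
    surviving = c(n0,
                  n0 - sum(discard_reason == "contamination", na.rm = TRUE),
                  sum(keep), sum(keep)),
    discarded = c(0,
                  sum(discard_reason == "contamination", na.rm = TRUE),
                  sum(discard_reason == "length", na.rm = TRUE), 0),
    stringsAsFactors = FALSE)
  report$input[4] <- sum(keep)

  clean <- data.frame(est_id = reads$est_id[keep], sequence = seqs[keep],
                      kept_start = kept_s[keep], kept_end = kept_e[keep],
                      stringsAsFactors = FALSE)
  if ("library" %in% names(reads)) clean$library <- reads$library[keep]
  clean$quality <- quals[keep]
  clean$stage_log <- logs[keep]
  list(clean = clean, report = report,
       discard_reason = discard_reason)
}
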