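# A lightweight anchored spliced aligner for ESTs against a desk-scale
# genome: exact k-mer anchors grouped by diagonal, colinear chaining,
# junction placement preferring canonical splice dinucleotides, and small
# indel resolution.  Sufficient for the low-divergence simulated regime; real
# spliced alignments can be imported from GFF3 instead.

#' Spliced-alignment parameters
#'
#' @param anchor_k k-mer size of the genome index (>= 8).
#' @param seed_step spacing of query k-mers sampled for seeding.
#' @param min_intron,max_intron genomic gap range treated as an intron.
#' @param match,mismatch,gap_open,gap_ext alignment scoring.
#' @param splice_bonus score added when a gap's termini read GT..AG (either
#'   strand); \code{minor_bonus} applies to configured minor site pairs.
#' @param minor_sites list of minor donor/acceptor pairs.
#' @return validated \code{AlignParams} list.
#' @export
alignParams <- function(anchor_k = 12L, seed_step = 6L, min_intron = 20L,
                        max_intron = 5000L, match = 1, mismatch = -3,
                        gap_open = -4, gap_ext = -2, splice_bonus = 6,
                        minor_bonus = 3,
                        minor_sites = list(c("GC", "AG"), c("AT", "AC"))) {
  stopifnot(anchor_k >= 8, min_intron < max_intron)
  structure(list(anchor_k = as.integer(anchor_k),
                 seed_step = as.integer(seed_step),
                 min_intron = as.integer(min_intron),
                 max_intron = as.integer(max_intron),
                 match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_ext = gap_ext, splice_bonus = splice_bonus,
                 minor_bonus = minor_bonus, minor_sites = minor_sites),
            class = "AlignParams")
}

#' Build a k-mer index of a genome
#'
#' @param genome named \code{DNAStringSet} or named character vector.
#' @param k k-mer size.
#' @return index object reused across \code{\link{splicedAlign}} calls.
#' @export
genomeIndex <- function(genome, k = 12L) {
  seqs <- if (is(genome, "DNAStringSet")) {
    stats::setNames(as.character(genome), names(genome))
  } else genome
  all_kmers <- character(0); all_cid <- integer(0); all_pos <- integer(0)
  for (ci in seq_along(seqs)) {
    n <- nchar(seqs[[ci]])
    if (n < k) next
    pos <- seq_len(n - k + 1)
    km <- substring(seqs[[ci]], pos, pos + k - 1)
    all_kmers <- c(all_kmers, km)
    all_cid <- c(all_cid, rep.int(ci, length(pos)))
    all_pos <- c(all_pos, pos)
  }
  idx <- split(seq_along(all_kmers), all_kmers)
  env <- list2env(idx, hash = TRUE, size = max(1L, length(idx)))
  list(env = env, cid = all_cid, pos = all_pos,
       raw = lapply(seqs, charToRaw), seqs = seqs,
       contigs = names(seqs), k = as.integer(k))
}

# Exact anchors (qs, qe, diag, cid) from sampled query k-mers.
.findAnchors <- function(qseq, qraw, gi, params) {
  k <- gi$k
  qn <- length(qraw)
  if (qn < k) return(NULL)
  starts <- unique(c(seq(1L, qn - k + 1L, by = params$seed_step), qn - k + 1L))
  km <- substring(qseq, starts, starts + k - 1L)
  hits <- mget(km, envir = gi$env, ifnotfound = list(NULL))
  qpos <- integer(0); cid <- integer(0); gpos <- integer(0)
  for (i in seq_along(hits)) {
    h <- hits[[i]]
    if (is.null(h) || length(h) > 40) next   # skip absent or repetitive seeds
    qpos <- c(qpos, rep.int(starts[i], length(h)))
    cid <- c(cid, gi$cid[h])
    gpos <- c(gpos, gi$pos[h])
  }
  if (!length(qpos)) return(NULL)
  diag <- gpos - qpos
  grp <- paste(cid, diag)
  anchors <- NULL
  for (g in unique(grp)) {
    sel <- which(grp == g)
    qp <- sort(unique(qpos[sel]))
    d <- diag[sel][1]; cc <- cid[sel][1]
    # split a diagonal into runs separated by > 60 unseeded bases
    br <- c(0, which(diff(qp) > 60), length(qp))
    for (b in seq_len(length(br) - 1)) {
      run <- qp[(br[b] + 1):br[b + 1]]
      anchors <- rbind(anchors, c(run[1], run[length(run)] + k - 1L, d, cc))
    }
  }
  colnames(anchors) <- c("qs", "qe", "diag", "cid")
  # exact extension of each anchor in both directions
  for (i in seq_len(nrow(anchors))) {
    a <- anchors[i, ]
    graw <- gi$raw[[a["cid"]]]
    gn <- length(graw)
    # left
    w <- min(a["qs"] - 1L, a["qs"] + a["diag"] - 1L)
    if (w > 0) {
      eq <- qraw[(a["qs"] - w):(a["qs"] - 1L)] ==
        graw[(a["qs"] + a["diag"] - w):(a["qs"] + a["diag"] - 1L)]
      bad <- which(!eq)
      ext <- if (length(bad)) w - max(bad) else w
      anchors[i, "qs"] <- a["qs"] - ext
    }
    # right
    w <- min(qn - a["qe"], gn - (a["qe"] + a["diag"]))
    if (w > 0) {
      eq <- qraw[(a["qe"] + 1L):(a["qe"] + w)] ==
        graw[(a["qe"] + a["diag"] + 1L):(a["qe"] + a["diag"] + w)]
      bad <- which(!eq)
      ext <- if (length(bad)) min(bad) - 1L else w
      anchors[i, "qe"] <- a["qe"] + ext
    }
  }
  unique(anchors)
}

# Colinear chain maximizing covered query length; returns anchor rows in
# query order, or NULL.
.chainAnchors <- function(anchors, params) {
  best_chain <- NULL; best_score <- -Inf; best_g <- Inf; best_c <- Inf
  for (cc in unique(anchors[, "cid"])) {
    a <- anchors[anchors[, "cid"] == cc, , drop = FALSE]
    a <- a[order(a[, "qs"], a[, "qe"]), , drop = FALSE]
    n <- nrow(a)
    len <- a[, "qe"] - a[, "qs"] + 1
    score <- len; prev <- integer(n)
    for (i in seq_len(n)) {
      for (j in seq_len(i - 1)) {
        if (a[j, "qe"] >= a[i, "qe"]) next
        D <- a[i, "diag"] - a[j, "diag"]
        if (D < -30 || D > params$max_intron) next
        qgap <- a[i, "qs"] - a[j, "qe"] - 1
        if (qgap > 40) next
        ov <- max(0, -qgap)
        if (ov >= len[i]) next
        cand <- score[j] + len[i] - ov - 2
        if (cand > score[i]) { score[i] <- cand; prev[i] <- j }
      }
    }
    k <- which.max(score)
    chain <- k
    while (prev[k] > 0) { k <- prev[k]; chain <- c(k, chain) }
    ch <- a[chain, , drop = FALSE]
    g0 <- ch[1, "qs"] + ch[1, "diag"]
    if (score[chain[length(chain)]] > best_score ||
        (score[chain[length(chain)]] == best_score &&
         (g0 < best_g || (g0 == best_g && cc < best_c)))) {
      best_score <- score[chain[length(chain)]]
      best_chain <- ch; best_g <- g0; best_c <- cc
    }
  }
  best_chain
}

# Terminal query overhangs shorter than the anchor k produce no seed; when
# such an overhang (>= 8 bases, so chance placements are negligible) matches
# the genome exactly right after a canonical splice site at intron distance,
# the junction is recovered.  The nearest qualifying placement is used.
.rescueTerminal <- function(blocks, qseq, gseq, qn, params) {
  glen <- nchar(gseq)
  # 3' overhang; delta retracts chance matches that extended the terminal
  # block a few bases into the intron (which would spoil the donor check)
  for (delta in 0:3) {
    qe <- blocks[nrow(blocks), "qend"] - delta
    ge <- blocks[nrow(blocks), "gend"] - delta
    if (qe <= blocks[nrow(blocks), "qstart"]) break
    t <- qn - qe
    if (t < 6 || t >= 60) next
    tail <- substr(qseq, qe + 1, qn)
    donor <- substr(gseq, ge + 1, ge + 2)
    acc_want <- if (donor == "GT") "AG" else if (donor == "CT") "AC" else NA
    if (is.na(acc_want)) next
    wlo <- ge + params$min_intron + 1
    whi <- min(glen, ge + params$max_intron + t)
    if (whi - wlo + 1 < t) next
    win <- substr(gseq, wlo, whi)
    hits <- gregexpr(tail, win, fixed = TRUE)[[1]]
    done <- FALSE
    for (h in hits) {
      if (h < 0) break
      s2 <- wlo + h - 1
      if (substr(gseq, s2 - 2, s2 - 1) == acc_want) {
        blocks[nrow(blocks), "qend"] <- qe
        blocks[nrow(blocks), "gend"] <- ge
        blocks <- rbind(blocks, c(qe + 1, qn, s2, s2 + t - 1))
        done <- TRUE
        break
      }
    }
    if (done) break
  }
  # 5' overhang, mirrored
  for (delta in 0:3) {
    qs <- blocks[1, "qstart"] + delta
    gs <- blocks[1, "gstart"] + delta
    if (qs >= blocks[1, "qend"]) break
    t <- qs - 1
    if (t < 6 || t >= 60) next
    head <- substr(qseq, 1, t)
    acc <- substr(gseq, gs - 2, gs - 1)
    don_want <- if (acc == "AG") "GT" else if (acc == "AC") "CT" else NA
    if (is.na(don_want)) next
    wlo <- max(1, gs - params$max_intron - t)
    whi <- gs - params$min_intron - 1
    if (whi - wlo + 1 < t) next
    win <- substr(gseq, wlo, whi)
    hits <- gregexpr(head, win, fixed = TRUE)[[1]]
    done <- FALSE
    if (hits[1] > 0) {
      # nearest placement = rightmost hit with the donor dinucleotide
      for (h in rev(hits)) {
        e2 <- wlo + h - 1 + t - 1
        if (substr(gseq, e2 + 1, e2 + 2) == don_want) {
          blocks[1, "qstart"] <- qs
          blocks[1, "gstart"] <- gs
          blocks <- rbind(c(1, t, e2 - t + 1, e2), blocks)
          done <- TRUE
          break
        }
      }
    }
    if (done) break
  }
  colnames(blocks) <- c("qstart", "qend", "gstart", "gend")
  blocks
}

# Splice-site bonus for an intron [s, e] on contig sequence `gseq`.
.spliceBonus <- function(gseq, s, e, params) {
  donor <- substr(gseq, s, s + 1)
  acc <- substr(gseq, e - 1, e)
  if ((donor == "GT" && acc == "AG") || (donor == "CT" && acc == "AC"))
    return(params$splice_bonus)
  for (ms in params$minor_sites) {
    if ((donor == ms[1] && acc == ms[2]) ||
        (donor == .revcomp(ms[2]) && acc == .revcomp(ms[1])))
      return(params$minor_bonus)
  }
  0
}

# Resolve the junction between consecutive chained anchors; returns the split
# point j (last query base of the upstream block) chosen to minimize created
# mismatches, preferring canonical splice dinucleotides for introns.
.stitchPair <- function(qraw, graw, gseq, aQs, aQe, dA, bQs, bQe, dB, params) {
  D <- dB - dA
  m_ins <- max(0, -D)
  piv <- min(aQe, bQs - 1)
  jlo <- max(aQs, piv - 8)
  jhi <- min(bQe - 1 - m_ins, max(aQe, bQs - 1) + 8)
  if (jhi < jlo) { jlo <- jhi <- max(aQs, min(aQe, bQe - 1 - m_ins)) }
  gn <- length(graw); qn <- length(qraw)
  cost <- numeric(jhi - jlo + 1)
  bonus <- numeric(jhi - jlo + 1)
  for (t in seq_along(cost)) {
    j <- jlo + t - 1
    cA <- 0; cB <- 0
    if (j > aQe) {
      qq <- (aQe + 1):j
      gg <- qq + dA
      ok <- gg >= 1 & gg <= gn
      cA <- sum(!ok) + sum(qraw[qq[ok]] != graw[gg[ok]])
    }
    jB <- j + m_ins + 1
    if (jB <= bQs - 1) {
      qq <- jB:(bQs - 1)
      gg <- qq + dB
      ok <- gg >= 1 & gg <= gn
      cB <- sum(!ok) + sum(qraw[qq[ok]] != graw[gg[ok]])
    }
    cost[t] <- cA + cB
    if (D >= params$min_intron)
      bonus[t] <- .spliceBonus(gseq, j + dA + 1, j + dB, params)
  }
  sc <- bonus + params$mismatch * cost
  j <- jlo + which.max(sc) - 1L
  list(j = as.integer(j), D = as.integer(D), cost = cost[j - jlo + 1])
}

#' Align one EST to the genome with introns
#'
#' Anchors the read by exact k-mers, chains anchors colinearly, closes the
#' inter-anchor gaps, and turns genomic gaps in
#' \code{[min_intron, max_intron]} into introns whose boundary placement
#' prefers canonical (then minor) splice dinucleotides.  Both the read and
#' its reverse complement are tried; the better-scoring placement wins, with
#' ties broken by the leftmost genome coordinate.
#'
#' @param est character read sequence.
#' @param genome \code{DNAStringSet}/character genome (ignored when
#'   \code{index} is given).
#' @param params an \code{\link{alignParams}}.
#' @param index a prebuilt \code{\link{genomeIndex}}.
#' @param est_id,library labels stored in the result.
#' @return a single-alignment \linkS4class{SplicedAlignments}, or \code{NULL}
#'   when the read has no anchor chain (unmapped).
#' @export
splicedAlign <- function(est, genome = NULL, params = alignParams(),
                         index = NULL, est_id = "est", library = NA_character_) {
  gi <- if (is.null(index)) genomeIndex(genome, params$anchor_k) else index
  cands <- list()
  for (rc in c(FALSE, TRUE)) {
    q <- if (rc) .revcomp(est) else est
    a <- .alignOneOrientation(q, gi, params)
    if (!is.null(a)) { a$query_rc <- rc; cands[[length(cands) + 1]] <- a }
  }
  if (!length(cands)) return(NULL)
  sc <- vapply(cands, function(a) a$score, 0)
  g0 <- vapply(cands, function(a) a$blocks[1, "gstart"], 0)
  best <- order(-sc, g0)[1]
  .asSplicedAlignments(list(cands[[best]]), est_id, library, gi)
}

.alignOneOrientation <- function(qseq, gi, params) {
  qraw <- charToRaw(qseq)
  anchors <- .findAnchors(qseq, qraw, gi, params)
  if (is.null(anchors) || nrow(anchors) == 0) return(NULL)
  chain <- .chainAnchors(anchors, params)
  if (is.null(chain)) return(NULL)
  cc <- chain[1, "cid"]
  graw <- gi$raw[[cc]]
  gseq <- gi$seqs[[cc]]

  qs <- chain[, "qs"]; qe <- chain[, "qe"]; dg <- chain[, "diag"]
  n <- nrow(chain)
  blocks <- NULL
  indels <- NULL
  cur_qs <- qs[1]; cur_d <- dg[1]; cur_qe <- qe[1]
  if (n > 1) {
    for (i in 2:n) {
      if (dg[i] == cur_d) { cur_qe <- max(cur_qe, qe[i]); next }
      st <- .stitchPair(qraw, graw, gseq, cur_qs, cur_qe, cur_d,
                        qs[i], qe[i], dg[i], params)
      j <- st$j; D <- st$D
      blocks <- rbind(blocks, c(cur_qs, j, cur_qs + cur_d, j + cur_d))
      if (D < 0) {
        indels <- rbind(indels,
                        data.frame(gpos = j + cur_d, qpos = j + 1,
                                   length = -D, type = "ins",
                                   stringsAsFactors = FALSE))
      } else if (D < params$min_intron && D > 0) {
        indels <- rbind(indels,
                        data.frame(gpos = j + cur_d + 1, qpos = j,
                                   length = D, type = "del",
                                   stringsAsFactors = FALSE))
      }
      cur_qs <- j + max(0, -D) + 1
      cur_d <- dg[i]; cur_qe <- qe[i]
      if (cur_qe < cur_qs) cur_qe <- cur_qs
    }
  }
  blocks <- rbind(blocks, c(cur_qs, cur_qe, cur_qs + cur_d, cur_qe + cur_d))
  colnames(blocks) <- c("qstart", "qend", "gstart", "gend")
  blocks <- blocks[blocks[, "qend"] >= blocks[, "qstart"], , drop = FALSE]
  blocks <- .rescueTerminal(blocks, qseq, gseq, length(qraw), params)

  # mismatches within blocks
  mm_q <- integer(0); mm_g <- integer(0)
  for (b in seq_len(nrow(blocks))) {
    qq <- blocks[b, "qstart"]:blocks[b, "qend"]
    gg <- blocks[b, "gstart"]:blocks[b, "gend"]
    bad <- which(qraw[qq] != graw[gg])
    mm_q <- c(mm_q, qq[bad]); mm_g <- c(mm_g, gg[bad])
  }
  # introns: inter-block genomic gaps at or above the intron minimum
  introns <- data.frame(start = numeric(0), end = numeric(0),
                        donor = character(0), acceptor = character(0),
                        length = numeric(0), stringsAsFactors = FALSE)
  score <- 0
  if (nrow(blocks) > 1) {
    for (b in 2:nrow(blocks)) {
      gap <- blocks[b, "gstart"] - blocks[b - 1, "gend"] - 1
      if (gap >= params$min_intron) {
        s <- blocks[b - 1, "gend"] + 1; e <- blocks[b, "gstart"] - 1
        introns <- rbind(introns, data.frame(
          start = s, end = e, donor = substr(gseq, s, s + 1),
          acceptor = substr(gseq, e - 1, e), length = gap,
          stringsAsFactors = FALSE))
        score <- score + .spliceBonus(gseq, s, e, params)
      }
    }
  }
  aligned_q <- sum(blocks[, "qend"] - blocks[, "qstart"] + 1)
  n_indel_cols <- if (is.null(indels)) 0 else sum(indels$length)
  n_mm <- length(mm_q)
  matches <- aligned_q - n_mm
  score <- score + params$match * matches + params$mismatch * n_mm +
    (if (is.null(indels)) 0 else
       sum(params$gap_open + params$gap_ext * (indels$length - 1)))
  identity <- if (aligned_q + n_indel_cols > 0)
    matches / (aligned_q + n_indel_cols) else 0
  list(contig = gi$contigs[cc], blocks = blocks,
       mismatches = data.frame(qpos = mm_q, gpos = mm_g),
       indels = if (is.null(indels))
         data.frame(gpos = numeric(0), qpos = numeric(0),
                    length = numeric(0), type = character(0),
                    stringsAsFactors = FALSE) else indels,
       introns = introns, score = score, identity = identity,
       coverage = aligned_q / length(qraw))
}

.asSplicedAlignments <- function(alist, est_ids, libraries, gi) {
  meta <- data.frame(
    est_id = est_ids,
    library = rep_len(libraries, length(alist)),
    contig = vapply(alist, `[[`, "", "contig"),
    query_rc = vapply(alist, `[[`, FALSE, "query_rc"),
    score = vapply(alist, `[[`, 0, "score"),
    identity = vapply(alist, `[[`, 0, "identity"),
    coverage = vapply(alist, `[[`, 0, "coverage"),
    n_introns = vapply(alist, function(a) nrow(a$introns), 0L),
    start = vapply(alist, function(a) a$blocks[1, "gstart"], 0),
    end = vapply(alist, function(a) a$blocks[nrow(a$blocks), "gend"], 0),
    stringsAsFactors = FALSE)
  new("SplicedAlignments",
      meta = meta,
      blocks = lapply(alist, function(a)
        as.data.frame(a$blocks)[, c("gstart", "gend", "qstart", "qend")]),
      introns = lapply(alist, `[[`, "introns"),
      mismatches = lapply(alist, `[[`, "mismatches"),
      indels = lapply(alist, `[[`, "indels"))
}

#' Align a batch of ESTs
#'
#' @param reads read table with \code{est_id}, \code{sequence} and optionally
#'   \code{library} columns.
#' @param genome genome sequences.
#' @param params an \code{\link{alignParams}}.
#' @param index optional prebuilt \code{\link{genomeIndex}}.
#' @return list with \code{alignments} (a \linkS4class{SplicedAlignments} of
#'   the mapped reads) and \code{unmapped} (character ids).
#' @export
alignESTs <- function(reads, genome, params = alignParams(), index = NULL) {
  gi <- if (is.null(index)) genomeIndex(genome, params$anchor_k) else index
  libs <- if ("library" %in% names(reads)) reads$library else
    rep(NA_character_, nrow(reads))
  alist <- list(); ids <- character(0); libv <- character(0)
  unmapped <- character(0)
  for (i in seq_len(nrow(reads))) {
    cands <- list()
    for (rc in c(FALSE, TRUE)) {
      q <- if (rc) .revcomp(reads$sequence[i]) else reads$sequence[i]
      a <- .alignOneOrientation(q, gi, params)
      if (!is.null(a)) { a$query_rc <- rc; cands[[length(cands) + 1]] <- a }
    }
    if (!length(cands)) { unmapped <- c(unmapped, reads$est_id[i]); next }
    sc <- vapply(cands, function(a) a$score, 0)
    g0 <- vapply(cands, function(a) a$blocks[1, "gstart"], 0)
    best <- cands[[order(-sc, g0)[1]]]
    alist[[length(alist) + 1]] <- best
    ids <- c(ids, reads$est_id[i]); libv <- c(libv, libs[i])
  }
  if (!length(alist)) {
    return(list(alignments = new("SplicedAlignments",
                                 meta = data.frame(), blocks = list(),
                                 introns = list(), mismatches = list(),
                                 indels = list()),
                unmapped = unmapped))
  }
  list(alignments = .asSplicedAlignments(alist, ids, libv, gi),
       unmapped = unmapped)
}

#' Apply the mapping-quality filter
#'
#' Keeps alignments whose identity and query coverage are both at or above
#' the thresholds (boundary inclusive), and tabulates per-library totals of
#' aligned, kept ("mapped") and spliced (at least one intron) ESTs.
#'
#' @param alns a \linkS4class{SplicedAlignments}.
#' @param min_identity,min_coverage thresholds (default 0.90 each).
#' @return list with \code{kept} (subset) and \code{counts} (per-library
#'   data.frame: \code{library}, \code{n_aligned}, \code{n_mapped},
#'   \code{n_spliced}).
#' @export
filterMapped <- function(alns, min_identity = 0.90, min_coverage = 0.90) {
  m <- alns@meta
  keep <- m$identity >= min_identity & m$coverage >= min_coverage
  libs <- if (nrow(m)) unique(m$library) else character(0)
  counts <- data.frame(
    library = libs,
    n_aligned = vapply(libs, function(l) sum(m$library %in% l), 0L),
    n_mapped = vapply(libs, function(l) sum(keep & m$library %in% l), 0L),
    n_spliced = vapply(libs, function(l)
      sum(keep & m$library %in% l & m$n_introns > 0), 0L),
    stringsAsFactors = FALSE)
  rownames(counts) <- NULL
  list(kept = alns[keep], counts = counts)
}

#' Summary statistics of unique intron calls
#'
#' Introns with identical contig and coordinates are counted once.
#'
#' @param alns a \linkS4class{SplicedAlignments} (or an
#'   \linkS4class{ESTTranscriptSet}).
#' @return list: \code{n}, \code{median_length}, \code{min_length},
#'   \code{frac_below_2000} (length < 2000), \code{frac_above_200}
#'   (length > 200), \code{defined} (FALSE when there are no introns; the
#'   statistics are then NA rather than an error).
#' @export
intronSummary <- function(alns) {
  if (is(alns, "SplicedAlignments")) {
    contigs <- alns@meta$contig; intr <- alns@introns
  } else {
    contigs <- alns@meta$contig; intr <- alns@introns
  }
  key <- character(0); len <- numeric(0)
  for (i in seq_along(intr)) {
    it <- intr[[i]]
    if (nrow(it) == 0) next
    key <- c(key, paste(contigs[i], it$start, it$end))
    len <- c(len, it$end - it$start + 1)
  }
  if (!length(key))
    return(list(n = 0L, median_length = NA_real_, min_length = NA_real_,
                frac_below_2000 = NA_real_, frac_above_200 = NA_real_,
                defined = FALSE))
  len <- len[!duplicated(key)]
  list(n = length(len), median_length = stats::median(len),
       min_length = min(len), frac_below_2000 = mean(len < 2000),
       frac_above_200 = mean(len > 200), defined = TRUE)
}
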