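# Sense / cis-natural-antisense pair (SCP) detection among ESTGenes,
# orientation classification (convergent, divergent, contained) and
# coding-overlap classification (pure 3'-UTR vs CDS-involved).

# Does a gene carry at least one canonical GT-AG junction (in its own
# orientation)?
.junctionConfirmed <- function(genes, gi) {
  tset <- genes@transcripts
  tm <- tset@meta
  strand <- genes@meta$strand[gi]
  for (tid in genes@members[[gi]]) {
    it <- tset@introns[[match(tid, tm$transcript_id)]]
    if (nrow(it) == 0) next
    p <- vapply(seq_len(nrow(it)), function(j)
      .orientedPair(it$donor[j], it$acceptor[j], strand), "")
    if (any(p == "GT:AG")) return(TRUE)
  }
  FALSE
}

#' Find sense / cis-NAT pairs among ESTGenes
#'
#' All pairs of a forward- and a reverse-strand gene on the same contig with
#' a non-empty span intersection, where both members carry at least one
#' canonical GT-AG splice junction (genes without canonical junctions are
#' excluded to guard against wrong strand calls).  Unknown-strand genes never
#' participate.
#'
#' @param genes an \linkS4class{ESTGeneSet}.
#' @param classify also classify orientation (default TRUE).
#' @return data.frame: \code{gene_plus}, \code{gene_minus}, \code{contig},
#'   \code{ov_start}, \code{ov_end}, and (when classified)
#'   \code{orientation}.
#' @export
findSCPs <- function(genes, classify = TRUE) {
  m <- genes@meta
  conf <- vapply(seq_len(nrow(m)), function(i)
    m$strand[i] %in% c("+", "-") && .junctionConfirmed(genes, i), FALSE)
  plus <- which(m$strand == "+" & conf)
  minus <- which(m$strand == "-" & conf)
  rows <- list()
  for (i in plus) for (j in minus) {
    if (m$contig[i] != m$contig[j]) next
    os <- max(m$start[i], m$start[j]); oe <- min(m$end[i], m$end[j])
    if (os > oe) next
    rows[[length(rows) + 1]] <- data.frame(
      gene_plus = m$gene_id[i], gene_minus = m$gene_id[j],
      contig = m$contig[i],
      plus_start = m$start[i], plus_end = m$end[i],
      minus_start = m$start[j], minus_end = m$end[j],
      ov_start = os, ov_end = oe, stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    out <- data.frame(gene_plus = character(0), gene_minus = character(0),
                      contig = character(0), plus_start = numeric(0),
                      plus_end = numeric(0), minus_start = numeric(0),
                      minus_end = numeric(0), ov_start = numeric(0),
                      ov_end = numeric(0), stringsAsFactors = FALSE)
    if (classify) out$orientation <- character(0)
    return(out)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$contig, out$ov_start, out$gene_plus), , drop = FALSE]
  rownames(out) <- NULL
  if (classify)
    out$orientation <- vapply(seq_len(nrow(out)), function(r)
      classifyOrientation(out[r, ]), "")
  out
}

#' Classify the orientation of an antisense pair
#'
#' \code{contained} when either span fully covers the other (evaluated
#' first); otherwise \code{convergent} (tail-to-tail) when the overlap
#' includes the forward gene's 3' terminus and the reverse gene's 3'
#' terminus, else \code{divergent} (head-to-head).
#'
#' @param scp one row with \code{plus_start}, \code{plus_end},
#'   \code{minus_start}, \code{minus_end} (or a list with those fields).
#' @return \code{"contained"}, \code{"convergent"} or \code{"divergent"}.
#' @examples
#' classifyOrientation(list(plus_start = 100, plus_end = 500,
#'                          minus_start = 450, minus_end = 900)) # convergent
#' @export
classifyOrientation <- function(scp) {
  ps <- scp$plus_start; pe <- scp$plus_end
  ms <- scp$minus_start; me <- scp$minus_end
  if ((ps <= ms && pe >= me) || (ms <= ps && me >= pe)) return("contained")
  # forward gene 3' end = pe; reverse gene 3' end = ms
  if (ps < ms) "convergent" else "divergent"
}

#' Classify the coding overlap of an antisense pair
#'
#' \code{pure_3utr} iff the overlap intersects neither gene's CDS and lies
#' 3' of each gene's CDS in that gene's own orientation (genomically right
#' of the forward gene's CDS and left of the reverse gene's CDS);
#' \code{cds_involved} otherwise; \code{undetermined} when a CDS is missing
#' for either gene.
#'
#' @param scp one SCP row (see \code{\link{findSCPs}}).
#' @param cds data.frame with \code{gene_id}, \code{cds_start},
#'   \code{cds_end} (genomic), e.g. the \code{genes} element of
#'   \code{\link{importTruthAnnotation}} or a user annotation.
#' @return character class.
#' @export
classifyCoding <- function(scp, cds) {
  ca <- cds[match(scp$gene_plus, cds$gene_id), , drop = FALSE]
  cb <- cds[match(scp$gene_minus, cds$gene_id), , drop = FALSE]
  if (nrow(ca) == 0 || nrow(cb) == 0 ||
      is.na(ca$cds_start) || is.na(cb$cds_start)) return("undetermined")
  os <- scp$ov_start; oe <- scp$ov_end
  clear_a <- .ovWidth(os, oe, ca$cds_start, ca$cds_end) <= 0
  clear_b <- .ovWidth(os, oe, cb$cds_start, cb$cds_end) <= 0
  three_prime_a <- os > ca$cds_end      # '+' gene: 3' is genomic right
  three_prime_b <- oe < cb$cds_start    # '-' gene: 3' is genomic left
  if (clear_a && clear_b && three_prime_a && three_prime_b) "pure_3utr"
  else "cds_involved"
}

#' Summarize an SCP set
#'
#' Integer counts plus display percentages (nearest integer): orientation
#' breakdown, the convergent share, and among convergent pairs the
#' protein-coding share and the pure-3'-UTR share of the coding ones.
#'
#' @param scps SCP table with an \code{orientation} column; optionally a
#'   logical \code{coding} column (both members protein-coding) and a
#'   \code{coding_class} column.
#' @return list of counts and percentages; with no input all counts are zero
#'   and the percentages are \code{NA} (flagged by \code{defined = FALSE}).
#' @examples
#' scps <- data.frame(orientation = rep(c("convergent", "divergent",
#'                                        "contained"), c(68, 7, 28)))
#' scpSummary(scps)$pct_convergent  # 67
#' @export
scpSummary <- function(scps) {
  n <- nrow(scps)
  if (n == 0)
    return(list(n = 0L, n_convergent = 0L, n_divergent = 0L,
                n_contained = 0L, pct_convergent = NA_real_,
                n_coding_convergent = NA_integer_,
                pct_coding_convergent = NA_real_,
                n_pure3utr = NA_integer_, pct_pure3utr_of_coding = NA_real_,
                defined = FALSE))
  nc <- sum(scps$orientation == "convergent")
  nd <- sum(scps$orientation == "divergent")
  nn <- sum(scps$orientation == "contained")
  out <- list(n = n, n_convergent = nc, n_divergent = nd, n_contained = nn,
              pct_convergent = round(100 * nc / n),
              n_coding_convergent = NA_integer_,
              pct_coding_convergent = NA_real_,
              n_pure3utr = NA_integer_, pct_pure3utr_of_coding = NA_real_,
              defined = TRUE)
  if ("coding" %in% names(scps) && nc > 0) {
    conv <- scps[scps$orientation == "convergent", , drop = FALSE]
    ncc <- sum(conv$coding)
    out$n_coding_convergent <- ncc
    out$pct_coding_convergent <- round(100 * ncc / nc)
    if ("coding_class" %in% names(scps) && ncc > 0) {
      np <- sum(conv$coding & conv$coding_class == "pure_3utr")
      out$n_pure3utr <- np
      out$pct_pure3utr_of_coding <- round(100 * np / ncc)
    }
  }
  out
}
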