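# Gene x library EST count matrices and the over-representation analyses:
# support listing, Monte-Carlo chi-square across culture stages, and the
# exact two-sided binomial test between strains.

#' Build a gene-by-library EST count matrix
#'
#' Counts of ESTs as a semi-quantitative expression measurement from
#' non-normalized libraries.  Every EST must be assigned to at most one
#' gene.
#'
#' @param support data.frame with \code{est_id}, \code{library},
#'   \code{gene_id} columns (one row per assigned EST).
#' @param libraries library table (\code{name}, \code{day},
#'   \code{karyotype}), e.g. \code{\link{table1Libraries}}; libraries with
#'   zero assigned ESTs keep a zero column.
#' @return a \code{SummarizedExperiment} with assay \code{counts}, library
#'   metadata as \code{colData} and library totals in \code{metadata}.
#' @export
buildCounts <- function(support, libraries) {
  if (anyDuplicated(support$est_id))
    stop("integrity error: an EST is assigned to more than one gene")
  genes <- sort(unique(support$gene_id))
  libs <- libraries$name
  counts <- matrix(0L, length(genes), length(libs),
                   dimnames = list(genes, libs))
  if (nrow(support)) {
    tab <- table(factor(support$gene_id, levels = genes),
                 factor(support$library, levels = libs))
    counts[] <- as.integer(tab)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(libraries, row.names = libs))
  S4Vectors::metadata(se)$library_totals <- colSums(counts)
  se
}

.countsOf <- function(x) {
  if (is(x, "SummarizedExperiment"))
    SummarizedExperiment::assay(x, "counts") else as.matrix(x)
}

#' Histogram of per-gene EST support
#'
#' @param x count matrix or \code{SummarizedExperiment} from
#'   \code{\link{buildCounts}}.
#' @param bin_edges increasing vector of lower bin edges starting at the
#'   smallest support level of interest; bins are
#'   \code{[e1, e2), [e2, e3), ..., [ek, Inf)} and must partition the row
#'   sums present.
#' @param min_support threshold for \code{genes_at_or_above} (default 50).
#' @return list with \code{bins} (data.frame \code{from}, \code{to},
#'   \code{n_genes}) and \code{genes_at_or_above}.
#' @export
supportHistogram <- function(x, bin_edges = c(0, 1, 50, 100, 150, 200, 250,
                                              300, 350, 400),
                             min_support = 50) {
  counts <- .countsOf(x)
  rs <- rowSums(counts)
  if (is.unsorted(bin_edges, strictly = TRUE))
    stop("bin_edges must be strictly increasing")
  if (length(rs) && min(rs) < bin_edges[1])
    stop("bin_edges do not cover the smallest row sum: not a partition")
  hi <- c(bin_edges[-1] - 1, Inf)
  n <- vapply(seq_along(bin_edges), function(i)
    sum(rs >= bin_edges[i] & rs <= hi[i]), 0L)
  list(bins = data.frame(from = bin_edges, to = hi, n_genes = n),
       genes_at_or_above = sum(rs >= min_support))
}

#' Monte-Carlo chi-square test of one gene's counts across libraries
#'
#' Tests whether a gene's EST counts deviate from proportionality to the
#' library totals, with the null distribution simulated by multinomial
#' draws: the statistic is \eqn{\sum_l (O_l - E_l)^2 / E_l} with
#' \eqn{E_l = n \cdot t_l / \sum t}, and
#' \eqn{p = (1 + \#\{T^* \ge T\}) / (B + 1)}.  This is R's simulated-p-value
#' chi-square (\code{\link[stats]{chisq.test}}), made deterministic under
#' \code{seed}.
#'
#' @param x integer vector of one gene's counts per library.
#' @param totals library totals defining the null proportions.
#' @param B Monte-Carlo replicates (default 2000).
#' @param seed optional integer seed.
#' @param alpha flagging threshold (default 1e-5); attainability requires
#'   \code{B >= 1/alpha}.
#' @return list: \code{statistic}, \code{p_value}, \code{flagged},
#'   \code{method}; a zero row is skipped (\code{NA} p with a reason).
#' @export
chisqStageTest <- function(x, totals, B = 2000L, seed = NULL, alpha = 1e-5) {
  stopifnot(length(x) == length(totals), all(totals > 0))
  if (sum(x) == 0)
    return(list(statistic = NA_real_, p_value = NA_real_, flagged = FALSE,
                method = "chisq_mc", skipped = "zero row total"))
  if (!is.null(seed)) set.seed(seed)
  props <- totals / sum(totals)
  ht <- suppressWarnings(stats::chisq.test(x, p = props,
                                           simulate.p.value = TRUE,
                                           B = as.integer(B)))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       flagged = ht$p.value < alpha, method = "chisq_mc")
}

#' Exact two-sided binomial test of strain representation
#'
#' Minimum-likelihood two-sided p: the sum of binomial probabilities of all
#' outcomes no more likely than the observed one
#' (\code{\link[stats]{binom.test}}).
#'
#' @param k ESTs from the strain of interest.
#' @param n total ESTs of the gene.
#' @param p0 null proportion, e.g. the strain's share of all mapped ESTs.
#' @param alpha flagging threshold (default 1e-5).
#' @return list: \code{statistic} (k), \code{p_value}, \code{flagged},
#'   \code{method}.
#' @examples
#' binomStrainTest(0, 10, 0.5)$p_value  # 2/1024
#' @export
binomStrainTest <- function(k, n, p0, alpha = 1e-5) {
  if (k < 0 || k > n) stop("k must lie in [0, n]")
  if (p0 <= 0 || p0 >= 1) stop("p0 must lie in (0, 1)")
  ht <- stats::binom.test(k, n, p0, alternative = "two.sided")
  list(statistic = k, p_value = ht$p.value, flagged = ht$p.value < alpha,
       method = "binomial")
}

#' Run both over-representation tests over a count matrix
#'
#' @param se \code{SummarizedExperiment} from \code{\link{buildCounts}} with
#'   \code{karyotype} in its \code{colData}.
#' @param B Monte-Carlo replicates for the chi-square test.
#' @param alpha flagging threshold.
#' @param seed integer seed (the chi-square null is simulated).
#' @param min_total genes with fewer supporting ESTs are skipped (default 1).
#' @param bh add a Benjamini-Hochberg adjusted column per test (reported,
#'   not used for flagging).
#' @return data.frame per gene: totals, chi-square statistic and p, binomial
#'   k/p (strain of interest = monokaryon), and flag columns.
#' @export
overrepTests <- function(se, B = 2000L, alpha = 1e-5, seed = 1L,
                         min_total = 1L, bh = TRUE) {
  counts <- .countsOf(se)
  totals <- colSums(counts)
  karyo <- SummarizedExperiment::colData(se)$karyotype
  mono <- karyo == "monokaryon"
  p0 <- sum(totals[mono]) / sum(totals)
  rs <- rowSums(counts)
  keep <- which(rs >= min_total)
  set.seed(seed)
  out <- data.frame(gene_id = rownames(counts)[keep], row_total = rs[keep],
                    stringsAsFactors = FALSE)
  cs <- lapply(keep, function(i)
    chisqStageTest(counts[i, ], totals, B = B, alpha = alpha))
  out$chisq_stat <- vapply(cs, `[[`, 0, "statistic")
  out$chisq_p <- vapply(cs, `[[`, 0, "p_value")
  out$chisq_flagged <- vapply(cs, `[[`, FALSE, "flagged")
  out$k_monokaryon <- vapply(keep, function(i) sum(counts[i, mono]), 0)
  bt <- lapply(keep, function(i)
    binomStrainTest(sum(counts[i, mono]), rs[i], p0, alpha = alpha))
  out$binom_p <- vapply(bt, `[[`, 0, "p_value")
  out$binom_flagged <- vapply(bt, `[[`, FALSE, "flagged")
  if (bh) {
    out$chisq_p_bh <- stats::p.adjust(out$chisq_p, "BH")
    out$binom_p_bh <- stats::p.adjust(out$binom_p, "BH")
  }
  rownames(out) <- NULL
  out
}

#' Sum EST counts over gene and library subsets
#'
#' @param x count matrix or \code{SummarizedExperiment}.
#' @param gene_subset gene ids (rows).
#' @param library_subset library names (columns) for the restricted sum.
#' @return named numeric vector: \code{subset_sum} (gene subset restricted
#'   to the named libraries) and \code{total_sum} (gene subset over all
#'   libraries).
#' @export
pathwayCounts <- function(x, gene_subset, library_subset) {
  counts <- .countsOf(x)
  if (length(gene_subset) == 0)
    return(c(subset_sum = 0, total_sum = 0))
  if (!all(gene_subset %in% rownames(counts)))
    stop("unknown gene id(s): ",
         paste(setdiff(gene_subset, rownames(counts)), collapse = ", "))
  if (!all(library_subset %in% colnames(counts)))
    stop("unknown library: ",
         paste(setdiff(library_subset, colnames(counts)), collapse = ", "))
  sub <- counts[gene_subset, , drop = FALSE]
  c(subset_sum = sum(sub[, library_subset, drop = FALSE]),
    total_sum = sum(sub))
}

#' Library-level EST accounting
#'
#' Totals and display percentages over a per-library accounting table:
#' the share of filtered ESTs that passed the mapping-quality filter
#' ("mapped") and the share of mapped alignments containing introns
#' ("spliced"), both rounded to the nearest integer percent.
#'
#' @param df data.frame with columns \code{library}, \code{filtered},
#'   \code{mapped}, \code{spliced}.
#' @return list: \code{total_filtered}, \code{total_mapped},
#'   \code{total_spliced}, \code{pct_mapped}, \code{pct_spliced}.
#' @export
libraryAccounting <- function(df) {
  tf <- sum(df$filtered); tm <- sum(df$mapped); ts <- sum(df$spliced)
  list(total_filtered = tf, total_mapped = tm, total_spliced = ts,
       pct_mapped = round(100 * tm / tf),
       pct_spliced = round(100 * ts / tm))
}
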