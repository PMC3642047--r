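# The cassette-exon fraction CE/(CE+RI) under three policies for counting
# stretches of consecutively skipped exons, its expectation from the
# intron-length linear model, and the variant-EST index.

#' Cassette-exon fraction under a CSE counting policy
#'
#' The CE fraction CE/(CE+RI) is used to infer whether exon definition or
#' intron definition dominates splice-site recognition.  How a stretch of
#' consecutively skipped exons (CSE) enters the CE count changes the answer,
#' so three policies are computed: \code{each_exon} counts every exon of a
#' stretch as a separate cassette exon; \code{stretch_as_one} counts a
#' stretch as a single skipping event; \code{exclude_cse} drops stretches
#' entirely and keeps only single-exon events.
#'
#' @param exon_counts integer vector with one entry per reliable
#'   skipped-exon event: 1 for a single cassette exon, k for a k-exon
#'   stretch.
#' @param ri_exon_count number of reliable retained-intron exons.
#' @param policy one of \code{"each_exon"}, \code{"stretch_as_one"},
#'   \code{"exclude_cse"}.
#' @param frac_long_introns optional fraction of introns longer than 200
#'   bases, used to add the linear-model expectation
#'   (\code{\link{expectedCEFraction}}).
#' @return data.frame row: \code{policy}, \code{ce_count}, \code{ri_count},
#'   \code{fraction} (full precision), \code{display} (the value rounded as
#'   conventionally displayed: two decimals for \code{each_exon}, three
#'   otherwise), \code{defined}, and when \code{frac_long_introns} is given,
#'   \code{expected_fraction}.
#' @examples
#' ceFraction(c(rep(1, 15), 11), 246, "each_exon")$display       # 0.10
#' ceFraction(c(rep(1, 15), 11), 246, "stretch_as_one")$display  # 0.061
#' ceFraction(c(rep(1, 15), 11), 246, "exclude_cse")$display     # 0.057
#' @export
ceFraction <- function(exon_counts, ri_exon_count,
                       policy = c("each_exon", "stretch_as_one",
                                  "exclude_cse"),
                       frac_long_introns = NULL) {
  policy <- match.arg(policy)
  stopifnot(all(exon_counts >= 1), ri_exon_count >= 0)
  ce <- switch(policy,
               each_exon = sum(exon_counts),
               stretch_as_one = length(exon_counts),
               exclude_cse = sum(exon_counts == 1))
  denom <- ce + ri_exon_count
  frac <- if (denom > 0) ce / denom else NA_real_
  digits <- if (policy == "each_exon") 2L else 3L
  out <- data.frame(policy = policy, ce_count = ce,
                    ri_count = ri_exon_count, fraction = frac,
                    display = round(frac, digits), defined = denom > 0,
                    stringsAsFactors = FALSE)
  if (!is.null(frac_long_introns))
    out$expected_fraction <- expectedCEFraction(frac_long_introns)
  out
}

#' CE fraction report across all three CSE policies
#'
#' @inheritParams ceFraction
#' @return data.frame with one row per policy.  The CE counts are
#'   monotone: each_exon >= stretch_as_one >= exclude_cse.
#' @export
ceFractionReport <- function(exon_counts, ri_exon_count,
                             frac_long_introns = NULL) {
  do.call(rbind, lapply(c("each_exon", "stretch_as_one", "exclude_cse"),
                        function(p) ceFraction(exon_counts, ri_exon_count, p,
                                               frac_long_introns)))
}

#' Expected CE fraction from the intron-length linear model
#'
#' Cross-species regression of the CE fraction on the fraction of introns
#' longer than 200 bases: y = 0.84 x + 0.00.  Long introns favour exon
#' definition, hence exon skipping.
#'
#' @param frac_long_introns fraction of introns longer than 200 bases, in
#'   [0, 1].
#' @return the expected CE fraction.
#' @examples
#' expectedCEFraction(0.05)  # 0.042, displays as 0.04
#' @export
expectedCEFraction <- function(frac_long_introns) {
  if (any(frac_long_introns < 0 | frac_long_introns > 1))
    stop("frac_long_introns must lie in [0, 1]")
  0.84 * frac_long_introns
}

#' Variant-EST index
#'
#' The number of splice-variant genes divided by the number of ESTs, a
#' sequencing-depth-normalized measure of alternative-splicing abundance for
#' comparing EST projects.
#'
#' @param n_variant_genes number of genes with alternative splice forms.
#' @param n_ests number of (mapped) ESTs; must be positive.
#' @return list: \code{n_variant_genes}, \code{n_ests}, \code{index} (full
#'   precision), \code{display} (three decimals).
#' @examples
#' veIndex(262, 46153)$display   # 0.006
#' @export
veIndex <- function(n_variant_genes, n_ests) {
  if (n_ests <= 0) stop("n_ests must be positive")
  idx <- n_variant_genes / n_ests
  list(n_variant_genes = n_variant_genes, n_ests = n_ests, index = idx,
       display = round(idx, 3))
}

#' Fraction of introns longer than a threshold in an annotation
#'
#' Computed over the introns of the (planted or predicted) gene models
#' rather than over EST-observed intron calls.
#'
#' @param exons exon table with \code{isoform_id}, \code{start}, \code{end}
#'   (as from \code{\link{importTruthAnnotation}} or
#'   \code{\link{truthExons}}).
#' @param threshold length threshold in bases (default 200, exclusive).
#' @return list: \code{n_introns}, \code{fraction}.
#' @export
fracLongIntrons <- function(exons, threshold = 200) {
  lens <- numeric(0)
  for (iso in unique(exons$isoform_id)) {
    ex <- exons[exons$isoform_id == iso, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) > 1)
      lens <- c(lens, ex$start[-1] - ex$end[-nrow(ex)] - 1)
  }
  list(n_introns = length(lens),
       fraction = if (length(lens)) mean(lens > threshold) else NA_real_)
}
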