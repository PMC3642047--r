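# Loaders for the study tables shipped with the package: the per-library EST
# accounting, the gene-support histogram, the triterpenoid-pathway EST
# counts, the curated splice-event tallies and headline summary quantities of
# the mycelium EST project.

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "ESTforge")
  if (path == "") stop("missing extdata file: ", file)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Bundled study tables
#'
#' \code{estLibraryCounts}: per-library EST accounting (filtered, mapped and
#' spliced counts for the five mycelium libraries).
#' \code{geneSupportBins}: histogram of predicted genes by EST support.
#' \code{triterpenoidCounts}: per-library EST counts of the triterpenoid
#' backbone biosynthesis genes (the last row, squalene synthase, acts
#' downstream of the backbone pathway).
#' \code{spliceEventTallies}: curated skipped-exon and retained-intron exon
#' tallies (15 single cassette exons, one 11-exon stretch, 246
#' retained-intron exons).
#' \code{studySummary}: named headline quantities (mapped EST total, number
#' of splice-variant genes, fraction of predicted-gene introns over 200
#' bases, and the comparison species' variant/EST counts).
#'
#' @return a data.frame (or named vector for \code{studySummary}).
#' @export
estLibraryCounts <- function() .extdata("library_est_counts.tsv")

#' @rdname estLibraryCounts
#' @export
geneSupportBins <- function() .extdata("gene_support_bins.tsv")

#' @rdname estLibraryCounts
#' @export
triterpenoidCounts <- function() .extdata("triterpenoid_est_counts.tsv")

#' @rdname estLibraryCounts
#' @export
spliceEventTallies <- function() .extdata("splice_event_tallies.tsv")

#' @rdname estLibraryCounts
#' @export
studySummary <- function() {
  df <- .extdata("study_summary.tsv")
  stats::setNames(df$value, df$quantity)
}

#' Expand curated event tallies into per-event exon counts
#'
#' @param tallies table as from \code{\link{spliceEventTallies}}.
#' @return list with \code{skipped_exon_counts} (one entry per skipped-exon
#'   event) and \code{ri_exon_count}.
#' @export
eventTallyCounts <- function(tallies = spliceEventTallies()) {
  sk <- tallies[tallies$event_class == "skipped", , drop = FALSE]
  ri <- tallies[tallies$event_class == "retained", , drop = FALSE]
  list(skipped_exon_counts = rep(sk$exon_count, sk$n_events),
       ri_exon_count = sum(ri$n_events * ri$exon_count))
}
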