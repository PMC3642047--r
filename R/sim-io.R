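# File output of simulated data sets and the matching readers.
# Genome as FASTA, truth annotation as GFF3 (1-based inclusive), reads as
# FASTA with a tab-separated per-base quality sidecar, and flat truth tables.

#' Write a simulated data set to disk
#'
#' Produces \code{genome.fasta}, \code{truth.gff3} (gene / mRNA / exon / CDS
#' hierarchy, 1-based inclusive), \code{reads.fasta},
#' \code{reads.qual.tsv} (per-base error probabilities), \code{truth_reads.tsv},
#' \code{planted_events.tsv} and \code{antisense_pairs.tsv}.
#'
#' @param truth a \linkS4class{GenomeTruth}.
#' @param reads read table from \code{\link{sampleESTs}} (may have 0 rows).
#' @param out_dir output directory; created if missing.
#' @return invisibly, the vector of file paths written.
#' @export
writeSimOutputs <- function(truth, reads, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  paths <- file.path(out_dir,
                     c("genome.fasta", "truth.gff3", "reads.fasta",
                       "reads.qual.tsv", "truth_reads.tsv",
                       "planted_events.tsv", "antisense_pairs.tsv"))
  names(paths) <- c("genome", "gff3", "reads", "quals", "truth_reads",
                    "events", "antisense")
  Biostrings::writeXStringSet(truth@contigs, paths["genome"])
  .writeTruthGFF3(truth, paths["gff3"])

  seqs <- Biostrings::DNAStringSet(
    if (nrow(reads)) stats::setNames(reads$sequence, reads$est_id)
    else character(0))
  Biostrings::writeXStringSet(seqs, paths["reads"])
  qlines <- if (nrow(reads)) {
    paste(reads$est_id,
          vapply(reads$quality,
                 function(q) paste(signif(q, 6), collapse = ","), ""),
          sep = "\t")
  } else character(0)
  writeLines(c("est_id\terror_prob", qlines), paths["quals"])

  tr <- reads
  tr$quality <- NULL
  tr$blocks <- vapply(reads$blocks, function(b) {
    if (is.null(b)) "" else paste(paste(b[, 1], b[, 2], sep = "-"),
                                  collapse = ";")
  }, "")
  utils::write.table(tr, paths["truth_reads"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(truth@events, paths["events"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(truth@antisense, paths["antisense"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

.writeTruthGFF3 <- function(truth, path) {
  lines <- c("##gff-version 3")
  g <- truth@genes
  for (i in seq_len(nrow(g))) {
    lines <- c(lines, paste(
      g$contig[i], "sim", "gene", g$start[i], g$end[i], ".", g$strand[i], ".",
      sprintf("ID=%s", g$gene_id[i]), sep = "\t"))
    isos <- truth@isoforms[truth@isoforms$gene_id == g$gene_id[i], ]
    for (j in seq_len(nrow(isos))) {
      ex <- truth@exons[truth@exons$isoform_id == isos$isoform_id[j], ,
                        drop = FALSE]
      ex <- ex[order(ex$start), , drop = FALSE]
      lines <- c(lines, paste(
        g$contig[i], "sim", "mRNA", min(ex$start), max(ex$end), ".",
        g$strand[i], ".",
        sprintf("ID=%s;Parent=%s", isos$isoform_id[j], g$gene_id[i]),
        sep = "\t"))
      lines <- c(lines, vapply(seq_len(nrow(ex)), function(k) paste(
        g$contig[i], "sim", "exon", ex$start[k], ex$end[k], ".", g$strand[i],
        ".", sprintf("Parent=%s", isos$isoform_id[j]), sep = "\t"), ""))
      if (j == 1L) {
        lines <- c(lines, paste(
          g$contig[i], "sim", "CDS", g$cds_start[i], g$cds_end[i], ".",
          g$strand[i], "0",
          sprintf("ID=cds-%s;Parent=%s", g$gene_id[i], isos$isoform_id[j]),
          sep = "\t"))
      }
    }
  }
  writeLines(lines, path)
}

#' Read back a simulated data set
#'
#' Counterpart of \code{\link{writeSimOutputs}} for the read files: sequences,
#' per-base quality sidecar and the truth table are combined into a table of
#' the same shape as the \code{\link{sampleESTs}} output.
#'
#' @param dir directory written by \code{\link{writeSimOutputs}}.
#' @return \code{data.frame} of reads with list columns \code{quality} and
#'   \code{blocks}.
#' @export
readSimulatedReads <- function(dir) {
  seqs <- Biostrings::readDNAStringSet(file.path(dir, "reads.fasta"))
  quals <- utils::read.delim(file.path(dir, "reads.qual.tsv"),
                             stringsAsFactors = FALSE)
  tr <- utils::read.delim(file.path(dir, "truth_reads.tsv"),
                          stringsAsFactors = FALSE)
  if (nrow(tr) == 0) {
    tr$quality <- list(); tr$blocks <- list()
    return(tr)
  }
  tr$sequence <- as.character(seqs[tr$est_id])
  qv <- lapply(strsplit(quals$error_prob[match(tr$est_id, quals$est_id)], ","),
               as.numeric)
  tr$quality <- qv
  tr$blocks <- lapply(tr$blocks, function(s) {
    if (is.na(s) || s == "") return(NULL)
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], "-", fixed = TRUE)
    m <- do.call(rbind, lapply(parts, as.numeric))
    unname(m)
  })
  tr$contaminant <- as.logical(tr$contaminant)
  tr
}

#' Import a truth annotation written as GFF3
#'
#' Reads the gene / mRNA / exon / CDS hierarchy back into flat tables with
#' 1-based inclusive coordinates.
#'
#' @param path GFF3 file.
#' @return list with elements \code{genes} (gene_id, contig, strand, start,
#'   end, cds_start, cds_end) and \code{exons} (isoform_id, gene_id, start,
#'   end).
#' @export
importTruthAnnotation <- function(path) {
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  genes <- df[df$type == "gene", ]
  cds <- df[df$type == "CDS", ]
  mrna <- df[df$type == "mRNA", ]
  ex <- df[df$type == "exon", ]
  parent_chr <- function(p) vapply(p, function(v)
    if (length(v)) v[[1]] else NA_character_, "")
  mrna$gene <- parent_chr(mrna$Parent)
  ex$iso <- parent_chr(ex$Parent)
  cds$iso <- parent_chr(cds$Parent)
  cds$gene <- mrna$gene[match(cds$iso, mrna$ID)]
  g <- data.frame(gene_id = genes$ID, contig = as.character(genes$seqnames),
                  strand = as.character(genes$strand),
                  start = genes$start, end = genes$end,
                  stringsAsFactors = FALSE)
  g$cds_start <- cds$start[match(g$gene_id, cds$gene)]
  g$cds_end <- cds$end[match(g$gene_id, cds$gene)]
  e <- data.frame(isoform_id = ex$iso,
                  gene_id = mrna$gene[match(ex$iso, mrna$ID)],
                  start = ex$start, end = ex$end, stringsAsFactors = FALSE)
  list(genes = g, exons = e[order(e$isoform_id, e$start), ])
}
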