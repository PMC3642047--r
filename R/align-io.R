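# GFF3 serialization of spliced alignments (match / match_part features with
# Target attributes), and import of externally produced alignments.

#' Export spliced alignments as GFF3
#'
#' One \code{match} feature per alignment with \code{match_part} children;
#' query intervals travel in the \code{Target} attribute.  Per-column detail
#' (mismatch/indel positions) is not serialized; identity and coverage are
#' carried as attributes.
#'
#' @param alns a \linkS4class{SplicedAlignments}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
exportAlignments <- function(alns, path) {
  lines <- "##gff-version 3"
  m <- alns@meta
  for (i in seq_len(nrow(m))) {
    b <- alns@blocks[[i]]
    attrs <- sprintf(
      "ID=aln%d;est_id=%s;library=%s;query_rc=%d;identity=%.6f;coverage=%.6f;score=%g",
      i, m$est_id[i], m$library[i], as.integer(m$query_rc[i]),
      m$identity[i], m$coverage[i], m$score[i])
    lines <- c(lines, paste(m$contig[i], "ESTforge", "match",
                            m$start[i], m$end[i], ".", "+", ".", attrs,
                            sep = "\t"))
    lines <- c(lines, vapply(seq_len(nrow(b)), function(r) paste(
      m$contig[i], "ESTforge", "match_part", b$gstart[r], b$gend[r], ".",
      "+", ".",
      sprintf("Parent=aln%d;Target=%s %d %d", i, m$est_id[i],
              b$qstart[r], b$qend[r]), sep = "\t"), ""))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Import spliced alignments from GFF3
#'
#' Accepts \code{match}/\code{match_part} hierarchies (as written by
#' \code{\link{exportAlignments}} or produced externally).  Intron donor and
#' acceptor dinucleotides are re-read from the genome rather than trusted
#' from the file.
#'
#' @param path GFF3 file.
#' @param genome genome sequences (named \code{DNAStringSet} or character).
#' @param min_intron inter-block genomic gaps at or above this size are
#'   recorded as introns.
#' @return a \linkS4class{SplicedAlignments} (mismatch/indel slots empty).
#' @export
importAlignments <- function(path, genome, min_intron = 20L) {
  seqs <- if (is(genome, "DNAStringSet")) {
    stats::setNames(as.character(genome), names(genome))
  } else genome
  gr <- tryCatch(rtracklayer::import(path),
                 error = function(e) stop("malformed GFF3 '", path, "': ",
                                          conditionMessage(e)))
  df <- as.data.frame(gr)
  parents <- df[df$type == "match", , drop = FALSE]
  parts <- df[df$type == "match_part", , drop = FALSE]
  getatt <- function(d, f, default = NA_character_) {
    if (f %in% names(d)) as.character(d[[f]]) else
      rep(default, nrow(d))
  }
  part_parent <- vapply(parts$Parent, function(p)
    if (length(p)) p[[1]] else NA_character_, "")
  alist <- list(); ids <- character(0); libs <- character(0)
  for (i in seq_len(nrow(parents))) {
    pid <- as.character(parents$ID[i])
    b <- parts[part_parent == pid, , drop = FALSE]
    b <- b[order(b$start), , drop = FALSE]
    if (nrow(b) == 0) stop("match feature without match_part children: ", pid)
    tgt <- do.call(rbind, strsplit(getatt(b, "Target"), " "))
    blocks <- data.frame(gstart = b$start, gend = b$end,
                         qstart = as.numeric(tgt[, 2]),
                         qend = as.numeric(tgt[, 3]))
    contig <- as.character(parents$seqnames[i])
    gseq <- seqs[[contig]]
    introns <- data.frame(start = numeric(0), end = numeric(0),
                          donor = character(0), acceptor = character(0),
                          length = numeric(0), stringsAsFactors = FALSE)
    if (nrow(blocks) > 1) {
      for (r in 2:nrow(blocks)) {
        gap <- blocks$gstart[r] - blocks$gend[r - 1] - 1
        if (gap >= min_intron) {
          s <- blocks$gend[r - 1] + 1; e <- blocks$gstart[r] - 1
          introns <- rbind(introns, data.frame(
            start = s, end = e, donor = substr(gseq, s, s + 1),
            acceptor = substr(gseq, e - 1, e), length = gap,
            stringsAsFactors = FALSE))
        }
      }
    }
    ident <- suppressWarnings(as.numeric(getatt(parents, "identity")[i]))
    covg <- suppressWarnings(as.numeric(getatt(parents, "coverage")[i]))
    score <- suppressWarnings(as.numeric(getatt(parents, "score.1",
                                                NA)[i]))
    if (is.na(score))
      score <- suppressWarnings(as.numeric(getatt(parents, "score", NA)[i]))
    alist[[length(alist) + 1]] <- list(
      contig = contig, blocks = as.matrix(blocks), introns = introns,
      mismatches = data.frame(qpos = numeric(0), gpos = numeric(0)),
      indels = data.frame(gpos = numeric(0), qpos = numeric(0),
                          length = numeric(0), type = character(0),
                          stringsAsFactors = FALSE),
      score = if (is.na(score)) 0 else score,
      identity = if (is.na(ident)) 1 else ident,
      coverage = if (is.na(covg)) 1 else covg,
      query_rc = getatt(parents, "query_rc", "0")[i] == "1")
    ids <- c(ids, getatt(parents, "est_id", NA)[i])
    libs <- c(libs, getatt(parents, "library", NA)[i])
  }
  if (!length(alist))
    return(new("SplicedAlignments", meta = data.frame(), blocks = list(),
               introns = list(), mismatches = list(), indels = list()))
  meta <- data.frame(
    est_id = ids, library = libs,
    contig = vapply(alist, `[[`, "", "contig"),
    query_rc = vapply(alist, `[[`, FALSE, "query_rc"),
    score = vapply(alist, `[[`, 0, "score"),
    identity = vapply(alist, `[[`, 0, "identity"),
    coverage = vapply(alist, `[[`, 0, "coverage"),
    n_introns = vapply(alist, function(a) nrow(a$introns), 0L),
    start = vapply(alist, function(a) a$blocks[1, "gstart"], 0),
    end = vapply(alist, function(a) a$blocks[nrow(a$blocks), "gend"], 0),
    stringsAsFactors = FALSE)
  new("SplicedAlignments", meta = meta,
      blocks = lapply(alist, function(a)
        as.data.frame(a$blocks)[, c("gstart", "gend", "qstart", "qend")]),
      introns = lapply(alist, `[[`, "introns"),
      mismatches = lapply(alist, `[[`, "mismatches"),
      indels = lapply(alist, `[[`, "indels"))
}
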