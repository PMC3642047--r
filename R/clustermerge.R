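# Genome-based cluster-and-merge: group alignments into loci, merge
# splice-compatible alignments into ESTTranscripts by deterministic greedy
# agglomeration to a fixpoint, house unspliced alignments, infer strand from
# the junction consensus, and group same-strand overlapping transcripts into
# ESTGenes.

# Light alignment structure used by the merge operations; tests may build
# these directly.
#' Convert alignments to plain structures for the merge operations
#'
#' @param alns a \linkS4class{SplicedAlignments}.
#' @return list of structures: \code{est_id}, \code{contig}, \code{start},
#'   \code{end}, \code{introns} (data.frame with \code{start}, \code{end},
#'   \code{donor}, \code{acceptor}), \code{exons} (2-column matrix).
#' @export
alignmentStructures <- function(alns, min_intron = 20L) {
  m <- alns@meta
  lapply(seq_len(nrow(m)), function(i) {
    b <- alns@blocks[[i]]
    it <- alns@introns[[i]]
    # exons = genome blocks, bridged across sub-intron gaps (indel splits)
    ex <- cbind(b$gstart, b$gend)
    if (nrow(ex) > 1) {
      out <- ex[1, , drop = FALSE]
      for (r in 2:nrow(ex)) {
        k <- nrow(out)
        if (ex[r, 1] - out[k, 2] - 1 < min_intron) {
          out[k, 2] <- max(out[k, 2], ex[r, 2])
        } else out <- rbind(out, ex[r, , drop = FALSE])
      }
      ex <- out
    }
    list(est_id = m$est_id[i], contig = m$contig[i],
         start = m$start[i], end = m$end[i],
         introns = it[, c("start", "end", "donor", "acceptor"), drop = FALSE],
         exons = unname(ex))
  })
}

#' Cluster alignments into genomically overlapping loci
#'
#' Two alignments share a cluster iff they are connected by a chain of
#' genomic-span overlaps on the same contig.
#'
#' @param structs list of alignment structures
#'   (\code{\link{alignmentStructures}}).
#' @return list of integer index vectors, one per cluster.
#' @export
clusterLoci <- function(structs) {
  if (!length(structs)) return(list())
  contig <- vapply(structs, `[[`, "", "contig")
  start <- vapply(structs, function(s) s$start, 0)
  end <- vapply(structs, function(s) s$end, 0)
  out <- list()
  for (cc in sort(unique(contig))) {
    sel <- which(contig == cc)
    comp <- .overlapComponents(start[sel], end[sel])
    for (k in sort(unique(comp))) out[[length(out) + 1]] <- sel[comp == k]
  }
  out
}

# Intron rows of `intr` intersecting the closed interval [lo, hi].
.intronsIn <- function(intr, lo, hi) {
  if (nrow(intr) == 0) return(intr)
  intr[intr$end >= lo & intr$start <= hi, , drop = FALSE]
}

#' Splice compatibility of two spliced alignments
#'
#' TRUE iff (i) at least one intron is identical in both (donor and acceptor
#' coordinates exactly equal) and (ii) over the genomic overlap of the two
#' alignments the intron sets are identical — no intron of one may intersect
#' an exon of the other, and no intron may be present in only one of them
#' within the shared region.  In particular, an alignment containing a
#' skipped exon that the other one retains is rejected.
#'
#' @param a,b alignment structures (see \code{\link{alignmentStructures}}),
#'   both spliced and on the same contig.
#' @return logical.
#' @export
spliceCompatible <- function(a, b) {
  if (nrow(a$introns) == 0 || nrow(b$introns) == 0)
    stop("spliceCompatible requires spliced alignments (use attachUnspliced)")
  if (a$contig != b$contig) return(FALSE)
  ka <- .key2(a$introns$start, a$introns$end)
  kb <- .key2(b$introns$start, b$introns$end)
  if (!length(intersect(ka, kb))) return(FALSE)
  lo <- max(a$start, b$start); hi <- min(a$end, b$end)
  if (lo > hi) return(FALSE)
  ia <- .intronsIn(a$introns, lo, hi)
  ib <- .intronsIn(b$introns, lo, hi)
  setequal(.key2(ia$start, ia$end), .key2(ib$start, ib$end))
}

# Transcript-level compatibility: candidate alignment vs merged structure.
.compatibleWithTranscript <- function(s, t) {
  if (s$contig != t$contig) return(FALSE)
  ks <- .key2(s$introns$start, s$introns$end)
  kt <- .key2(t$introns$start, t$introns$end)
  if (!length(intersect(ks, kt))) return(FALSE)
  lo <- max(s$start, t$start); hi <- min(s$end, t$end)
  if (lo > hi) return(FALSE)
  is <- .intronsIn(s$introns, lo, hi)
  it <- .intronsIn(t$introns, lo, hi)
  setequal(.key2(is$start, is$end), .key2(it$start, it$end))
}

.mergeIntrons <- function(a, b) {
  out <- rbind(a, b)
  out <- out[!duplicated(.key2(out$start, out$end)), , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

#' Merge one locus cluster into ESTTranscripts
#'
#' Spliced alignments are agglomerated greedily in a deterministic order
#' (descending intron count, then descending span width, then EST id): a
#' candidate joins the first growing transcript whose merged structure it is
#' compatible with, else founds a new one.  A final pairwise pass merges
#' transcripts until a fixpoint, so the output is pairwise non-mergeable and
#' invariant under permutations of the input.
#'
#' @param structs list of spliced alignment structures belonging to one
#'   cluster.
#' @return list of transcript structures: \code{contig}, \code{exons}
#'   (2-column matrix), \code{introns}, \code{support}, \code{start},
#'   \code{end}.
#' @export
mergeCluster <- function(structs) {
  if (!length(structs)) return(list())
  ni <- vapply(structs, function(s) nrow(s$introns), 0L)
  w <- vapply(structs, function(s) s$end - s$start + 1, 0)
  id <- vapply(structs, `[[`, "", "est_id")
  ord <- order(-ni, -w, id)
  trs <- list()
  for (i in ord) {
    s <- structs[[i]]
    placed <- FALSE
    for (k in seq_along(trs)) {
      if (.compatibleWithTranscript(s, trs[[k]])) {
        trs[[k]]$exons <- .unionIntervals(rbind(trs[[k]]$exons, s$exons))
        trs[[k]]$introns <- .mergeIntrons(trs[[k]]$introns, s$introns)
        trs[[k]]$support <- c(trs[[k]]$support, s$est_id)
        trs[[k]]$start <- min(trs[[k]]$start, s$start)
        trs[[k]]$end <- max(trs[[k]]$end, s$end)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      trs[[length(trs) + 1]] <- list(contig = s$contig, exons = s$exons,
                                     introns = s$introns,
                                     support = s$est_id,
                                     start = s$start, end = s$end)
    }
  }
  # fixpoint: merge transcripts pairwise until stable
  repeat {
    merged <- FALSE
    if (length(trs) > 1) {
      for (i in seq_len(length(trs) - 1)) {
        for (j in (i + 1):length(trs)) {
          if (.compatibleWithTranscript(trs[[j]], trs[[i]])) {
            trs[[i]]$exons <- .unionIntervals(rbind(trs[[i]]$exons,
                                                    trs[[j]]$exons))
            trs[[i]]$introns <- .mergeIntrons(trs[[i]]$introns,
                                              trs[[j]]$introns)
            trs[[i]]$support <- c(trs[[i]]$support, trs[[j]]$support)
            trs[[i]]$start <- min(trs[[i]]$start, trs[[j]]$start)
            trs[[i]]$end <- max(trs[[i]]$end, trs[[j]]$end)
            trs[[j]] <- NULL
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
    }
    if (!merged) break
  }
  trs
}

#' House unspliced alignments
#'
#' An unspliced alignment joins a spliced transcript iff its span lies within
#' one exon slot: inside an internal exon, or overlapping a terminal exon
#' without crossing the adjacent intron (terminal exons are extended
#' outward).  Leftovers are merged among themselves by overlap into
#' single-exon transcripts of unknown strand.
#'
#' @param transcripts transcript structures from \code{\link{mergeCluster}}
#'   (across all clusters).
#' @param structs unspliced alignment structures.
#' @return list with \code{transcripts} (updated; single-exon leftovers
#'   appended) and \code{absorbed} (logical per unspliced input).
#' @export
attachUnspliced <- function(transcripts, structs) {
  if (length(structs)) {
    w <- vapply(structs, function(s) s$end - s$start + 1, 0)
    id <- vapply(structs, `[[`, "", "est_id")
    ord <- order(-w, id)
  } else ord <- integer(0)
  # transcripts are scanned in a deterministic order too
  tord <- order(vapply(transcripts, `[[`, "", "contig"),
                vapply(transcripts, function(t) t$start, 0),
                vapply(transcripts, function(t) t$end, 0))
  absorbed <- rep(FALSE, length(structs))
  leftovers <- list()
  for (i in ord) {
    s <- structs[[i]]
    hit <- FALSE
    for (k in tord) {
      t <- transcripts[[k]]
      if (t$contig != s$contig) next
      if (nrow(t$introns) == 0) next
      if (.ovWidth(s$start, s$end, t$start, t$end) <= 0) next
      ib <- t$introns
      # exon slots: (-Inf, first intron), between introns, (last intron, Inf)
      slots_lo <- c(-Inf, ib$end + 1)
      slots_hi <- c(ib$start - 1, Inf)
      fit <- which(s$start >= slots_lo & s$end <= slots_hi)
      if (length(fit)) {
        transcripts[[k]]$exons <- .unionIntervals(
          rbind(t$exons, c(s$start, s$end)))
        transcripts[[k]]$support <- c(t$support, s$est_id)
        transcripts[[k]]$start <- min(t$start, s$start)
        transcripts[[k]]$end <- max(t$end, s$end)
        absorbed[i] <- TRUE
        hit <- TRUE
        break
      }
    }
    if (!hit) leftovers[[length(leftovers) + 1]] <- s
  }
  # leftovers merged by overlap into single-exon transcripts
  if (length(leftovers)) {
    contig <- vapply(leftovers, `[[`, "", "contig")
    for (cc in sort(unique(contig))) {
      sel <- which(contig == cc)
      st <- vapply(leftovers[sel], function(s) s$start, 0)
      en <- vapply(leftovers[sel], function(s) s$end, 0)
      comp <- .overlapComponents(st, en)
      for (k in sort(unique(comp))) {
        mem <- sel[comp == k]
        transcripts[[length(transcripts) + 1]] <- list(
          contig = cc,
          exons = matrix(c(min(st[comp == k]), max(en[comp == k])), 1),
          introns = data.frame(start = numeric(0), end = numeric(0),
                               donor = character(0), acceptor = character(0),
                               stringsAsFactors = FALSE),
          support = vapply(leftovers[mem], `[[`, "", "est_id"),
          start = min(st[comp == k]), end = max(en[comp == k]))
      }
    }
  }
  list(transcripts = transcripts, absorbed = absorbed)
}

#' Infer transcript strand from the junction consensus
#'
#' \code{+} when every intron matches a site pair from \code{sites} on the
#' forward genome strand, \code{-} when every intron matches on the reverse
#' strand, and \code{*} (unknown) otherwise — including the ambiguous case
#' where both orientations fit, and transcripts with no introns.  The
#' default consensus is the GT..AG pattern alone; the merge pipeline uses
#' the full canonical set so transcripts with a minor-site intron are not
#' orphaned from their locus.
#'
#' @param introns data.frame with \code{donor}, \code{acceptor} columns as
#'   read on the forward strand.
#' @param sites list of donor/acceptor pairs accepted as consensus.
#' @return \code{"+"}, \code{"-"} or \code{"*"}.
#' @export
inferStrand <- function(introns, sites = list(c("GT", "AG"))) {
  if (nrow(introns) == 0) return("*")
  fwd_pairs <- vapply(sites, function(s) .sitePair(s[1], s[2]), "")
  rev_pairs <- vapply(sites, function(s)
    .sitePair(.revcomp(s[2]), .revcomp(s[1])), "")
  p <- .sitePair(introns$donor, introns$acceptor)
  fwd <- all(p %in% fwd_pairs)
  rev <- all(p %in% rev_pairs)
  if (fwd && !rev) "+" else if (rev && !fwd) "-" else "*"
}

#' Group transcripts into ESTGenes
#'
#' Connected components of the same-strand genomic-overlap graph.
#' Unknown-strand transcripts group only among themselves and never bridge
#' the two strands.
#'
#' @param tset an \linkS4class{ESTTranscriptSet}.
#' @param prefix id prefix for the serial gene ids.
#' @return an \linkS4class{ESTGeneSet}.
#' @export
groupESTGenes <- function(tset, prefix = "ESTG") {
  m <- tset@meta
  genes <- list(); members <- list()
  for (cc in sort(unique(m$contig))) {
    for (sd in c("+", "-", "*")) {
      sel <- which(m$contig == cc & m$strand == sd)
      if (!length(sel)) next
      comp <- .overlapComponents(m$start[sel], m$end[sel])
      for (k in sort(unique(comp))) {
        mem <- sel[comp == k]
        genes[[length(genes) + 1]] <- data.frame(
          contig = cc, strand = sd,
          start = min(m$start[mem]), end = max(m$end[mem]),
          n_transcripts = length(mem), stringsAsFactors = FALSE)
        members[[length(members) + 1]] <- m$transcript_id[mem]
      }
    }
  }
  g <- if (length(genes)) do.call(rbind, genes) else
    data.frame(contig = character(0), strand = character(0),
               start = numeric(0), end = numeric(0),
               n_transcripts = integer(0), stringsAsFactors = FALSE)
  ord <- order(g$contig, g$start, g$end)
  g <- g[ord, , drop = FALSE]
  members <- members[ord]
  g <- cbind(data.frame(gene_id = sprintf("%s%05d", prefix, seq_len(nrow(g))),
                        stringsAsFactors = FALSE), g)
  rownames(g) <- NULL
  new("ESTGeneSet", meta = g, members = members, transcripts = tset)
}

# Wrap transcript structures into an ESTTranscriptSet with serial ids.
.asTranscriptSet <- function(trs, prefix = "ESTT",
                             strand_sites = list(c("GT", "AG"))) {
  if (!length(trs)) {
    return(new("ESTTranscriptSet",
               meta = data.frame(transcript_id = character(0),
                                 contig = character(0), strand = character(0),
                                 start = numeric(0), end = numeric(0),
                                 n_exons = integer(0), n_introns = integer(0),
                                 n_support = integer(0),
                                 stringsAsFactors = FALSE),
               exons = list(), introns = list(), support = list()))
  }
  ord <- order(vapply(trs, `[[`, "", "contig"),
               vapply(trs, function(t) t$start, 0),
               vapply(trs, function(t) t$end, 0),
               vapply(trs, function(t) paste(sort(t$support), collapse = ","),
                      ""))
  trs <- trs[ord]
  meta <- data.frame(
    transcript_id = sprintf("%s%05d", prefix, seq_along(trs)),
    contig = vapply(trs, `[[`, "", "contig"),
    strand = vapply(trs, function(t) inferStrand(t$introns, strand_sites),
                    ""),
    start = vapply(trs, function(t) t$start, 0),
    end = vapply(trs, function(t) t$end, 0),
    n_exons = vapply(trs, function(t) nrow(t$exons), 0L),
    n_introns = vapply(trs, function(t) nrow(t$introns), 0L),
    n_support = vapply(trs, function(t) length(t$support), 0L),
    stringsAsFactors = FALSE)
  new("ESTTranscriptSet", meta = meta,
      exons = lapply(trs, `[[`, "exons"),
      introns = lapply(trs, `[[`, "introns"),
      support = lapply(trs, function(t) sort(t$support)))
}

#' Run the full cluster-and-merge procedure
#'
#' Splits alignments into spliced and unspliced, clusters the spliced ones
#' into loci, merges each locus into non-redundant ESTTranscripts, houses the
#' unspliced alignments, infers strands from the junction consensus, and
#' groups same-strand overlapping transcripts into ESTGenes.
#'
#' @param alns a \linkS4class{SplicedAlignments} (after
#'   \code{\link{filterMapped}}).
#' @param attach_unspliced house unspliced alignments (default TRUE); when
#'   FALSE they are dropped.
#' @param strand_sites donor/acceptor pairs accepted by the strand consensus
#'   (default: the canonical GT:AG, GC:AG and AT:AC, so a transcript with a
#'   minor-site intron stays with its locus).
#' @param transcript_prefix,gene_prefix id prefixes.
#' @return list with \code{transcripts} (\linkS4class{ESTTranscriptSet}) and
#'   \code{genes} (\linkS4class{ESTGeneSet}).
#' @export
mergeAlignments <- function(alns, attach_unspliced = TRUE,
                            strand_sites = list(c("GT", "AG"), c("GC", "AG"),
                                                c("AT", "AC")),
                            transcript_prefix = "ESTT",
                            gene_prefix = "ESTG") {
  structs <- alignmentStructures(alns)
  ni <- vapply(structs, function(s) nrow(s$introns), 0L)
  spliced <- structs[ni > 0]
  unspliced <- structs[ni == 0]
  trs <- list()
  for (cl in clusterLoci(spliced))
    trs <- c(trs, mergeCluster(spliced[cl]))
  if (attach_unspliced) {
    trs <- attachUnspliced(trs, unspliced)$transcripts
  }
  tset <- .asTranscriptSet(trs, transcript_prefix, strand_sites)
  genes <- groupESTGenes(tset, gene_prefix)
  list(transcripts = tset, genes = genes)
}
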