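# Detection of alternative-splicing events among the transcripts of each
# ESTGene (cassette exons, consecutively skipped exon stretches, retained
# introns, alternative 5'/3' splice sites) and the reliability filters that
# replace manual curation: canonical splice sites, bounded indel runs, and
# exact-match flanks around each candidate region.

#' Reliability-filter specification
#'
#' @param sites canonical donor:acceptor pairs.  The default is
#'   \code{GT:AG, GC:AG, AT:AC}; \code{literal_minor_sites = TRUE} swaps in
#'   \code{CG:AG} for \code{GC:AG}.
#' @param literal_minor_sites see above.
#' @param max_indel_run indel runs outside introns must be strictly shorter
#'   than this many bases (default 9, exclusive bound).
#' @param min_flank_matches number of consecutive exactly matching aligned
#'   bases required immediately inside each boundary of a candidate region
#'   (default 3), in at least one supporting alignment per side.
#' @return validated \code{FilterSpec} list.
#' @export
filterSpec <- function(sites = c("GT:AG", "GC:AG", "AT:AC"),
                       literal_minor_sites = FALSE, max_indel_run = 9L,
                       min_flank_matches = 3L) {
  if (literal_minor_sites) sites <- c("GT:AG", "CG:AG", "AT:AC")
  stopifnot(length(sites) >= 1, max_indel_run >= 1)
  structure(list(sites = sites, max_indel_run = as.integer(max_indel_run),
                 min_flank_matches = as.integer(min_flank_matches)),
            class = "FilterSpec")
}

.emptyEvents <- function() {
  data.frame(event_id = character(0), gene_id = character(0),
             type = character(0), contig = character(0), start = numeric(0),
             end = numeric(0), exon_count = integer(0),
             inclusion_transcripts = character(0),
             exclusion_transcripts = character(0),
             canonical_sites = logical(0), indel_ok = logical(0),
             flank_matches = logical(0), reliable = logical(0),
             stringsAsFactors = FALSE)
}

# CE/CSE candidates of ordered pair (A includes, B skips).
.skippedExonEvents <- function(exA, inA, inB) {
  out <- NULL
  if (nrow(inA) < 2 || nrow(inB) < 1) return(out)
  for (j in seq_len(nrow(inB))) {
    up <- which(inA$start == inB$start[j])
    dn <- which(inA$end == inB$end[j])
    if (length(up) != 1 || length(dn) != 1 || dn <= up) next
    skipped <- exA[exA[, 1] >= inA$end[up] + 1 &
                     exA[, 2] <= inA$start[dn] - 1, , drop = FALSE]
    if (nrow(skipped) == 0) next
    out <- rbind(out, data.frame(
      type = if (nrow(skipped) == 1) "CE" else "CSE",
      start = skipped[1, 1], end = skipped[nrow(skipped), 2],
      exon_count = nrow(skipped), stringsAsFactors = FALSE))
  }
  out
}

#' Detect alternative-splicing events within ESTGenes
#'
#' For every transcript pair of a gene: a cassette exon (CE) or a stretch of
#' consecutively skipped exons (CSE) is called when one transcript's
#' consecutive internal exon block is absent from the other, which instead
#' carries a single intron whose donor equals the upstream flanking intron's
#' donor and whose acceptor equals the downstream flanking intron's acceptor;
#' a retained intron (RI) when one transcript's intron is fully covered by an
#' exon of the other, with both flanking exon boundaries inside that exon;
#' ALT5/ALT3 when two introns share exactly one splice site (labelled by the
#' gene strand: donor-side variation is ALT5).  Duplicate events (same type
#' and coordinates) are reported once per gene.
#'
#' @param genes an \linkS4class{ESTGeneSet}.
#' @return events data.frame with filter-flag columns initialized to
#'   \code{NA}; single-transcript genes yield no events.
#' @export
detectEvents <- function(genes) {
  tset <- genes@transcripts
  tm <- tset@meta
  rows <- list()
  gm <- genes@meta
  for (gi in seq_len(nrow(gm))) {
    mem <- match(genes@members[[gi]], tm$transcript_id)
    if (length(mem) < 2) next
    strand <- gm$strand[gi]
    seen <- character(0)
    recs <- list()
    add <- function(type, s, e, k, inc, exc) {
      key <- paste(type, s, e)
      if (key %in% names(recs)) {
        recs[[key]]$inc <<- union(recs[[key]]$inc, inc)
        recs[[key]]$exc <<- union(recs[[key]]$exc, exc)
      } else {
        recs[[key]] <<- list(type = type, s = s, e = e, k = k,
                             inc = inc, exc = exc)
      }
    }
    for (ai in mem) for (bi in mem) {
      if (ai == bi) next
      inA <- tset@introns[[ai]]
      inB <- tset@introns[[bi]]
      exA <- tset@exons[[ai]]
      exB <- tset@exons[[bi]]
      # CE / CSE: A includes the exon block, B skips it
      sk <- .skippedExonEvents(exA, inA, inB)
      for (r in seq_len(NROW(sk)))
        add(sk$type[r], sk$start[r], sk$end[r], sk$exon_count[r],
            tm$transcript_id[ai], tm$transcript_id[bi])
      # RI: intron of A covered by an exon of B
      for (j in seq_len(nrow(inA))) {
        cov <- exB[exB[, 1] <= inA$start[j] - 1 &
                     exB[, 2] >= inA$end[j] + 1, , drop = FALSE]
        if (nrow(cov))
          add("RI", inA$start[j], inA$end[j], 1L,
              tm$transcript_id[bi], tm$transcript_id[ai])
      }
      # ALT5 / ALT3: introns sharing exactly one splice site
      if (ai < bi) {
        for (j in seq_len(nrow(inA))) for (l in seq_len(nrow(inB))) {
          same_s <- inA$start[j] == inB$start[l]
          same_e <- inA$end[j] == inB$end[l]
          if (same_s == same_e) next
          # an intron that fully covers an exon of the other transcript is a
          # skipping event (CE/CSE), not an alternative splice site
          if (nrow(inA) && nrow(inB)) {
            lo <- c(inA$start[j], inB$start[l]); hi <- c(inA$end[j], inB$end[l])
            longer <- which.max(hi - lo)
            oth_ex <- if (longer == 1) exB else exA
            if (any(oth_ex[, 1] >= lo[longer] & oth_ex[, 2] <= hi[longer]))
              next
          }
          if (same_s) {
            s <- min(inA$end[j], inB$end[l]) + 1
            e <- max(inA$end[j], inB$end[l])
            type <- if (strand == "-") "ALT5" else "ALT3"
          } else {
            s <- min(inA$start[j], inB$start[l])
            e <- max(inA$start[j], inB$start[l]) - 1
            type <- if (strand == "-") "ALT3" else "ALT5"
          }
          add(type, s, e, 1L, tm$transcript_id[ai], tm$transcript_id[bi])
        }
      }
    }
    for (key in names(recs)) {
      r <- recs[[key]]
      rows[[length(rows) + 1]] <- data.frame(
        gene_id = gm$gene_id[gi], type = r$type, contig = gm$contig[gi],
        start = r$s, end = r$e, exon_count = as.integer(r$k),
        inclusion_transcripts = paste(sort(r$inc), collapse = ","),
        exclusion_transcripts = paste(sort(r$exc), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(.emptyEvents())
  ev <- do.call(rbind, rows)
  ev <- ev[order(ev$gene_id, ev$start, ev$type), , drop = FALSE]
  ev <- cbind(data.frame(event_id = sprintf("EVT%04d", seq_len(nrow(ev))),
                         stringsAsFactors = FALSE), ev)
  ev$canonical_sites <- NA
  ev$indel_ok <- NA
  ev$flank_matches <- NA
  ev$reliable <- NA
  rownames(ev) <- NULL
  ev
}

# Genome positions of one alignment that are aligned and exactly matching
# (inside a block, not a mismatch, not covered by a deletion).
.matchedAt <- function(alns, i, positions) {
  b <- alns@blocks[[i]]
  mm <- alns@mismatches[[i]]$gpos
  ind <- alns@indels[[i]]
  bad_g <- numeric(0)
  if (nrow(ind)) {
    del <- ind[ind$type == "del", , drop = FALSE]
    for (r in seq_len(nrow(del)))
      bad_g <- c(bad_g, del$gpos[r]:(del$gpos[r] + del$length[r] - 1))
  }
  vapply(positions, function(p) {
    inb <- any(b$gstart <= p & b$gend >= p)
    inb && !(p %in% mm) && !(p %in% bad_g)
  }, FALSE)
}

# Donor/acceptor pair of an intron as seen in the orientation of `strand`.
.orientedPair <- function(donor, acceptor, strand) {
  if (strand == "-") .sitePair(.revcomp(acceptor), .revcomp(donor))
  else .sitePair(donor, acceptor)
}

#' Apply the reliability filters to detected events
#'
#' For each event, over the supporting alignments (those of the inclusion
#' and exclusion transcripts): \code{canonical_sites} is TRUE iff every
#' intron of every supporting alignment belongs to the canonical site set
#' (read in the gene's orientation; for unknown-strand genes either
#' orientation may satisfy it); \code{indel_ok} iff every indel run outside
#' introns is strictly shorter than \code{max_indel_run} bases;
#' \code{flank_matches} iff at least \code{min_flank_matches} consecutive
#' exactly matching aligned bases lie immediately inside each boundary of the
#' candidate region in at least one supporting alignment per side.  An event
#' is \code{reliable} iff all three hold.
#'
#' @param events events from \code{\link{detectEvents}}.
#' @param genes the \linkS4class{ESTGeneSet} they came from.
#' @param alns the supporting \linkS4class{SplicedAlignments}.
#' @param spec a \code{\link{filterSpec}}.
#' @return the events with the flag columns filled.
#' @export
applyFilters <- function(events, genes, alns, spec = filterSpec()) {
  if (nrow(events) == 0) return(events)
  tset <- genes@transcripts
  tm <- tset@meta
  aid <- alns@meta$est_id
  gm <- genes@meta
  for (r in seq_len(nrow(events))) {
    tids <- unique(unlist(strsplit(c(events$inclusion_transcripts[r],
                                     events$exclusion_transcripts[r]), ",")))
    ests <- unique(unlist(tset@support[match(tids, tm$transcript_id)]))
    ai <- which(aid %in% ests)
    strand <- gm$strand[match(events$gene_id[r], gm$gene_id)]
    # canonical splice sites in every supporting alignment
    canon <- TRUE
    for (i in ai) {
      it <- alns@introns[[i]]
      if (nrow(it) == 0) next
      if (strand == "*") {
        p1 <- vapply(seq_len(nrow(it)), function(j)
          .orientedPair(it$donor[j], it$acceptor[j], "+"), "")
        p2 <- vapply(seq_len(nrow(it)), function(j)
          .orientedPair(it$donor[j], it$acceptor[j], "-"), "")
        if (!(all(p1 %in% spec$sites) || all(p2 %in% spec$sites))) {
          canon <- FALSE; break
        }
      } else {
        p <- vapply(seq_len(nrow(it)), function(j)
          .orientedPair(it$donor[j], it$acceptor[j], strand), "")
        if (!all(p %in% spec$sites)) { canon <- FALSE; break }
      }
    }
    # indel runs outside introns strictly shorter than the bound
    indel_ok <- TRUE
    for (i in ai) {
      ind <- alns@indels[[i]]
      if (nrow(ind) && any(ind$length >= spec$max_indel_run)) {
        indel_ok <- FALSE; break
      }
    }
    # exact-match flanks immediately inside each boundary
    s <- events$start[r]; e <- events$end[r]
    fl <- spec$min_flank_matches
    left_ok <- FALSE; right_ok <- FALSE
    for (i in ai) {
      if (!left_ok && all(.matchedAt(alns, i, s:(s + fl - 1))))
        left_ok <- TRUE
      if (!right_ok && all(.matchedAt(alns, i, (e - fl + 1):e)))
        right_ok <- TRUE
      if (left_ok && right_ok) break
    }
    events$canonical_sites[r] <- canon
    events$indel_ok[r] <- indel_ok
    events$flank_matches[r] <- left_ok && right_ok
  }
  events$reliable <- events$canonical_sites & events$indel_ok &
    events$flank_matches
  events
}

#' Count events at gene or exon level
#'
#' At gene level, the number of distinct genes with at least one event of the
#' type; at exon level, the number of affected exons (a CSE stretch of k
#' exons contributes k; an RI contributes its one retained-intron exon).
#'
#' @param events events (typically filtered to \code{reliable}).
#' @param level \code{"gene"} or \code{"exon"}.
#' @return named integer vector over the event types present.
#' @export
countEvents <- function(events, level = c("gene", "exon")) {
  level <- match.arg(level)
  types <- c("CE", "CSE", "RI", "ALT5", "ALT3")
  out <- stats::setNames(integer(length(types)), types)
  for (ty in types) {
    sel <- events[events$type == ty, , drop = FALSE]
    out[ty] <- if (level == "gene") length(unique(sel$gene_id))
    else sum(sel$exon_count)
  }
  out
}
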