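#' @import methods
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#'   pairwiseAlignment matchPattern reverseComplement
#' @importFrom S4Vectors metadata
NULL

#' Set of EST-to-genome spliced alignments
#'
#' Container for the placements of ESTs on genome contigs.  Each alignment is
#' an ordered run of aligned blocks (genome interval, query interval, both
#' 1-based inclusive); the gaps between consecutive genome blocks are the
#' candidate introns, annotated with their donor and acceptor dinucleotides as
#' read on the forward genome strand.  Per-alignment mismatch and indel
#' records support the downstream reliability filters for splice events.
#'
#' @slot meta \code{data.frame} with one row per alignment: \code{est_id},
#'   \code{library}, \code{contig}, \code{query_rc} (was the reverse
#'   complement of the read aligned), \code{score}, \code{identity} (matching
#'   fraction of aligned columns, gaps included), \code{coverage} (aligned
#'   query bases / query length), \code{n_introns}, \code{start}, \code{end}
#'   (genomic span).
#' @slot blocks list of \code{data.frame}s (\code{gstart}, \code{gend},
#'   \code{qstart}, \code{qend}).
#' @slot introns list of \code{data.frame}s (\code{start}, \code{end},
#'   \code{donor}, \code{acceptor}, \code{length}).
#' @slot mismatches list of \code{data.frame}s (\code{qpos}, \code{gpos}).
#' @slot indels list of \code{data.frame}s (\code{gpos}, \code{qpos},
#'   \code{length}, \code{type}) for indel runs outside introns.
#' @export
setClass("SplicedAlignments",
  representation(meta = "data.frame", blocks = "list", introns = "list",
                 mismatches = "list", indels = "list"),
  validity = function(object) {
    n <- nrow(object@meta)
    if (length(object@blocks) != n || length(object@introns) != n ||
        length(object@mismatches) != n || length(object@indels) != n)
      return("slot lengths disagree with number of alignments")
    for (i in seq_len(n)) {
      b <- object@blocks[[i]]
      if (nrow(b) > 1) {
        if (any(diff(b$gstart) <= 0) || any(diff(b$qstart) <= 0))
          return(sprintf("alignment %d: blocks not strictly increasing", i))
      }
      # inter-block gaps are introns or recorded indel runs
      if (nrow(object@introns[[i]]) > max(0, nrow(b) - 1))
        return(sprintf("alignment %d: more introns than block gaps", i))
    }
    if (n) {
      ok <- with(object@meta, identity >= 0 & identity <= 1 &
                   coverage >= 0 & coverage <= 1)
      if (!all(ok)) return("identity/coverage outside [0,1]")
    }
    TRUE
  })

#' Non-redundant merged splice structures (ESTTranscripts)
#'
#' ESTTranscripts are expressed contigs obtained by merging EST-genome
#' alignments that share compatible splicing structures.  Exons are the union
#' of the member alignments' blocks, introns the union of their junction
#' calls, and every supporting EST is recorded.
#'
#' @slot meta \code{data.frame}: \code{transcript_id}, \code{contig},
#'   \code{strand} (\code{+}, \code{-} or \code{*} for unknown),
#'   \code{start}, \code{end}, \code{n_exons}, \code{n_introns},
#'   \code{n_support}.
#' @slot exons list of 2-column matrices (start, end).
#' @slot introns list of \code{data.frame}s (\code{start}, \code{end},
#'   \code{donor}, \code{acceptor}).
#' @slot support list of character vectors of supporting EST ids.
#' @export
setClass("ESTTranscriptSet",
  representation(meta = "data.frame", exons = "list", introns = "list",
                 support = "list"),
  validity = function(object) {
    n <- nrow(object@meta)
    if (length(object@exons) != n || length(object@introns) != n ||
        length(object@support) != n)
      return("slot lengths disagree")
    for (i in seq_len(n)) {
      ex <- object@exons[[i]]
      if (nrow(ex) > 1 && any(ex[-1, 1] <= ex[-nrow(ex), 2]))
        return(sprintf("transcript %d: exons overlap or are unsorted", i))
      if (length(object@support[[i]]) == 0)
        return(sprintf("transcript %d: empty support set", i))
    }
    TRUE
  })

#' Groups of overlapping same-strand ESTTranscripts (ESTGenes)
#'
#' An ESTGene is a connected group of genomically overlapping ESTTranscripts
#' on the same strand of one locus, regardless of whether the members share a
#' splicing structure.  The span is the hull of the member exons.
#'
#' @slot meta \code{data.frame}: \code{gene_id}, \code{contig},
#'   \code{strand}, \code{start}, \code{end}, \code{n_transcripts}.
#' @slot members list of character vectors of member transcript ids.
#' @slot transcripts the underlying \linkS4class{ESTTranscriptSet}.
#' @export
setClass("ESTGeneSet",
  representation(meta = "data.frame", members = "list",
                 transcripts = "ESTTranscriptSet"),
  validity = function(object) {
    if (nrow(object@meta) != length(object@members))
      return("one member list per gene required")
    TRUE
  })

#' Simulated genome with planted transcript structures and truth registries
#'
#' Produced by \code{\link{simulateGenome}}.  Holds the contig sequences, the
#' planted gene/isoform/exon models, and machine-readable registries of the
#' planted alternative-splicing events, antisense pairs and over-represented
#' genes, so recovery of every analysis stage can be measured.
#'
#' @slot contigs \code{DNAStringSet} of contig sequences.
#' @slot genes \code{data.frame}: \code{gene_id}, \code{contig},
#'   \code{strand}, \code{start}, \code{end}, \code{cds_start},
#'   \code{cds_end}, \code{n_exons}, \code{base_weight}.
#' @slot isoforms \code{data.frame}: \code{isoform_id}, \code{gene_id},
#'   \code{role}.
#' @slot exons \code{data.frame}: \code{isoform_id}, \code{gene_id},
#'   \code{rank}, \code{start}, \code{end}.
#' @slot events planted splice-event registry.
#' @slot antisense planted antisense-pair registry.
#' @slot overrep planted over-representation registry.
#' @slot config the \code{\link{simConfig}} used.
#' @export
setClass("GenomeTruth",
  representation(contigs = "ANY", genes = "data.frame",
                 isoforms = "data.frame", exons = "data.frame",
                 events = "data.frame", antisense = "data.frame",
                 overrep = "data.frame", config = "list"))

# ---- accessors -------------------------------------------------------------

#' @describeIn SplicedAlignments number of alignments
#' @param x object
#' @export
setMethod("length", "SplicedAlignments", function(x) nrow(x@meta))

#' Accessors for SplicedAlignments
#'
#' @param x a \linkS4class{SplicedAlignments}
#' @return \code{alignmentMeta}: the per-alignment metadata frame;
#'   \code{alignmentBlocks}, \code{alignmentIntrons},
#'   \code{alignmentMismatches}, \code{alignmentIndels}: per-alignment lists.
#' @export
alignmentMeta <- function(x) x@meta

#' @rdname alignmentMeta
#' @export
alignmentBlocks <- function(x) x@blocks

#' @rdname alignmentMeta
#' @export
alignmentIntrons <- function(x) x@introns

#' @rdname alignmentMeta
#' @export
alignmentMismatches <- function(x) x@mismatches

#' @rdname alignmentMeta
#' @export
alignmentIndels <- function(x) x@indels

#' @export
setMethod("[", "SplicedAlignments", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, x@meta$est_id)
  if (is.logical(i)) i <- which(i)
  new("SplicedAlignments",
      meta = x@meta[i, , drop = FALSE],
      blocks = x@blocks[i], introns = x@introns[i],
      mismatches = x@mismatches[i], indels = x@indels[i])
})

setMethod("show", "SplicedAlignments", function(object) {
  n <- length(object)
  cat(sprintf("SplicedAlignments with %d alignment%s\n", n,
              if (n == 1) "" else "s"))
  if (n) {
    cat(sprintf("  spliced: %d | median identity: %.3f | median coverage: %.3f\n",
                sum(object@meta$n_introns > 0),
                stats::median(object@meta$identity),
                stats::median(object@meta$coverage)))
  }
})

#' Accessors for ESTTranscriptSet
#'
#' @param x an \linkS4class{ESTTranscriptSet}
#' @export
transcriptMeta <- function(x) x@meta

#' @rdname transcriptMeta
#' @export
transcriptExons <- function(x) x@exons

#' @rdname transcriptMeta
#' @export
transcriptIntrons <- function(x) x@introns

#' @rdname transcriptMeta
#' @export
transcriptSupport <- function(x) x@support

#' @export
setMethod("length", "ESTTranscriptSet", function(x) nrow(x@meta))

#' @export
setMethod("[", "ESTTranscriptSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, x@meta$transcript_id)
  if (is.logical(i)) i <- which(i)
  new("ESTTranscriptSet", meta = x@meta[i, , drop = FALSE],
      exons = x@exons[i], introns = x@introns[i], support = x@support[i])
})

setMethod("show", "ESTTranscriptSet", function(object) {
  cat(sprintf("ESTTranscriptSet with %d transcripts (%d spliced)\n",
              length(object), sum(object@meta$n_introns > 0)))
})

#' Accessors for ESTGeneSet
#'
#' @param x an \linkS4class{ESTGeneSet}
#' @export
geneMeta <- function(x) x@meta

#' @rdname geneMeta
#' @export
geneMembers <- function(x) x@members

#' @rdname geneMeta
#' @export
geneTranscripts <- function(x) x@transcripts

#' @export
setMethod("length", "ESTGeneSet", function(x) nrow(x@meta))

setMethod("show", "ESTGeneSet", function(object) {
  s <- table(factor(object@meta$strand, levels = c("+", "-", "*")))
  cat(sprintf("ESTGeneSet with %d genes (+: %d, -: %d, unknown: %d)\n",
              length(object), s[["+"]], s[["-"]], s[["*"]]))
})

#' Accessors for GenomeTruth
#'
#' @param x a \linkS4class{GenomeTruth}
#' @export
truthContigs <- function(x) x@contigs

#' @rdname truthContigs
#' @export
truthGenes <- function(x) x@genes

#' @rdname truthContigs
#' @export
truthIsoforms <- function(x) x@isoforms

#' @rdname truthContigs
#' @export
truthExons <- function(x) x@exons

#' @rdname truthContigs
#' @export
plantedEvents <- function(x) x@events

#' @rdname truthContigs
#' @export
plantedAntisense <- function(x) x@antisense

#' @rdname truthContigs
#' @export
plantedOverrep <- function(x) x@overrep

setMethod("show", "GenomeTruth", function(object) {
  cat(sprintf(
    "GenomeTruth: %d contig(s), %d genes, %d isoforms, %d planted events, %d antisense pairs\n",
    length(object@contigs), nrow(object@genes), nrow(object@isoforms),
    nrow(object@events), nrow(object@antisense)))
})
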