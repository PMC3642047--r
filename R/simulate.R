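# Simulation of a toy genome with planted transcript structures and of
# per-library EST reads with the statistical features the downstream analysis
# assumes (non-normalized abundance skew, 3'-biased fragments, polyA tails,
# vector remnants, contaminants), plus machine-readable truth.

#' Library specification table in the proportions of the mycelium study
#'
#' Five non-normalized cDNA libraries: 5-, 14-, 18- and 30-day dikaryotic
#' mycelium plus an 18-day monokaryotic one, with EST targets proportional to
#' 1,001 : 6,848 : 21,547 : 11,059 : 6,830 and scaled by \code{scale}.
#'
#' @param scale multiplier applied to the full library sizes before rounding.
#' @return \code{data.frame} with columns \code{name}, \code{day},
#'   \code{karyotype}, \code{target}.
#' @export
table1Libraries <- function(scale = 0.1) {
  full <- c(1001, 6848, 21547, 11059, 6830)
  data.frame(
    name = c("5D_36123", "14D_36123", "18D_36123", "18D_37180", "30D_36123"),
    day = c(5L, 14L, 18L, 18L, 30L),
    karyotype = c("dikaryon", "dikaryon", "dikaryon", "monokaryon", "dikaryon"),
    target = as.integer(round(full * scale)),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' All tunables of the genome/read simulator.  Defaults emulate the study
#' conditions: intron lengths log-normal with median 280 bases bounded to
#' [24, 2000]; EST lengths matching the reported quantiles (min 50, Q1 593,
#' median 729, Q3 793, max 949); five libraries in the published size
#' proportions; mostly GT-AG introns with a small minor-site fraction; a
#' log-normal expression skew so raw EST counts are a semi-quantitative
#' abundance proxy; and planted cassette exons, skipped-exon stretches,
#' retained introns, alternative splice sites, antisense pairs and
#' over-represented genes.
#'
#' @param seed integer master seed; identical configurations (including the
#'   seed) give byte-identical outputs.
#' @param n_contigs,contig_length genome shape.
#' @param n_genes number of genes to place.
#' @param n_exons_range inclusive range of exon counts per gene.
#' @param exon_length,intron_length log-normal parameter lists
#'   (\code{meanlog}, \code{sdlog}, \code{min}, \code{max}).
#' @param minor_splice_fraction probability that an intron uses a minor
#'   donor/acceptor pair from \code{minor_sites}.
#' @param minor_sites list of length-2 character vectors (donor, acceptor).
#'   The default uses GC:AG and AT:AC; \code{literal_minor_sites = TRUE}
#'   swaps in CG:AG for GC:AG.
#' @param literal_minor_sites use the literal minor-site listing (see
#'   Details in the package vignette).
#' @param isoform_rates per-gene probabilities of planting one event of each
#'   type (\code{p_CE}, \code{p_CSE}, \code{p_RI}, \code{p_ALT5},
#'   \code{p_ALT3}); at most one event is planted per gene.
#' @param cse_len_range inclusive range for the length of a planted stretch
#'   of consecutively skipped exons.
#' @param antisense_pair_rate probability that a placement event plants an
#'   overlapping antisense pair instead of a single gene.
#' @param orientation_mix named probabilities for convergent / divergent /
#'   contained pair arrangements.
#' @param p_pure_3utr probability that a convergent pair overlaps only in
#'   both genes' 3' UTRs.
#' @param libraries a library table as from \code{\link{table1Libraries}}.
#' @param read_length empirical quantile spec (\code{q} knots, \code{p}
#'   probabilities).
#' @param three_prime list(\code{p_at_end}, \code{geom_p}): probability the
#'   cDNA insert reaches the transcript 3' end intact (oligo-dT priming) and
#'   the geometric decay of the 5' truncation otherwise.
#' @param read_five_prime_prob probability a clone is sequenced from its 5'
#'   end (reading the insert 5' prefix) rather than its 3' end (the suffix).
#' @param error_rates substitution / insertion / deletion probabilities per
#'   base.
#' @param quality list(\code{baseline}, \code{bad_end_rate},
#'   \code{bad_end_len}, \code{bad_end_err}): per-base error-probability
#'   model, including occasional low-quality read ends.
#' @param polya list(\code{rate}, \code{meanlog}, \code{sdlog}, \code{max})
#'   for appended polyA tails on fragments reaching the transcript 3' end.
#' @param vector_seq,adaptor_seqs cloning vector/adaptor remnants; a remnant
#'   is prepended to the 5' end of a read with probability
#'   \code{vector_rate}.
#' @param vector_rate see above.
#' @param contamination_fraction probability that a read is a contaminant.
#' @param contaminant_seqs named character vector of foreign sequences;
#'   \code{NULL} generates two fixed pseudo-random foreign sequences from the
#'   seed.
#' @param expression list(\code{sdlog}, \code{sdlog_library}): gene abundance
#'   skew and per-library jitter.
#' @param n_overrep_genes,overrep_fold,overrep_library planted stage-specific
#'   over-representation (fold change in one library).
#' @param n_strain_genes,strain_fold planted dikaryon-over-monokaryon skew
#'   (monokaryon weight divided by \code{strain_fold}).
#' @return object of class \code{SimConfig} (a validated list).
#' @export
simConfig <- function(seed = 1L,
                      n_contigs = 4L,
                      contig_length = 65000L,
                      n_genes = 100L,
                      n_exons_range = c(2L, 6L),
                      exon_length = list(meanlog = log(150), sdlog = 0.35,
                                         min = 40, max = 500),
                      intron_length = list(meanlog = log(280), sdlog = 0.45,
                                           min = 24, max = 2000),
                      minor_splice_fraction = 0.02,
                      minor_sites = NULL,
                      literal_minor_sites = FALSE,
                      isoform_rates = list(p_CE = 0.10, p_CSE = 0.05,
                                           p_RI = 0.20, p_ALT5 = 0.05,
                                           p_ALT3 = 0.05),
                      cse_len_range = c(2L, 4L),
                      antisense_pair_rate = 0.08,
                      orientation_mix = c(convergent = 0.6, divergent = 0.15,
                                          contained = 0.25),
                      p_pure_3utr = 0.6,
                      libraries = table1Libraries(0.1),
                      read_length = list(q = c(50, 593, 729, 793, 949),
                                         p = c(0, 0.25, 0.5, 0.75, 1)),
                      three_prime = list(p_at_end = 0.7, geom_p = 0.01),
                      read_five_prime_prob = 0.5,
                      error_rates = list(sub = 0, ins = 0, del = 0),
                      quality = list(baseline = 0.001, bad_end_rate = 0,
                                     bad_end_len = c(5, 40),
                                     bad_end_err = c(0.05, 0.4)),
                      polya = list(rate = 0, meanlog = log(15), sdlog = 0.4,
                                   max = 40),
                      vector_seq = "AATTCGGCACGAGGTTCGCAACCGTCAGATCGGAAGAGCG",
                      adaptor_seqs = character(0),
                      vector_rate = 0,
                      contamination_fraction = 0,
                      contaminant_seqs = NULL,
                      expression = list(sdlog = 1.0, sdlog_library = 0.2),
                      n_overrep_genes = 4L,
                      overrep_fold = 8,
                      overrep_library = "18D_36123",
                      n_strain_genes = 2L,
                      strain_fold = 8) {
  if (is.null(minor_sites)) {
    minor_sites <- if (literal_minor_sites) {
      list(c("CG", "AG"), c("AT", "AC"))
    } else {
      list(c("GC", "AG"), c("AT", "AC"))
    }
  }
  cfg <- list(seed = as.integer(seed), n_contigs = as.integer(n_contigs),
              contig_length = as.integer(contig_length),
              n_genes = as.integer(n_genes),
              n_exons_range = as.integer(n_exons_range),
              exon_length = exon_length, intron_length = intron_length,
              minor_splice_fraction = minor_splice_fraction,
              minor_sites = minor_sites,
              isoform_rates = isoform_rates,
              cse_len_range = as.integer(cse_len_range),
              antisense_pair_rate = antisense_pair_rate,
              orientation_mix = orientation_mix,
              p_pure_3utr = p_pure_3utr,
              libraries = libraries, read_length = read_length,
              three_prime = three_prime,
              read_five_prime_prob = read_five_prime_prob,
              error_rates = error_rates,
              quality = quality, polya = polya,
              vector_seq = vector_seq, adaptor_seqs = adaptor_seqs,
              vector_rate = vector_rate,
              contamination_fraction = contamination_fraction,
              contaminant_seqs = contaminant_seqs,
              expression = expression,
              n_overrep_genes = as.integer(n_overrep_genes),
              overrep_fold = overrep_fold,
              overrep_library = overrep_library,
              n_strain_genes = as.integer(n_strain_genes),
              strain_fold = strain_fold)
  probs <- c(minor_splice_fraction, unlist(isoform_rates),
             antisense_pair_rate, p_pure_3utr, vector_rate,
             contamination_fraction, polya$rate, quality$bad_end_rate,
             unlist(error_rates))
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0,1]")
  if (intron_length$min < 24)
    stop("intron minimum must be at least 24 bases")
  if (any(libraries$target < 0)) stop("library EST targets must be >= 0")
  if (sum(unlist(isoform_rates)) > 1)
    stop("isoform event rates must sum to at most 1")
  if (is.null(cfg$contaminant_seqs)) {
    # fixed foreign sequences derived from the seed, outside the main stream
    old <- .Random.seed_exists()
    set.seed(cfg$seed + 7777L)
    cfg$contaminant_seqs <- c(contamA = .randSeq(1500), contamB = .randSeq(1500))
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  class(cfg) <- "SimConfig"
  cfg
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

# Clipped log-normal draws.
.rclnorm <- function(n, p) {
  pmin(pmax(round(stats::rlnorm(n, p$meanlog, p$sdlog)), p$min), p$max)
}

# Plan one gene starting at `start` (genomic, 1-based). Splice-site classes
# are assigned per intron; dinucleotides are written into the contig later.
.planGene <- function(start, strand, cfg, force_canonical = FALSE,
                      n_exons = NULL, first_exon_min = 0, last_exon_min = 0,
                      force_long_intron = 0) {
  if (is.null(n_exons))
    n_exons <- .sample1(seq(cfg$n_exons_range[1], cfg$n_exons_range[2]))
  ex_w <- .rclnorm(n_exons, cfg$exon_length)
  if (first_exon_min > 0) ex_w[1] <- max(ex_w[1], first_exon_min)
  if (last_exon_min > 0) ex_w[n_exons] <- max(ex_w[n_exons], last_exon_min)
  in_w <- if (n_exons > 1) .rclnorm(n_exons - 1, cfg$intron_length) else integer(0)
  long_intron <- NA_integer_
  if (force_long_intron > 0 && n_exons > 1) {
    long_intron <- ceiling((n_exons - 1) / 2)
    in_w[long_intron] <- force_long_intron
  }
  ex <- matrix(0, n_exons, 2)
  pos <- start
  for (i in seq_len(n_exons)) {
    ex[i, ] <- c(pos, pos + ex_w[i] - 1)
    pos <- ex[i, 2] + 1 + if (i < n_exons) in_w[i] else 0
  }
  sites <- replicate(max(0, n_exons - 1), {
    if (!force_canonical && stats::runif(1) < cfg$minor_splice_fraction) {
      cfg$minor_sites[[sample(length(cfg$minor_sites), 1)]]
    } else c("GT", "AG")
  }, simplify = FALSE)
  list(strand = strand, exons = ex, sites = sites, end = ex[n_exons, 2],
       long_intron = long_intron)
}

# Introns (as seen on the forward genome) between consecutive exon rows.
.gapIntrons <- function(ex) {
  if (nrow(ex) < 2) return(matrix(numeric(0), ncol = 2))
  cbind(ex[-nrow(ex), 2] + 1, ex[-1, 1] - 1)
}

# Plant at most one alternative-splicing event in a gene plan; returns NULL
# or list(type, alt_exons, ev_start, ev_end, exon_count, extra_sites).
.planEvent <- function(plan, cfg) {
  r <- cfg$isoform_rates
  u <- stats::runif(1)
  cum <- cumsum(c(r$p_CE, r$p_CSE, r$p_RI, r$p_ALT5, r$p_ALT3))
  type <- c("CE", "CSE", "RI", "ALT5", "ALT3")[match(TRUE, u < cum)]
  if (is.na(type)) return(NULL)
  ex <- plan$exons
  n <- nrow(ex)
  # the skip junction joins the upstream intron's donor to the downstream
  # intron's acceptor, so both flanking introns must be canonical — mixed
  # classes would fabricate a chimeric U2/U12 junction
  canon <- vapply(plan$sites, identical, TRUE, y = c("GT", "AG"))
  if (type == "CE" && n >= 3) {
    i <- if (n == 3) 2L else sample(2:(n - 1), 1)
    if (!canon[i - 1] || !canon[i]) return(NULL)
    alt <- ex[-i, , drop = FALSE]
    return(list(type = "CE", alt_exons = alt, ev_start = ex[i, 1],
                ev_end = ex[i, 2], exon_count = 1L, extra_sites = NULL))
  }
  if (type == "CSE") {
    kmax <- min(cfg$cse_len_range[2], n - 2)
    if (kmax >= max(2, cfg$cse_len_range[1])) {
      k <- .sample1(seq(cfg$cse_len_range[1], kmax))
      i <- if (n - k - 1 < 2) 2L else sample(2:(n - k), 1)
      if (!canon[i - 1] || !canon[i + k - 1]) return(NULL)
      alt <- ex[-(i:(i + k - 1)), , drop = FALSE]
      return(list(type = "CSE", alt_exons = alt, ev_start = ex[i, 1],
                  ev_end = ex[i + k - 1, 2], exon_count = as.integer(k),
                  extra_sites = NULL))
    }
  }
  # retained introns are planted only in genes with >= 2 introns so the
  # retaining isoform remains spliced (junction-confirmed) and mergeable
  if (type == "RI" && n >= 3) {
    j <- sample(n - 1, 1)
    alt <- ex
    alt[j, 2] <- alt[j + 1, 2]
    alt <- alt[-(j + 1), , drop = FALSE]
    return(list(type = "RI", alt_exons = alt, ev_start = ex[j, 2] + 1,
                ev_end = ex[j + 1, 1] - 1, exon_count = 1L,
                extra_sites = NULL))
  }
  if (type %in% c("ALT5", "ALT3") && n >= 2) {
    j <- sample(n - 1, 1)
    # alternative sites are only planted on canonical introns so the shifted
    # boundary dinucleotide is unambiguous
    if (!identical(plan$sites[[j]], c("GT", "AG"))) return(NULL)
    istart <- ex[j, 2] + 1
    iend <- ex[j + 1, 1] - 1
    ilen <- iend - istart + 1
    dmax <- ilen - cfg$intron_length$min
    if (dmax >= 6) {
      d <- .sample1(6:min(15, dmax))
      # donor-side variation (ALT5) shifts the intron boundary at the donor
      # end; acceptor-side (ALT3) at the acceptor end.  The donor end is the
      # genomic start on '+' and the genomic end on '-'.
      shift_start <- (type == "ALT5") == (plan$strand == "+")
      alt <- ex
      if (shift_start) {
        alt[j, 2] <- ex[j, 2] + d          # exon j extended; intron start + d
        extra <- list(list(pos = istart + d, which = "start",
                           site = plan$sites[[j]]))
        evs <- istart; eve <- istart + d - 1
      } else {
        alt[j + 1, 1] <- ex[j + 1, 1] - d  # exon j+1 extended; intron end - d
        # the shifted acceptor dinucleotide occupies (end-1, end)
        extra <- list(list(pos = iend - d - 1, which = "end",
                           site = plan$sites[[j]]))
        evs <- iend - d + 1; eve <- iend
      }
      return(list(type = type, alt_exons = alt, ev_start = evs, ev_end = eve,
                  exon_count = 1L, extra_sites = extra, alt_intron_j = j))
    }
  }
  NULL
}

#' Generate a toy genome with planted transcript structures
#'
#' Places genes with log-normal exon and intron lengths on random contigs,
#' plants one alternative-splicing event in a configurable fraction of genes
#' (cassette exon, consecutively-skipped-exon stretch, retained intron, or an
#' alternative 5'/3' splice site), plants overlapping antisense gene pairs in
#' convergent / divergent / contained arrangements, writes the donor and
#' acceptor dinucleotides of every planted intron into the contig sequence,
#' and records everything in truth registries.
#'
#' @param config a \code{\link{simConfig}}.
#' @return a \linkS4class{GenomeTruth}.
#' @examples
#' truth <- simulateGenome(simConfig(seed = 7, n_genes = 10,
#'                                   contig_length = 12000, n_contigs = 1))
#' truth
#' @export
simulateGenome <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(config$seed)
  cfg <- config
  contig_ids <- sprintf("contig%02d", seq_len(cfg$n_contigs))

  genes <- list(); isoforms <- list(); exons <- list()
  events <- list(); anti <- list()
  gene_n <- 0L; ev_n <- 0L; pair_n <- 0L
  writes <- list()   # splice-site dinucleotide writes: contig, pos, chars

  addSiteWrites <- function(contig, ex, sites, strand) {
    # record donor/acceptor dinucleotide writes for the gap introns of `ex`
    gaps <- .gapIntrons(ex)
    out <- list()
    for (j in seq_len(nrow(gaps))) {
      s <- gaps[j, 1]; e <- gaps[j, 2]
      donor <- sites[[j]][1]; acc <- sites[[j]][2]
      if (strand == "+") {
        out[[length(out) + 1]] <- list(contig = contig, pos = s, chars = donor)
        out[[length(out) + 1]] <- list(contig = contig, pos = e - 1, chars = acc)
      } else {
        out[[length(out) + 1]] <- list(contig = contig, pos = s,
                                       chars = .revcomp(acc))
        out[[length(out) + 1]] <- list(contig = contig, pos = e - 1,
                                       chars = .revcomp(donor))
      }
    }
    out
  }

  # site list for an exon chain derived from the primary chain: look up the
  # class of each gap intron by its boundary positions in the primary plan.
  # On '-' genes the genomic start of an intron carries the acceptor and the
  # genomic end the donor, so the lookup is strand-aware.
  .sitesFor <- function(plan, ex) {
    gaps <- .gapIntrons(ex)
    prim <- .gapIntrons(plan$exons)
    lapply(seq_len(nrow(gaps)), function(j) {
      s <- gaps[j, 1]; e <- gaps[j, 2]
      donor <- NULL; acc <- NULL
      for (k in seq_len(nrow(prim))) {
        if (prim[k, 1] == s) {
          if (plan$strand == "+") donor <- plan$sites[[k]][1]
          else acc <- plan$sites[[k]][2]
        }
        if (prim[k, 2] == e) {
          if (plan$strand == "+") acc <- plan$sites[[k]][2]
          else donor <- plan$sites[[k]][1]
        }
      }
      # boundaries created by ALT events reuse the canonical class
      if (is.null(donor)) donor <- "GT"
      if (is.null(acc)) acc <- "AG"
      c(donor, acc)
    })
  }

  registerGene <- function(contig, plan, event = NULL, utr3_min = 0,
                           cds_clip = NULL) {
    gene_n <<- gene_n + 1L
    gid <- sprintf("G%03d", gene_n)
    ex <- plan$exons
    tlen <- sum(ex[, 2] - ex[, 1] + 1)
    utr5 <- min(60, max(3, floor(0.15 * tlen)))
    utr3 <- max(min(120, max(3, floor(0.25 * tlen))), utr3_min)
    if (!is.null(cds_clip)) utr3 <- cds_clip     # force CDS into the overlap
    if (utr5 + utr3 >= tlen) { utr5 <- 1; utr3 <- max(1, tlen - 2) }
    # map transcript interval [utr5+1, tlen-utr3] to a genomic hull
    cds_t <- c(utr5 + 1, tlen - utr3)
    if (plan$strand == "-") cds_t <- c(tlen - cds_t[2] + 1, tlen - cds_t[1] + 1)
    gpos <- .mapConcatToGenome(cds_t[1], cds_t[2], ex)
    cds <- c(min(gpos[, 1]), max(gpos[, 2]))

    genes[[gene_n]] <<- data.frame(
      gene_id = gid, contig = contig, strand = plan$strand,
      start = ex[1, 1], end = plan$end,
      cds_start = cds[1], cds_end = cds[2],
      n_exons = nrow(ex), stringsAsFactors = FALSE)

    iso1 <- paste0(gid, ".1")
    isoforms[[length(isoforms) + 1]] <<- data.frame(
      isoform_id = iso1, gene_id = gid, role = "primary",
      stringsAsFactors = FALSE)
    exons[[length(exons) + 1]] <<- data.frame(
      isoform_id = iso1, gene_id = gid, rank = seq_len(nrow(ex)),
      start = ex[, 1], end = ex[, 2], stringsAsFactors = FALSE)
    writes[[length(writes) + 1]] <<- addSiteWrites(contig, ex, plan$sites,
                                                   plan$strand)
    if (!is.null(event)) {
      iso2 <- paste0(gid, ".2")
      isoforms[[length(isoforms) + 1]] <<- data.frame(
        isoform_id = iso2, gene_id = gid, role = paste0("alt_", event$type),
        stringsAsFactors = FALSE)
      aex <- event$alt_exons
      exons[[length(exons) + 1]] <<- data.frame(
        isoform_id = iso2, gene_id = gid, rank = seq_len(nrow(aex)),
        start = aex[, 1], end = aex[, 2], stringsAsFactors = FALSE)
      writes[[length(writes) + 1]] <<- addSiteWrites(contig, aex,
                                                     .sitesFor(plan, aex),
                                                     plan$strand)
      if (!is.null(event$extra_sites)) {
        for (xs in event$extra_sites) {
          # dinucleotide of the shifted boundary, oriented like the original
          site <- xs$site
          chars <- if (xs$which == "start") {
            if (plan$strand == "+") site[1] else .revcomp(site[2])
          } else {
            if (plan$strand == "+") site[2] else .revcomp(site[1])
          }
          writes[[length(writes) + 1]] <<- list(list(contig = contig,
                                                     pos = xs$pos,
                                                     chars = chars))
        }
      }
      ev_n <<- ev_n + 1L
      inc <- if (event$type == "RI") iso2 else iso1
      exc <- if (event$type == "RI") iso1 else iso2
      events[[ev_n]] <<- data.frame(
        event_id = sprintf("EV%03d", ev_n), gene_id = gid,
        type = event$type, contig = contig,
        start = event$ev_start, end = event$ev_end,
        exon_count = event$exon_count,
        inclusion_isoform = inc, exclusion_isoform = exc,
        stringsAsFactors = FALSE)
    }
    gid
  }

  # ---- place genes contig by contig ---------------------------------------
  remaining <- cfg$n_genes
  for (ci in seq_len(cfg$n_contigs)) {
    cursor <- 200L
    while (remaining > 0) {
      gap <- sample(200:600, 1)
      make_pair <- remaining >= 2 &&
        stats::runif(1) < cfg$antisense_pair_rate
      placed_pair <- FALSE
      if (make_pair) {
        ori <- sample(names(cfg$orientation_mix), 1,
                      prob = cfg$orientation_mix)
        res <- .placePair(contig_ids[ci], cursor, ori, cfg, registerGene,
                          cfg$contig_length)
        if (!is.null(res)) {
          pair_n <- pair_n + 1L
          res$row$pair_id <- sprintf("AP%02d", pair_n)
          anti[[pair_n]] <- res$row
          cursor <- res$end + gap
          remaining <- remaining - 2L
          placed_pair <- TRUE
        }
      }
      if (!placed_pair) {
        # single gene; also the fallback when a pair did not fit here
        strand <- sample(c("+", "-"), 1)
        plan <- .planGene(cursor, strand, cfg)
        if (plan$end > cfg$contig_length - 200) break
        event <- .planEvent(plan, cfg)
        registerGene(contig_ids[ci], plan, event)
        cursor <- plan$end + gap
        remaining <- remaining - 1L
      }
    }
  }
  if (remaining > 0)
    stop(sprintf(paste0("contigs too short to host the requested genes: ",
                        "%d gene(s) unplaced with n_contigs=%d, ",
                        "contig_length=%d"),
                 remaining, cfg$n_contigs, cfg$contig_length))

  genes <- if (length(genes)) do.call(rbind, genes) else
    data.frame(gene_id = character(0), contig = character(0),
               strand = character(0), start = numeric(0), end = numeric(0),
               cds_start = numeric(0), cds_end = numeric(0),
               n_exons = integer(0), stringsAsFactors = FALSE)
  isoforms <- if (length(isoforms)) do.call(rbind, isoforms) else
    data.frame(isoform_id = character(0), gene_id = character(0),
               role = character(0), stringsAsFactors = FALSE)
  exons <- if (length(exons)) do.call(rbind, exons) else
    data.frame(isoform_id = character(0), gene_id = character(0),
               rank = integer(0), start = numeric(0), end = numeric(0),
               stringsAsFactors = FALSE)
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(event_id = character(0), gene_id = character(0),
               type = character(0), contig = character(0), start = numeric(0),
               end = numeric(0), exon_count = integer(0),
               inclusion_isoform = character(0),
               exclusion_isoform = character(0), stringsAsFactors = FALSE)
  anti <- if (length(anti)) do.call(rbind, anti) else
    data.frame(pair_id = character(0), gene_plus = character(0),
               gene_minus = character(0), orientation = character(0),
               ov_start = numeric(0), ov_end = numeric(0),
               coding_class = character(0), stringsAsFactors = FALSE)

  # ---- contig sequences with splice-site dinucleotides written in ---------
  seqs <- vapply(seq_len(cfg$n_contigs),
                 function(i) .randSeq(cfg$contig_length), character(1))
  names(seqs) <- contig_ids
  writes <- do.call(c, writes)
  if (length(writes)) {
    wdf <- data.frame(contig = vapply(writes, `[[`, "", "contig"),
                      pos = vapply(writes, function(w) w$pos, 0),
                      chars = vapply(writes, `[[`, "", "chars"),
                      stringsAsFactors = FALSE)
    key <- paste(wdf$contig, wdf$pos)
    dup <- duplicated(key)
    conflict <- tapply(wdf$chars, key, function(v) length(unique(v)) > 1)
    if (any(conflict)) stop("internal error: conflicting splice-site writes")
    wdf <- wdf[!dup, ]
    for (cid in unique(wdf$contig)) {
      sub <- wdf[wdf$contig == cid, ]
      s <- strsplit(seqs[[cid]], "", fixed = TRUE)[[1]]
      for (r in seq_len(nrow(sub))) {
        ch <- strsplit(sub$chars[r], "", fixed = TRUE)[[1]]
        s[sub$pos[r]:(sub$pos[r] + length(ch) - 1)] <- ch
      }
      seqs[[cid]] <- paste(s, collapse = "")
    }
  }

  # ---- expression weights and planted over-representation -----------------
  ng <- nrow(genes)
  base_w <- if (ng) stats::rlnorm(ng, 0, cfg$expression$sdlog) else numeric(0)
  overrep <- data.frame(gene_id = character(0), kind = character(0),
                        library = character(0), fold = numeric(0),
                        stringsAsFactors = FALSE)
  if (ng) {
    in_pair <- genes$gene_id %in% c(anti$gene_plus, anti$gene_minus)
    # planted antisense pairs must be expressed to be detectable at all;
    # floor their abundance at 1.5x the mean weight
    base_w[in_pair] <- pmax(base_w[in_pair], 1.5 * mean(base_w))
    free <- genes$gene_id[!in_pair]
    n_o <- min(cfg$n_overrep_genes, length(free))
    stage_genes <- utils::head(free, n_o)
    free <- setdiff(free, stage_genes)
    n_s <- min(cfg$n_strain_genes, length(free))
    strain_genes <- utils::head(free, n_s)
    # strain-skewed genes need overall depth for the binomial test; stage
    # genes draw their support from the planted fold itself (boosting them
    # would inflate the target library's total and dilute the fold)
    boost <- genes$gene_id %in% strain_genes
    base_w[boost] <- base_w[boost] + 3 * mean(base_w)
    if (n_o)
      overrep <- rbind(overrep, data.frame(
        gene_id = stage_genes, kind = "stage",
        library = cfg$overrep_library, fold = cfg$overrep_fold,
        stringsAsFactors = FALSE))
    if (n_s)
      overrep <- rbind(overrep, data.frame(
        gene_id = strain_genes, kind = "strain", library = "monokaryon",
        fold = 1 / cfg$strain_fold, stringsAsFactors = FALSE))
  }
  genes$base_weight <- base_w

  new("GenomeTruth",
      contigs = Biostrings::DNAStringSet(seqs),
      genes = genes, isoforms = isoforms, exons = exons, events = events,
      antisense = anti, overrep = overrep, config = unclass(cfg))
}

# Map a closed interval [a, b] of the forward exon concatenation to genomic
# blocks (matrix of start, end rows), given the exon matrix.
.mapConcatToGenome <- function(a, b, ex) {
  w <- ex[, 2] - ex[, 1] + 1
  ends <- cumsum(w)
  starts <- ends - w + 1
  out <- NULL
  for (i in seq_len(nrow(ex))) {
    lo <- max(a, starts[i]); hi <- min(b, ends[i])
    if (lo <= hi) {
      gs <- ex[i, 1] + (lo - starts[i])
      ge <- ex[i, 1] + (hi - starts[i])
      out <- rbind(out, c(gs, ge))
    }
  }
  out
}

# Place an antisense pair; returns list(row = registry row, end = cursor) or
# NULL if the contig has no room left.
.placePair <- function(contig, cursor, ori, cfg, registerGene, contig_len) {
  ov_target <- sample(40:100, 1)
  if (ori == "convergent") {
    planA <- .planGene(cursor, "+", cfg, force_canonical = TRUE,
                       last_exon_min = ov_target + 60)
    startB <- planA$end - ov_target + 1
    planB <- .planGene(startB, "-", cfg, force_canonical = TRUE,
                       first_exon_min = ov_target + 60)
    if (planB$end > contig_len - 200) return(NULL)
    ov <- c(startB, planA$end)
    pure <- stats::runif(1) < cfg$p_pure_3utr
    # + gene 3' UTR is at the genomic right end; - gene 3' UTR at the left
    gA <- registerGene(contig, planA,
                       utr3_min = if (pure) ov_target + 20 else 0,
                       cds_clip = if (pure) NULL else 3)
    gB <- registerGene(contig, planB,
                       utr3_min = if (pure) ov_target + 20 else 0,
                       cds_clip = if (pure) NULL else 3)
    cls <- if (pure) "pure_3utr" else "cds_involved"
    return(list(row = data.frame(gene_plus = gA, gene_minus = gB,
                                 orientation = "convergent",
                                 ov_start = ov[1], ov_end = ov[2],
                                 coding_class = cls, stringsAsFactors = FALSE),
                end = planB$end))
  }
  if (ori == "divergent") {
    planB <- .planGene(cursor, "-", cfg, force_canonical = TRUE,
                       last_exon_min = ov_target + 60)
    startA <- planB$end - ov_target + 1
    planA <- .planGene(startA, "+", cfg, force_canonical = TRUE,
                       first_exon_min = ov_target + 60)
    if (planA$end > contig_len - 200) return(NULL)
    ov <- c(startA, planB$end)
    gB <- registerGene(contig, planB)
    gA <- registerGene(contig, planA)
    return(list(row = data.frame(gene_plus = gA, gene_minus = gB,
                                 orientation = "divergent",
                                 ov_start = ov[1], ov_end = ov[2],
                                 coding_class = "cds_involved",
                                 stringsAsFactors = FALSE),
                end = planA$end))
  }
  # contained: small '-' gene inside a long intron of a '+' gene; the inner
  # gene uses a compact intron so it fits the host
  host_intron <- sample(900:1400, 1)
  planA <- .planGene(cursor, "+", cfg, force_canonical = TRUE,
                     n_exons = max(3, cfg$n_exons_range[1]),
                     force_long_intron = host_intron)
  if (planA$end > contig_len - 200) return(NULL)
  j <- planA$long_intron
  istart <- planA$exons[j, 2] + 1
  cfg_inner <- cfg
  cfg_inner$intron_length <- list(meanlog = log(60), sdlog = 0.3,
                                  min = cfg$intron_length$min, max = 150)
  cfg_inner$exon_length$max <- 200
  planB <- .planGene(istart + 30, "-", cfg_inner, force_canonical = TRUE,
                     n_exons = 2)
  if (planB$end > istart + host_intron - 30) return(NULL)
  gA <- registerGene(contig, planA)
  gB <- registerGene(contig, planB)
  list(row = data.frame(gene_plus = gA, gene_minus = gB,
                        orientation = "contained",
                        ov_start = planB$exons[1, 1], ov_end = planB$end,
                        coding_class = "cds_involved",
                        stringsAsFactors = FALSE),
       end = planA$end)
}

# Spliced (mRNA-sense) sequence and exon matrix of an isoform.
.isoformSeq <- function(truth, isoform_id) {
  ex <- truth@exons[truth@exons$isoform_id == isoform_id, , drop = FALSE]
  ex <- ex[order(ex$start), , drop = FALSE]
  gid <- ex$gene_id[1]
  g <- truth@genes[truth@genes$gene_id == gid, ]
  s <- as.character(truth@contigs[[g$contig]])
  parts <- substring(s, ex$start, ex$end)
  fwd <- paste(parts, collapse = "")
  list(seq = if (g$strand == "+") fwd else .revcomp(fwd),
       exons = cbind(ex$start, ex$end), strand = g$strand,
       contig = g$contig)
}

#' Sample per-library EST reads from a simulated genome
#'
#' Draws per-gene read counts from a multinomial over expression weights
#' (log-normal abundance skew times planted fold changes times per-library
#' jitter), emulating non-normalized cDNA libraries.  Reads are 3'-biased
#' mRNA-sense fragments of the spliced isoform sequences with configured
#' substitution/indel errors, per-base quality values, polyA tails on
#' fragments reaching the transcript 3' end, 5' vector remnants, and a
#' configured fraction of contaminant reads.  Truth fields are recorded per
#' read.
#'
#' @param truth a \linkS4class{GenomeTruth}.
#' @param config the matching \code{\link{simConfig}}.
#' @return \code{data.frame} with one row per read: \code{est_id},
#'   \code{library}, \code{sequence}, list column \code{quality} (per-base
#'   error probabilities), truth columns \code{gene_id}, \code{isoform_id},
#'   \code{blocks} (list of genomic block matrices of the insert),
#'   \code{insert_start}, \code{insert_end} (insert interval in read
#'   coordinates), \code{tail_len}, \code{vec5_len}, \code{contaminant}.
#'   The per-library gene sampling weights are attached as attribute
#'   \code{library_weights}.
#' @export
sampleESTs <- function(truth, config) {
  stopifnot(is(truth, "GenomeTruth"), inherits(config, "SimConfig"))
  cfg <- config
  libs <- cfg$libraries
  ng <- nrow(truth@genes)
  if (ng == 0 && sum(libs$target) > 0)
    stop("configuration error: empty gene table with nonzero EST targets")
  set.seed(cfg$seed + 1L)

  # spliced sequences for all isoforms, once
  iso_ids <- truth@isoforms$isoform_id
  iso <- lapply(iso_ids, function(id) .isoformSeq(truth, id))
  names(iso) <- iso_ids
  iso_by_gene <- split(iso_ids, truth@isoforms$gene_id[match(iso_ids,
                         truth@isoforms$isoform_id)])

  base_w <- truth@genes$base_weight
  wmat <- matrix(0, ng, nrow(libs),
                 dimnames = list(truth@genes$gene_id, libs$name))
  rows <- vector("list", sum(libs$target))
  ri <- 0L
  for (li in seq_len(nrow(libs))) {
    lib <- libs[li, ]
    mult <- rep(1, ng)
    ov <- truth@overrep
    for (k in seq_len(nrow(ov))) {
      gi <- match(ov$gene_id[k], truth@genes$gene_id)
      hit <- if (ov$kind[k] == "strain") lib$karyotype == ov$library[k]
             else lib$name == ov$library[k]
      if (hit) mult[gi] <- mult[gi] * ov$fold[k]
    }
    jitter <- stats::rlnorm(ng, 0, cfg$expression$sdlog_library)
    w <- base_w * mult * jitter
    if (ng) wmat[, li] <- w
    if (lib$target == 0) next
    if (ng == 0 || all(w <= 0)) stop("no positive expression weights")
    counts <- as.vector(stats::rmultinom(1, lib$target, w))
    gene_of <- rep(truth@genes$gene_id, counts)
    for (g in gene_of) {
      ri <- ri + 1L
      rows[[ri]] <- .makeRead(g, lib$name, ri, iso, iso_by_gene, cfg)
    }
  }
  rows <- rows[seq_len(ri)]
  out <- data.frame(
    est_id = vapply(rows, `[[`, "", "est_id"),
    library = vapply(rows, `[[`, "", "library"),
    sequence = vapply(rows, `[[`, "", "sequence"),
    gene_id = vapply(rows, `[[`, "", "gene_id"),
    isoform_id = vapply(rows, `[[`, "", "isoform_id"),
    insert_start = vapply(rows, function(r) r$insert_start, 0),
    insert_end = vapply(rows, function(r) r$insert_end, 0),
    tail_len = vapply(rows, function(r) r$tail_len, 0),
    vec5_len = vapply(rows, function(r) r$vec5_len, 0),
    contaminant = vapply(rows, function(r) r$contaminant, FALSE),
    stringsAsFactors = FALSE)
  out$quality <- lapply(rows, `[[`, "quality")
  out$blocks <- lapply(rows, `[[`, "blocks")
  attr(out, "library_weights") <- wmat
  out
}

# Build one read.
.makeRead <- function(gene_id, lib_name, idx, iso, iso_by_gene, cfg) {
  est_id <- sprintf("%s_%05d", lib_name, idx)
  if (stats::runif(1) < cfg$contamination_fraction) {
    src <- cfg$contaminant_seqs[[sample(length(cfg$contaminant_seqs), 1)]]
    len <- round(.interpQuantile(stats::runif(1), cfg$read_length$q,
                                 cfg$read_length$p))
    len <- min(len, nchar(src))
    a <- sample(nchar(src) - len + 1, 1)
    seqc <- substr(src, a, a + len - 1)
    return(list(est_id = est_id, library = lib_name, sequence = seqc,
                quality = rep(cfg$quality$baseline, nchar(seqc)),
                gene_id = NA_character_, isoform_id = NA_character_,
                blocks = NULL, insert_start = NA_real_, insert_end = NA_real_,
                tail_len = 0, vec5_len = 0, contaminant = TRUE))
  }
  iid <- sample(iso_by_gene[[gene_id]], 1)
  it <- iso[[iid]]
  tlen <- nchar(it$seq)
  rl <- round(.interpQuantile(stats::runif(1), cfg$read_length$q,
                              cfg$read_length$p))
  # the cDNA insert is anchored at the transcript 3' end (oligo-dT priming),
  # occasionally 5'-truncated; the clone is sequenced from either end
  at_end <- stats::runif(1) < cfg$three_prime$p_at_end
  trunc5 <- if (at_end) 0L else
    min(stats::rgeom(1, cfg$three_prime$geom_p), max(0, tlen - 50))
  s0 <- 1L + trunc5
  if (stats::runif(1) < cfg$read_five_prime_prob) {
    a <- s0; b <- min(tlen, s0 + rl - 1)
  } else {
    b <- tlen; a <- max(s0, tlen - rl + 1)
  }
  insert <- substr(it$seq, a, b)

  # genomic blocks of the insert (transcript coords -> forward concatenation)
  ab <- if (it$strand == "+") c(a, b) else c(tlen - b + 1, tlen - a + 1)
  blocks <- .mapConcatToGenome(ab[1], ab[2], it$exons)

  tail_len <- 0L
  if (b == tlen && stats::runif(1) < cfg$polya$rate) {
    tail_len <- min(round(stats::rlnorm(1, cfg$polya$meanlog,
                                        cfg$polya$sdlog)), cfg$polya$max)
    tail_len <- max(tail_len, 8L)
  }
  vec5 <- 0L
  vecs <- c(cfg$vector_seq, cfg$adaptor_seqs)
  if (length(vecs) && stats::runif(1) < cfg$vector_rate) {
    v <- vecs[[sample(length(vecs), 1)]]
    vec5 <- nchar(v)
  } else v <- ""
  seqr <- paste0(v, insert, strrep("A", tail_len))
  n <- nchar(seqr)
  insert_start <- vec5 + 1
  insert_end <- vec5 + nchar(insert)

  # reported quality: baseline plus optional low-quality end segment; the
  # actual substitution probability is the configured rate, raised inside a
  # low-quality segment so bad ends carry real errors
  q <- rep(cfg$quality$baseline, n)
  p_act <- rep(cfg$error_rates$sub, n)
  if (stats::runif(1) < cfg$quality$bad_end_rate) {
    bl <- sample(seq(cfg$quality$bad_end_len[1], cfg$quality$bad_end_len[2]), 1)
    bl <- min(bl, n)
    be <- stats::runif(1, cfg$quality$bad_end_err[1], cfg$quality$bad_end_err[2])
    seg <- if (stats::runif(1) < 0.5) seq_len(bl) else (n - bl + 1):n
    q[seg] <- be
    p_act[seg] <- pmax(p_act[seg], be)
  }
  ch <- strsplit(seqr, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(n) < p_act)
  for (i in hit) ch[i] <- sample(setdiff(.BASES, ch[i]), 1)

  # rare indels; track how the insert interval shifts
  if (cfg$error_rates$ins > 0 || cfg$error_rates$del > 0) {
    u <- stats::runif(n)
    del <- which(u < cfg$error_rates$del)
    ins <- which(u >= cfg$error_rates$del &
                   u < cfg$error_rates$del + cfg$error_rates$ins)
    if (length(del) || length(ins)) {
      keep <- setdiff(seq_len(n), del)
      newch <- character(0); newq <- numeric(0)
      shift_s <- -sum(del < insert_start) + sum(ins < insert_start)
      shift_e <- -sum(del <= insert_end) + sum(ins < insert_end)
      for (i in keep) {
        newch <- c(newch, ch[i]); newq <- c(newq, q[i])
        if (i %in% ins) {
          newch <- c(newch, sample(.BASES, 1)); newq <- c(newq, q[i])
        }
      }
      ch <- newch; q <- newq
      insert_start <- insert_start + shift_s
      insert_end <- insert_end + shift_e
    }
  }
  list(est_id = est_id, library = lib_name,
       sequence = paste(ch, collapse = ""), quality = q,
       gene_id = gene_id, isoform_id = iid, blocks = blocks,
       insert_start = insert_start, insert_end = insert_end,
       tail_len = as.integer(tail_len), vec5_len = as.integer(vec5),
       contaminant = FALSE)
}
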