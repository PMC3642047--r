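# Simulator: degenerate cases, planted-structure consistency, distributional
# properties, library accounting, determinism and file round-trips.

test_that("degenerate configurations give the expected structures", {
  cfg0 <- simConfig(seed = 1, n_genes = 0, n_contigs = 1,
                    contig_length = 5000,
                    libraries = data.frame(name = "L1", day = 1L,
                                           karyotype = "dikaryon",
                                           target = 0L))
  t0 <- simulateGenome(cfg0)
  expect_equal(length(truthContigs(t0)), 1L)
  expect_equal(nrow(truthGenes(t0)), 0L)
  expect_equal(nrow(sampleESTs(t0, cfg0)), 0L)

  # a nonzero target over an empty gene table is a configuration error
  cfg_bad <- simConfig(seed = 1, n_genes = 0, n_contigs = 1,
                       contig_length = 5000,
                       libraries = data.frame(name = "L1", day = 1L,
                                              karyotype = "dikaryon",
                                              target = 10L))
  expect_error(sampleESTs(simulateGenome(cfg_bad), cfg_bad),
               "configuration error")

  # one single-exon gene, no isoform events
  cfg1 <- simConfig(seed = 2, n_genes = 1, n_contigs = 1,
                    contig_length = 5000, n_exons_range = c(1, 1),
                    isoform_rates = list(p_CE = 0, p_CSE = 0, p_RI = 0,
                                         p_ALT5 = 0, p_ALT3 = 0),
                    antisense_pair_rate = 0,
                    libraries = table1Libraries(0.001))
  t1 <- simulateGenome(cfg1)
  expect_equal(nrow(truthGenes(t1)), 1L)
  expect_equal(nrow(truthIsoforms(t1)), 1L)
  expect_equal(nrow(truthExons(t1)), 1L)   # zero introns
  expect_equal(nrow(plantedEvents(t1)), 0L)

  # contig too short: sizing error names the offending parameters
  expect_error(simulateGenome(simConfig(seed = 1, n_genes = 50,
                                        n_contigs = 1,
                                        contig_length = 3000)),
               "contig_length")
})

test_that("planted introns respect bounds, registry dinucleotides and the length distribution", {
  fx <- smallFixture()
  truth <- fx$truth
  ex <- truthExons(truth)
  g <- truthGenes(truth)
  seqs <- as.character(truthContigs(truth))
  lens <- numeric(0)
  for (iso in unique(ex$isoform_id)) {
    e <- ex[ex$isoform_id == iso, ]
    e <- e[order(e$start), ]
    if (nrow(e) < 2) next
    gi <- match(e$gene_id[1], g$gene_id)
    s <- seqs[[g$contig[gi]]]
    istart <- e$end[-nrow(e)] + 1
    iend <- e$start[-1] - 1
    lens <- c(lens, iend - istart + 1)
    # donor/acceptor read in gene orientation must be a planted class
    for (j in seq_along(istart)) {
      d5 <- substr(s, istart[j], istart[j] + 1)
      d3 <- substr(s, iend[j] - 1, iend[j])
      pair <- if (g$strand[gi] == "+") paste(d5, d3) else
        paste(ESTforge:::.revcomp(d3), ESTforge:::.revcomp(d5))
      expect_true(pair %in% c("GT AG", "GC AG", "AT AC"), info = pair)
    }
  }
  expect_true(all(lens >= 24 & lens <= 2000))
  # oracle: quantiles of the configured distribution itself
  set.seed(999)
  oracle <- pmin(pmax(round(rlnorm(5000, log(280), 0.45)), 24), 2000)
  expect_lt(abs(median(lens) - median(oracle)) / median(oracle), 0.15)
  expect_lt(abs(median(lens) - 280) / 280, 0.15)
})

test_that("every planted event has an including and an excluding isoform", {
  truth <- smallFixture()$truth
  ex <- truthExons(truth)
  pe <- plantedEvents(truth)
  for (r in seq_len(nrow(pe))) {
    inc <- ex[ex$isoform_id == pe$inclusion_isoform[r], ]
    exc <- ex[ex$isoform_id == pe$exclusion_isoform[r], ]
    covers <- function(e) any(e$start <= pe$start[r] & e$end >= pe$end[r])
    if (pe$type[r] %in% c("CE", "CSE")) {
      # skipped exons present in the inclusion chain, absent from exclusion
      expect_true(any(inc$start == pe$start[r]))
      expect_false(any(exc$start >= pe$start[r] & exc$end <= pe$end[r]))
    } else if (pe$type[r] == "RI") {
      expect_true(covers(inc))     # retained within one exon
      expect_true(any(exc$end == pe$start[r] - 1))  # spliced out
    }
  }
})

test_that("read counts, lengths and abundance follow the configured laws", {
  fx <- smallFixture()
  reads <- fx$reads
  libs <- fx$cfg$libraries
  # realized per-library counts equal the targets exactly
  tab <- table(factor(reads$library, levels = libs$name))
  expect_equal(as.integer(tab), libs$target)
  # read lengths within configured range; median in a sane band
  len <- nchar(reads$sequence)
  expect_true(all(len >= 50))
  # per-gene counts in the largest library follow the sampling weights
  # (oracle: multinomial law, chi-square goodness of fit not rejected)
  w <- attr(reads, "library_weights")
  lib <- libs$name[which.max(libs$target)]
  sel <- reads$library == lib & !reads$contaminant
  counts <- table(factor(reads$gene_id[sel], levels = rownames(w)))
  p <- w[, lib] / sum(w[, lib])
  keep <- p > 5 / sum(counts)   # pool rare genes for the test's validity
  chi <- suppressWarnings(chisq.test(
    c(counts[keep], sum(counts[!keep])), p = c(p[keep], sum(p[!keep]))))
  expect_gt(chi$p.value, 0.01)
})

test_that("noise-free reads are exact substrings of their isoform sequences", {
  fx <- smallFixture()
  reads <- fx$reads
  truth <- fx$truth
  idx <- which(!reads$contaminant)[1:50]
  for (i in idx) {
    iso <- ESTforge:::.isoformSeq(truth, reads$isoform_id[i])
    expect_true(grepl(reads$sequence[i], iso$seq, fixed = TRUE))
  }
})

test_that("identical configurations give byte-identical outputs", {
  cfg <- simConfig(seed = 5, n_genes = 8, n_contigs = 1,
                   contig_length = 20000, libraries = table1Libraries(0.004))
  d1 <- file.path(tempdir(), "sim_a"); d2 <- file.path(tempdir(), "sim_b")
  for (d in c(d1, d2)) {
    truth <- simulateGenome(cfg)
    reads <- sampleESTs(truth, cfg)
    writeSimOutputs(truth, reads, d)
  }
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("write/read round-trips preserve coordinates and records", {
  cfg <- simConfig(seed = 6, n_genes = 6, n_contigs = 1,
                   contig_length = 16000, libraries = table1Libraries(0.003))
  truth <- simulateGenome(cfg)
  reads <- sampleESTs(truth, cfg)
  d <- file.path(tempdir(), "sim_rt")
  writeSimOutputs(truth, reads, d)

  # genome round-trip
  g2 <- Biostrings::readDNAStringSet(file.path(d, "genome.fasta"))
  expect_identical(as.character(g2), as.character(truthContigs(truth)))

  # GFF3 round-trip reproduces exon coordinates exactly
  ann <- importTruthAnnotation(file.path(d, "truth.gff3"))
  ex <- truthExons(truth)
  ex <- ex[order(ex$isoform_id, ex$start), ]
  expect_equal(ann$exons$start, ex$start)
  expect_equal(ann$exons$end, ex$end)
  expect_equal(ann$genes$cds_start,
               truthGenes(truth)$cds_start[match(ann$genes$gene_id,
                                                 truthGenes(truth)$gene_id)])

  # reads re-parsed equal the in-memory records field by field
  r2 <- readSimulatedReads(d)
  expect_equal(r2$est_id, reads$est_id)
  expect_equal(r2$sequence, reads$sequence)
  expect_equal(r2$insert_start, reads$insert_start)
  expect_equal(r2$tail_len, reads$tail_len)
  expect_equal(r2$contaminant, reads$contaminant)
  for (i in seq_len(nrow(reads))) {
    expect_equal(r2$quality[[i]], reads$quality[[i]], tolerance = 1e-4)
    expect_equal(r2$blocks[[i]], reads$blocks[[i]])
  }

  # empty read set still writes valid files
  d0 <- file.path(tempdir(), "sim_empty")
  writeSimOutputs(truth, reads[0, ], d0)
  expect_equal(length(Biostrings::readDNAStringSet(
    file.path(d0, "reads.fasta"))), 0L)
  expect_equal(nrow(readSimulatedReads(d0)), 0L)
})
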