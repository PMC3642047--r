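# Cluster-and-merge: locus clustering vs a graph oracle, the splice
# compatibility rules, merge fixpoint behaviour, unspliced housing, strand
# inference and ESTGene grouping, plus order invariance.

bruteComponents <- function(start, end) {
  n <- length(start)
  adj <- outer(seq_len(n), seq_len(n), function(i, j)
    start[i] <= end[j] & start[j] <= end[i])
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] > comp[i]) { comp[j] <- comp[i]; changed <- TRUE }
      if (adj[i, j] && comp[i] > comp[j]) { comp[i] <- comp[j]; changed <- TRUE }
    }
    if (!changed) break
  }
  comp
}

test_that("locus clustering equals connected components of the overlap graph", {
  s1 <- alnStruct("a", 100, 200, intronsDF(120, 150))
  s2 <- alnStruct("b", 500, 700, intronsDF(550, 600))
  expect_equal(length(clusterLoci(list(s1, s2))), 2L)
  # transitive chaining: A-B overlap, B-C overlap, A and C disjoint
  s3 <- alnStruct("c", 180, 520, intronsDF(250, 300))
  cl <- clusterLoci(list(s1, s2, s3))
  expect_equal(length(cl), 1L)
  expect_setequal(cl[[1]], 1:3)
  # randomized oracle
  set.seed(404)
  for (rep in 1:20) {
    n <- sample(3:25, 1)
    st <- sample(1:2000, n, TRUE)
    en <- st + sample(20:400, n, TRUE)
    structs <- lapply(seq_len(n), function(i)
      alnStruct(sprintf("e%02d", i), st[i], en[i], intronsDF(st[i] + 5,
                                                            st[i] + 10)))
    cl <- clusterLoci(structs)
    got <- integer(n)
    for (k in seq_along(cl)) got[cl[[k]]] <- k
    oracle <- bruteComponents(st, en)
    expect_equal(length(unique(got)), length(unique(oracle)))
    # same partition
    expect_true(all(tapply(got, oracle, function(v)
      length(unique(v))) == 1))
  }
})

# Definition-checking oracle for splice compatibility, written directly from
# the rule: one shared intron, and identical intron sets over the shared
# genomic region.
oracleCompatible <- function(a, b) {
  if (a$contig != b$contig) return(FALSE)
  keys <- function(x) paste(x$introns$start, x$introns$end)
  if (length(intersect(keys(a), keys(b))) == 0) return(FALSE)
  lo <- max(a$start, b$start); hi <- min(a$end, b$end)
  if (lo > hi) return(FALSE)
  ina <- a$introns[a$introns$end >= lo & a$introns$start <= hi, ]
  inb <- b$introns[b$introns$end >= lo & b$introns$start <= hi, ]
  setequal(paste(ina$start, ina$end), paste(inb$start, inb$end))
}

test_that("splice compatibility follows the shared-junction rules", {
  # identical single intron, staggered terminal exons
  a <- alnStruct("a", 100, 400, intronsDF(200, 300))
  b <- alnStruct("b", 150, 480, intronsDF(200, 300))
  expect_true(spliceCompatible(a, b))
  # skipped-exon conflict: a's intron spans an exon present in b
  a2 <- alnStruct("a2", 100, 600, intronsDF(200, 500))
  b2 <- alnStruct("b2", 100, 600, intronsDF(c(200, 400), c(300, 500)))
  expect_false(spliceCompatible(a2, b2))
  # no shared junction at all
  c2 <- alnStruct("c2", 100, 600, intronsDF(210, 310))
  expect_false(spliceCompatible(a, c2))
  # unspliced input violates the contract
  expect_error(spliceCompatible(a, alnStruct("u", 100, 200)),
               "attachUnspliced")
  # randomized agreement with the definition-checking oracle
  fx <- smallFixture()
  structs <- alignmentStructures(filterMapped(fx$aln$alignments)$kept)
  spliced <- Filter(function(s) nrow(s$introns) > 0, structs)
  spliced <- spliced[1:min(200, length(spliced))]
  set.seed(405)
  pairs <- cbind(sample(length(spliced), 400, TRUE),
                 sample(length(spliced), 400, TRUE))
  for (r in seq_len(nrow(pairs))) {
    x <- spliced[[pairs[r, 1]]]; y <- spliced[[pairs[r, 2]]]
    expect_equal(spliceCompatible(x, y), oracleCompatible(x, y))
  }
})

test_that("merging builds non-redundant transcripts and separates conflicting isoforms", {
  # three ESTs tiling one 4-exon isoform with shared junctions
  # exons [100,199] [300,399] [500,599] [700,780]
  i123 <- intronsDF(c(200, 400, 600), c(299, 499, 699))
  tile <- list(alnStruct("t1", 100, 599, i123[1:2, ]),
               alnStruct("t2", 320, 780, i123[2:3, ]),
               alnStruct("t3", 510, 780, i123[3, , drop = FALSE]))
  trs <- mergeCluster(tile)
  expect_equal(length(trs), 1L)
  expect_equal(nrow(trs[[1]]$exons), 4L)
  expect_equal(c(trs[[1]]$start, trs[[1]]$end), c(100, 780))
  expect_setequal(trs[[1]]$support, c("t1", "t2", "t3"))
  # two isoforms differing by a skipped exon give exactly two transcripts
  inc <- alnStruct("inc", 100, 700, intronsDF(c(200, 400), c(300, 500)))
  exc <- alnStruct("exc", 100, 700, intronsDF(200, 500))
  trs2 <- mergeCluster(list(inc, exc))
  expect_equal(length(trs2), 2L)
  # support conservation: every alignment in exactly one transcript
  expect_setequal(unlist(lapply(trs2, `[[`, "support")), c("inc", "exc"))
})

test_that("merging is invariant under input permutations", {
  fx <- smallFixture()
  structs <- alignmentStructures(filterMapped(fx$aln$alignments)$kept)
  spliced <- Filter(function(s) nrow(s$introns) > 0, structs)
  cl <- clusterLoci(spliced)
  big <- cl[[which.max(lengths(cl))]]
  sub <- spliced[big]
  sig <- function(trs) sort(vapply(trs, function(t)
    paste(paste(t$exons[, 1], t$exons[, 2], collapse = ";"),
          paste(sort(t$support), collapse = ","), sep = "|"), ""))
  ref <- sig(mergeCluster(sub))
  set.seed(406)
  for (rep in 1:5) {
    expect_equal(sig(mergeCluster(sample(sub))), ref)
  }
})

test_that("merged transcripts are internally consistent", {
  # audit: every member shares at least one intron with the merged
  # structure, and no pair of members disagrees over its shared genomic
  # region (members may share junctions only via an intermediary)
  fx <- smallFixture()
  structs <- alignmentStructures(filterMapped(fx$aln$alignments)$kept)
  spliced <- Filter(function(s) nrow(s$introns) > 0, structs)
  names(spliced) <- vapply(spliced, `[[`, "", "est_id")
  trs <- unlist(lapply(clusterLoci(spliced), function(cl)
    mergeCluster(spliced[cl])), recursive = FALSE)
  noConflict <- function(a, b) {
    lo <- max(a$start, b$start); hi <- min(a$end, b$end)
    if (lo > hi) return(TRUE)
    ia <- a$introns[a$introns$end >= lo & a$introns$start <= hi, ]
    ib <- b$introns[b$introns$end >= lo & b$introns$start <= hi, ]
    setequal(paste(ia$start, ia$end), paste(ib$start, ib$end))
  }
  set.seed(407)
  for (t in sample(trs, min(25, length(trs)))) {
    mem <- spliced[t$support]
    tkey <- paste(t$introns$start, t$introns$end)
    for (m in mem) {
      expect_true(any(paste(m$introns$start, m$introns$end) %in% tkey))
    }
    if (length(mem) < 2) next
    for (i in 1:(length(mem) - 1)) for (j in (i + 1):length(mem)) {
      expect_true(noConflict(mem[[i]], mem[[j]]))
    }
  }
})

test_that("unspliced alignments are housed by the containment rule", {
  t1 <- list(contig = "c1",
             exons = rbind(c(100, 200), c(300, 400), c(500, 600)),
             introns = intronsDF(c(201, 401), c(299, 499)),
             support = "s1", start = 100, end = 600)
  inside <- alnStruct("u1", 320, 380)          # inside an internal exon
  spanning <- alnStruct("u2", 250, 350)        # crosses an intron
  term <- alnStruct("u3", 80, 150)             # extends the first exon
  res <- attachUnspliced(list(t1), list(inside, spanning, term))
  expect_equal(res$absorbed, c(TRUE, FALSE, TRUE))
  expect_equal(length(res$transcripts), 2L)    # t1 + one leftover
  expect_equal(res$transcripts[[1]]$exons[1, 1], 80)  # extended outward
  lo <- res$transcripts[[2]]
  expect_equal(nrow(lo$introns), 0L)
  expect_equal(c(lo$start, lo$end), c(250, 350))
  # containment decisions agree with a direct check on simulated reads
  fx <- smallFixture()
  structs <- alignmentStructures(filterMapped(fx$aln$alignments)$kept)
  ni <- vapply(structs, function(s) nrow(s$introns), 0L)
  spliced <- structs[ni > 0]; unspliced <- structs[ni == 0]
  trs <- unlist(lapply(clusterLoci(spliced), function(cl)
    mergeCluster(spliced[cl])), recursive = FALSE)
  res2 <- attachUnspliced(trs, unspliced)
  directFit <- vapply(unspliced, function(s) {
    any(vapply(trs, function(t) {
      if (t$contig != s$contig || nrow(t$introns) == 0) return(FALSE)
      if (min(t$start, s$start) > min(t$end, s$end)) return(FALSE)
      if (s$end < t$start || s$start > t$end) return(FALSE)
      lo <- c(-Inf, t$introns$end + 1); hi <- c(t$introns$start - 1, Inf)
      any(s$start >= lo & s$end <= hi)
    }, FALSE))
  }, FALSE)
  expect_equal(res2$absorbed, directFit)
})

test_that("strand inference reads the junction consensus", {
  expect_equal(inferStrand(intronsDF(c(10, 50), c(30, 70))), "+")
  expect_equal(inferStrand(intronsDF(c(10, 50), c(30, 70),
                                     donor = "CT", acceptor = "AC")), "-")
  expect_equal(inferStrand(intronsDF(c(10, 50), c(30, 70),
                                     donor = c("GT", "CT"),
                                     acceptor = c("AG", "AC"))), "*")
  expect_equal(inferStrand(intronsDF(numeric(0), numeric(0))), "*")
  # minor sites are unknown under the default consensus but resolve with the
  # canonical set
  gc <- intronsDF(10, 30, donor = "GC", acceptor = "AG")
  expect_equal(inferStrand(gc), "*")
  expect_equal(inferStrand(gc, sites = list(c("GT", "AG"), c("GC", "AG"))),
               "+")
})

test_that("ESTGene grouping joins same-strand overlaps and never bridges strands", {
  mk <- function(id, start, end, donor, acceptor) {
    list(contig = "c1", exons = rbind(c(start, start + 19),
                                      c(end - 19, end)),
         introns = intronsDF(start + 20, end - 20, donor, acceptor),
         support = id, start = start, end = end)
  }
  # two incompatible same-strand overlapping transcripts: one gene
  a <- mk("a", 100, 400, "GT", "AG")
  b <- mk("b", 300, 700, "GT", "AG")
  # an antisense transcript overlapping both: its own gene
  r <- mk("r", 350, 650, "CT", "AC")
  genes <- toGeneSet(list(a, b, r))
  gm <- geneMeta(genes)
  expect_equal(nrow(gm), 2L)
  expect_setequal(gm$strand, c("+", "-"))
  expect_equal(gm$n_transcripts[gm$strand == "+"], 2L)
  # randomized: component structure equals the brute-force graph components
  set.seed(408)
  for (rep in 1:10) {
    n <- sample(4:15, 1)
    st <- sample(1:3000, n, TRUE)
    en <- st + sample(100:400, n, TRUE)
    sd <- sample(c("+", "-"), n, TRUE)
    trs <- lapply(seq_len(n), function(i)
      mk(sprintf("x%02d", i), st[i], en[i],
         if (sd[i] == "+") "GT" else "CT", if (sd[i] == "+") "AG" else "AC"))
    gm2 <- geneMeta(toGeneSet(trs))
    for (s in c("+", "-")) {
      sel <- sd == s
      if (!any(sel)) next
      expect_equal(sum(gm2$strand == s),
                   length(unique(bruteComponents(st[sel], en[sel]))))
    }
  }
})
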