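# Internal helpers shared across modules.

.BASES <- c("A", "C", "G", "T")

# Random uniform-composition nucleotide string.
.randSeq <- function(n) {
  paste(sample(.BASES, n, replace = TRUE), collapse = "")
}

# Reverse complement of plain character vectors (Biostrings used for sets;
# this avoids object churn for single short strings in hot loops).
.revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTNacgtn", "TGCANtgcan",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# Piecewise-linear inverse CDF through (p, q) knots.
.interpQuantile <- function(u, q, p) {
  stats::approx(p, q, xout = u, rule = 2)$y
}

# Union of closed integer intervals given as a 2-column matrix (start, end).
# Returns a matrix sorted by start with touching/overlapping rows merged.
.unionIntervals <- function(m) {
  if (is.null(m) || nrow(m) == 0) return(matrix(numeric(0), ncol = 2))
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  out <- m[1, , drop = FALSE]
  if (nrow(m) > 1) {
    for (i in 2:nrow(m)) {
      k <- nrow(out)
      if (m[i, 1] <= out[k, 2] + 1) {
        out[k, 2] <- max(out[k, 2], m[i, 2])
      } else {
        out <- rbind(out, m[i, , drop = FALSE])
      }
    }
  }
  unname(out)
}

# Connected components of an interval-overlap graph by plane sweep.
# Returns an integer component id per row of (start, end).
.overlapComponents <- function(start, end) {
  n <- length(start)
  if (n == 0) return(integer(0))
  o <- order(start, end)
  comp <- integer(n)
  cur <- 0L
  maxend <- -Inf
  for (i in o) {
    if (start[i] > maxend) cur <- cur + 1L
    comp[i] <- cur
    maxend <- max(maxend, end[i])
  }
  comp
}

# sample() treats a length-1 numeric as 1:x; this always samples elements.
.sample1 <- function(x) if (length(x) == 1) x else sample(x, 1)

# Intersection width of [s1,e1] and [s2,e2]; <= 0 means disjoint.
.ovWidth <- function(s1, e1, s2, e2) pmin(e1, e2) - pmax(s1, s2) + 1

.key2 <- function(s, e) paste(s, e, sep = "-")

# Canonical splice-site pair string as seen in the transcript orientation.
.sitePair <- function(donor, acceptor) paste(donor, acceptor, sep = ":")
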