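# shared fixture builders and independent oracles

# brute-force base-level segmentation oracle: mark every base with the set
# of isoforms covering it, then merge maximal runs of constant membership
oracle_segments <- function(isoform_exons) {
  hi <- max(vapply(isoform_exons, function(e) max(e$end), numeric(1)))
  memb <- sapply(isoform_exons, function(e) {
    cov <- logical(hi)
    for (k in seq_len(nrow(e)))
      cov[(e$start[k] + 1L):e$end[k]] <- TRUE   # base i-1 -> index i
    cov
  })
  memb <- matrix(memb, nrow = hi)
  key <- apply(memb, 1L, paste, collapse = "")
  key[rowSums(memb) == 0L] <- NA
  segs <- list()
  run_start <- NA
  for (i in seq_len(hi + 1L)) {
    k <- if (i <= hi) key[i] else NA
    prev <- if (i > 1L) key[i - 1L] else NA
    new_run <- !identical(k, prev)
    if (new_run && !is.na(prev))
      segs[[length(segs) + 1L]] <- c(run_start - 1L, i - 1L)
    if (new_run && !is.na(k)) run_start <- i
  }
  start <- vapply(segs, `[`, numeric(1), 1L)
  end <- vapply(segs, `[`, numeric(1), 2L)
  inclusion <- t(vapply(seq_along(isoform_exons), function(j)
    as.integer(memb[start + 1L, j]), integer(length(start))))
  if (length(start) == 1L)
    inclusion <- matrix(vapply(seq_along(isoform_exons), function(j)
      as.integer(memb[start + 1L, j]), integer(1L)), ncol = 1L)
  list(segments = data.frame(start = start, end = end,
                             length = end - start),
       inclusion = inclusion)
}

# random exon structures for property tests (m <= 4, <= 6 intervals,
# coordinates <= 10000)
random_isoform_exons <- function() {
  m <- sample(1:4, 1L)
  lapply(seq_len(m), function(i) {
    k <- sample(1:6, 1L)
    bounds <- sort(sample(0:10000, 2L * k))
    data.frame(start = bounds[seq(1L, 2L * k, by = 2L)],
               end = bounds[seq(2L, 2L * k, by = 2L)])
  })
}

# quadratic-time read assigner: scan every read against every segment
brute_count <- function(alignments, genes) {
  lapply(genes, function(g) {
    x <- integer(nrow(g$segments))
    for (r in seq_len(nrow(alignments))) {
      if (alignments$chrom[r] != g$chrom) next
      p <- alignments$pos[r]
      j <- which(g$segments$start <= p & p < g$segments$end)
      if (length(j) == 1L) x[j] <- x[j] + 1L
    }
    x
  })
}

# a two-isoform cassette-exon gene used across tests
cassette_gene <- function() {
  seg <- segment_gene(list(
    A = data.frame(start = c(0, 500, 1000), end = c(300, 800, 1400)),
    B = data.frame(start = c(0, 1000), end = c(300, 1400))))
  gene_model("gX", "chr1", "+", c("A", "B"), seg$segments, seg$inclusion)
}

# direct Poisson log-pmf oracle for the segment-count likelihood
oracle_loglik <- function(theta, x, l, b, w) {
  lam <- as.numeric(l) * as.numeric(w) * as.vector(crossprod(b, theta))
  sum(stats::dpois(x, lam, log = TRUE))
}

# random well-posed estimation instances: structure without all-zero
# rows/columns, positive weights on included segments, Poisson counts
random_instance <- function(m_max = 4L, n_max = 12L) {
  m <- sample(1:m_max, 1L)
  n <- sample(max(2L, m):n_max, 1L)
  repeat {
    a <- matrix(rbinom(m * n, 1L, 0.7), m, n)
    if (all(rowSums(a) > 0L) && all(colSums(a) > 0L)) break
  }
  b <- a * matrix(runif(m * n, 0.3, 2), m, n)
  l <- sample(100:1000, n, replace = TRUE)
  w <- round(runif(1, 1e5, 1e6))
  theta <- 10^runif(m, -7.5, -6)
  lam <- as.numeric(l) * w * as.vector(crossprod(b, theta))
  x <- rpois(n, lam)
  list(m = m, n = n, b = b, l = l, w = w, theta_true = theta, x = x)
}

write_sam <- function(lines, path = tempfile(fileext = ".sam")) {
  writeLines(lines, path)
  path
}

sam_record <- function(qname, flag, chrom, pos1,
                       cigar = "75M") {
  paste(qname, flag, chrom, pos1, 255, cigar, "*", 0, 0, "*", "*",
        sep = "\t")
}
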