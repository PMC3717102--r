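#' Binned positional bias curves
#'
#' A bias curve is a nonparametric, piecewise-constant read-density profile
#' over relative position t in \[0,1) measured 5' to 3' along a transcript
#' (global curve, GBC) or along a gene's exonic union (local curve, LBC).
#' Bin weights are non-negative and normalized to mean 1, so a flat curve
#' of all ones encodes the uniform model.
#'
#' @param weights numeric vector of `B >= 2` non-negative bin weights; they
#'   are rescaled to mean 1.
#' @param kind `"global"` or `"local"`.
#' @return object of class `bias_curve` with fields `weights` and `kind`.
#' @export
bias_curve <- function(weights, kind = c("global", "local")) {
  kind <- match.arg(kind)
  weights <- as.numeric(weights)
  if (length(weights) < 2L) stop("a bias curve needs >= 2 bins")
  if (any(!is.finite(weights)) || any(weights < 0))
    stop("bin weights must be finite and non-negative")
  if (mean(weights) <= 0) stop("bin weights must not be all zero")
  structure(list(weights = weights / mean(weights), kind = kind),
            class = "bias_curve")
}

#' @export
print.bias_curve <- function(x, ...) {
  cat(sprintf("%s bias curve, %d bins:\n", x$kind, length(x$weights)))
  print(round(x$weights, 4))
  invisible(x)
}

#' Flat (uniform) bias curve
#' @param bins number of bins.
#' @param kind `"global"` or `"local"`.
#' @return a [bias_curve()] of all ones.
#' @export
flat_bias_curve <- function(bins = 10L, kind = "global") {
  bias_curve(rep(1, bins), kind)
}

#' Linear 5'-decay bias curve
#'
#' Piecewise-constant discretization of the density 2(1 - t): read density
#' decreases linearly from the 5' end to zero at the 3' end, a strong
#' version of the positional trend seen in some library preparations.
#'
#' @param bins number of bins.
#' @return a [bias_curve()] with weights `2 * (1 - midpoint)`.
#' @export
linear_decay_curve <- function(bins = 10L) {
  mid <- (seq_len(bins) - 0.5) / bins
  bias_curve(2 * (1 - mid), "global")
}

# bin index of integer offsets 0..L-1 for B bins over [0,1)
.bin_of <- function(off, L, B) pmin(B, floor(off * B / L) + 1L)

# convert genomic-orientation union offsets to 5'->3' offsets
.offsets_5p <- function(gene, off, L = exonic_length(gene)) {
  if (gene$strand == "-") L - 1L - off else off
}

#' Estimate the global bias curve (GBC)
#'
#' Pools single-isoform genes, where the transcript-relative position of a
#' read is unambiguous: each read's exonic offset is mapped to
#' t = offset / exonic_length, histogrammed into `bins` bins, each gene's
#' histogram normalized to sum 1 (equal gene weighting), averaged over
#' genes, and rescaled to bin mean 1.
#'
#' @param genes list of [gene_model()] objects.
#' @param offsets named list of per-gene read offsets within the exonic
#'   union (genomic orientation), as produced by [count_reads()].
#' @param bins number of bins (>= 2).
#' @return a `"global"` [bias_curve()]. If no single-isoform gene has any
#'   assigned read, the flat curve is returned with a warning.
#' @export
estimate_gbc <- function(genes, offsets, bins = 10L) {
  stopifnot(bins >= 2L)
  hs <- NULL
  n_used <- 0L
  acc <- numeric(bins)
  for (g in genes) {
    if (length(g$isoform_ids) != 1L) next
    off <- offsets[[g$gene_id]]
    if (is.null(off) || length(off) == 0L) next
    L <- exonic_length(g)
    k <- .bin_of(.offsets_5p(g, off, L), L, bins)
    h <- tabulate(k, bins)
    acc <- acc + h / sum(h)
    n_used <- n_used + 1L
  }
  if (n_used == 0L) {
    warning("no single-isoform gene with assigned reads; using flat global bias curve",
            call. = FALSE)
    return(flat_bias_curve(bins, "global"))
  }
  bias_curve(acc / n_used, "global")
}

#' Estimate a local bias curve (LBC) for one gene
#'
#' Profiles the gene's own positional read density over its exonic union.
#' Only reads falling in constitutive segments (segments included by every
#' isoform) enter the estimate, and each bin's read count is divided by the
#' number of constitutive bases it contains: on constitutive bases the read
#' density is proportional to summed isoform expression, so its positional
#' shape reflects sequencing bias rather than which isoform is expressed.
#' Bins without constitutive bases are set to the neutral weight 1.
#'
#' @param gene a [gene_model()].
#' @param offsets integer read offsets within the gene's exonic union
#'   (genomic orientation).
#' @param bins number of bins.
#' @param min_reads minimum number of constitutive-segment reads; below it
#'   the curve is deemed unavailable and `NULL` is returned (the caller
#'   then falls back to the global curve alone, alpha = 1).
#' @return a `"local"` [bias_curve()], or `NULL` when unavailable.
#' @export
estimate_lbc <- function(gene, offsets, bins = 10L, min_reads = 50L) {
  stopifnot(bins >= 2L)
  l <- gene$segments$length
  L <- sum(l)
  const <- colSums(gene$inclusion) == nrow(gene$inclusion)
  if (!any(const)) return(NULL)
  uoff <- cumsum(c(0L, l))[seq_along(l)]
  base_tab <- numeric(bins)
  for (j in which(const)) {
    k <- .bin_of(.offsets_5p(gene, uoff[j] + seq_len(l[j]) - 1L, L), L, bins)
    base_tab <- base_tab + tabulate(k, bins)
  }
  if (length(offsets) > 0L) {
    seg_of <- findInterval(offsets, uoff)
    offsets <- offsets[const[seg_of]]
  }
  if (length(offsets) < min_reads) return(NULL)
  read_tab <- tabulate(.bin_of(.offsets_5p(gene, offsets, L), L, bins), bins)
  d <- read_tab / base_tab
  d[base_tab == 0] <- NA_real_
  d <- d / mean(d, na.rm = TRUE)
  d[is.na(d)] <- 1
  bias_curve(d, "local")
}

#' Weighted structure matrix from a bias curve
#'
#' Reweights the 0/1 inclusion matrix `a_ij` by the average curve weight
#' over the relative positions occupied by each included segment. With
#' `frame = "isoform"` (used for the global bias matrix, GBM) segment
#' positions are taken in the coordinate system of each isoform separately:
#' cumulative offsets of the isoform's included segments divided by the
#' isoform length. With `frame = "union"` (local bias matrix, LBM) the
#' gene's exonic-union coordinates are used, where a read's isoform is
#' unknown. Excluded segments (`a_ij = 0`) stay exactly 0, and a flat curve
#' reproduces `a_ij`.
#'
#' @param gene a [gene_model()].
#' @param curve a [bias_curve()].
#' @param frame `"isoform"` or `"union"`.
#' @return non-negative `m x n` matrix.
#' @export
bias_matrix <- function(gene, curve, frame = c("isoform", "union")) {
  frame <- match.arg(frame)
  a <- gene$inclusion
  m <- nrow(a); n <- ncol(a)
  l <- gene$segments$length
  wts <- curve$weights
  B <- length(wts)
  out <- matrix(0, m, n, dimnames = dimnames(a))
  if (frame == "union") {
    L <- sum(l)
    uoff <- cumsum(c(0L, l))[seq_len(n)]
    for (j in seq_len(n)) {
      k <- .bin_of(.offsets_5p(gene, uoff[j] + seq_len(l[j]) - 1L, L), L, B)
      v <- mean(wts[k])
      out[a[, j] == 1L, j] <- v
    }
  } else {
    for (i in seq_len(m)) {
      inc <- which(a[i, ] == 1L)
      li <- l[inc]
      Li <- sum(li)
      # cumulative offsets inside the isoform, in genomic segment order;
      # on the minus strand the 5' end is the genomically last base
      coff <- cumsum(c(0L, li))[seq_along(inc)]
      for (t in seq_along(inc)) {
        offs <- coff[t] + seq_len(li[t]) - 1L
        if (gene$strand == "-") offs <- Li - 1L - offs
        out[i, inc[t]] <- mean(wts[.bin_of(offs, Li, B)])
      }
    }
  }
  out
}

#' Mix global and local bias matrices
#'
#' Elementwise arithmetic mixture `b_ij = alpha * GBM_ij + (1 - alpha) *
#' LBM_ij`; `alpha = 1` keeps only the global correction and `alpha = 0`
#' only the local one. The mixed matrix replaces `a_ij` in the
#' log-likelihood.
#'
#' @param gbm global bias matrix (`m x n`).
#' @param lbm local bias matrix (same shape).
#' @param alpha mixing weight in \[0, 1\].
#' @return `m x n` matrix.
#' @export
mix_bias <- function(gbm, lbm, alpha) {
  if (!identical(dim(gbm), dim(lbm)))
    stop("GBM and LBM dimensions differ")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1)
    stop("alpha must be a single value in [0, 1]")
  alpha * gbm + (1 - alpha) * lbm
}
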