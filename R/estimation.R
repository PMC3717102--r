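#' Optimizer settings
#'
#' @param eps bisection interval precision on theta; every 1-D search stops
#'   once its bracketing interval is no wider than `eps`, after at most
#'   `ceiling(log2((hi - lo) / eps))` bisections.
#' @param max_sweeps maximum number of full coordinate sweeps.
#' @param loglik_tol stop when a full sweep improves the log-likelihood by
#'   less than this.
#' @param theta_upper_factor the 1-D search interval for theta_i is
#'   `[0, factor * sum(x) / (w * min_j l_j b_ij)]` over included segments,
#'   which always brackets the coordinate-wise maximizer.
#' @param start optional start vector overriding the default equal-split
#'   initialization `sum(x) / (m w sum_j l_j b_ij)`.
#' @return list of class `optimizer_config`.
#' @export
optimizer_config <- function(eps = 1e-8, max_sweeps = 100L,
                             loglik_tol = 1e-8, theta_upper_factor = 2,
                             start = NULL) {
  stopifnot(eps > 0, max_sweeps >= 1L, loglik_tol > 0,
            theta_upper_factor > 0)
  structure(list(eps = eps, max_sweeps = as.integer(max_sweeps),
                 loglik_tol = loglik_tol,
                 theta_upper_factor = theta_upper_factor, start = start),
            class = "optimizer_config")
}

#' Bias-corrected Poisson log-likelihood of a gene
#'
#' The count of segment j is Poisson with rate
#' `lambda_j = l_j w sum_i b_ij theta_i`, so the joint log-likelihood is
#' `-w sum_j sum_i l_j b_ij theta_i + sum_j x_j log(l_j w sum_i b_ij theta_i)
#'  - sum_j log(x_j!)`.
#' Segments with `x_j = 0` contribute only the `-lambda_j` penalty; if some
#' `x_j > 0` has zero rate the function returns `-Inf`.
#'
#' @param theta non-negative vector of `m` isoform expression levels
#'   (expected reads per base per sequenced read).
#' @param x integer vector of `n` segment read counts.
#' @param l integer vector of `n` segment lengths.
#' @param b `m x n` weighted structure matrix (the inclusion matrix for the
#'   uniform model).
#' @param w library total read count.
#' @return log-likelihood value (possibly `-Inf`).
#' @export
gene_loglik <- function(theta, x, l, b, w) {
  if (any(theta < 0)) stop("theta must be non-negative")
  s <- as.vector(crossprod(b, theta))          # sum_i b_ij theta_i
  if (any(x > 0 & s <= 0)) return(-Inf)
  pos <- x > 0
  -w * sum(l * s) + sum(x[pos] * log(l[pos] * w * s[pos])) -
    sum(lfactorial(x))
}

#' Partial derivative of the log-likelihood in theta_i
#'
#' `d logL / d theta_i = -w sum_j l_j b_ij + sum_j x_j b_ij / (sum_k b_kj
#' theta_k)`. Terms with `b_ij = 0` or `x_j = 0` contribute nothing; a
#' counted segment whose total rate is zero but with `b_ij > 0` yields
#' `+Inf` (the gradient points into the interior away from 0).
#'
#' @inheritParams gene_loglik
#' @param i isoform index.
#' @return gradient component (possibly `Inf`).
#' @export
gene_gradient <- function(theta, i, x, l, b, w) {
  if (any(theta < 0)) stop("theta must be non-negative")
  bi <- b[i, ]
  s <- as.vector(crossprod(b, theta))
  act <- x > 0 & bi > 0
  if (any(act & s <= 0)) return(Inf)
  -w * sum(l * bi) + sum(x[act] * bi[act] / s[act])
}

#' Binary interval search for the root of a monotone gradient
#'
#' Bisection on a nonincreasing function `g` over `[lo, hi]`. If
#' `g(lo) <= 0` the boundary `lo` is returned (maximum at the left edge,
#' e.g. theta clipped at 0); if `g(hi) >= 0`, `hi` is returned. Otherwise
#' the bracketing interval is halved until it is no wider than `eps` and
#' the midpoint is returned. The number of bisections never exceeds
#' `ceiling(log2((hi - lo) / eps))`.
#'
#' @param g function of one variable, nonincreasing on `[lo, hi]`; may
#'   return `+/-Inf` but not `NA`/`NaN` at the endpoints.
#' @param lo,hi interval bounds, `lo < hi`.
#' @param eps positive interval precision.
#' @return list with `root` and `iterations` (bisection count).
#' @export
bisect_root <- function(g, lo, hi, eps) {
  stopifnot(lo < hi, eps > 0)
  glo <- g(lo)
  ghi <- g(hi)
  if (is.na(glo) || is.na(ghi))
    stop("gradient is NA/NaN at a search interval endpoint")
  if (glo <= 0) return(list(root = lo, iterations = 0L))
  if (ghi >= 0) return(list(root = hi, iterations = 0L))
  kmax <- ceiling(log2((hi - lo) / eps))
  it <- 0L
  while (it < kmax && hi - lo > eps) {
    mid <- (lo + hi) / 2
    gm <- g(mid)
    if (is.na(gm)) stop("gradient is NA/NaN inside the search interval")
    it <- it + 1L
    if (gm > 0) lo <- mid else hi <- mid
  }
  list(root = (lo + hi) / 2, iterations = it)
}

#' Coordinate-wise binary search maximization of a concave function
#'
#' Cyclically maximizes a concave multivariate objective one coordinate at
#' a time; each 1-D subproblem is solved by [bisect_root()] on the partial
#' gradient, which is monotone nonincreasing by concavity. A coordinate
#' update is kept only if it does not decrease the objective, so the
#' recorded objective trace is non-decreasing; sweeps stop when a full
#' cycle improves the objective by less than `tol`.
#'
#' @param grad function `(theta, i)` returning the i-th partial derivative.
#' @param objective function `(theta)` returning the objective value.
#' @param start numeric start vector.
#' @param lower,upper per-coordinate search bounds (recycled).
#' @param eps 1-D interval precision.
#' @param max_sweeps maximum number of full sweeps.
#' @param tol sweep-improvement stopping tolerance.
#' @param order coordinate visiting order within a sweep.
#' @param accelerate after each sweep, additionally bisect along the net
#'   displacement direction of that sweep (a pattern move). Pure
#'   coordinate steps converge slowly along tilted ridges — e.g. when two
#'   isoforms have nearly collinear structure rows — and the diagonal
#'   step removes that stall; it is itself a binary search on the
#'   directional derivative, so monotone ascent is preserved.
#' @return list with `par`, `value`, `sweeps`, `converged`, `trace`
#'   (objective after every inner step) and `max_bisections`.
#' @export
coordinate_search <- function(grad, objective, start, lower = 0, upper,
                              eps = 1e-8, max_sweeps = 100L, tol = 1e-8,
                              order = seq_along(start),
                              accelerate = TRUE) {
  m <- length(start)
  lower <- rep_len(lower, m)
  upper <- rep_len(upper, m)
  theta <- pmin(pmax(start, lower), upper)
  val <- objective(theta)
  trace <- val
  converged <- FALSE
  max_bis <- 0L
  sweeps <- 0L
  for (s in seq_len(max_sweeps)) {
    sweeps <- s
    val0 <- val
    theta_sweep0 <- theta
    for (i in order) {
      g1 <- function(v) {
        th <- theta
        th[i] <- v
        grad(th, i)
      }
      r <- bisect_root(g1, lower[i], upper[i], eps)
      max_bis <- max(max_bis, r$iterations)
      cand <- theta
      cand[i] <- r$root
      vc <- objective(cand)
      if (vc >= val) {
        theta <- cand
        val <- vc
      }
      trace <- c(trace, val)
    }
    if (accelerate) {
      d <- theta - theta_sweep0
      nz <- which(d != 0)
      if (length(nz) > 0L) {
        tmax <- suppressWarnings(min(
          ifelse(d[nz] > 0, (upper[nz] - theta[nz]) / d[nz],
                 (lower[nz] - theta[nz]) / d[nz])))
        if (is.finite(tmax) && tmax > 0) {
          gdir <- function(t) {
            th <- theta + t * d
            sum(d[nz] * vapply(nz, function(i) grad(th, i), numeric(1)))
          }
          r <- tryCatch(
            bisect_root(gdir, 0, tmax, eps / max(abs(d[nz]))),
            error = function(e) NULL)
          if (!is.null(r) && r$root > 0) {
            cand <- theta + r$root * d
            vc <- objective(cand)
            if (vc >= val) {
              theta <- cand
              val <- vc
              trace <- c(trace, val)
            }
          }
        }
      }
    }
    if (val - val0 < tol) {
      converged <- TRUE
      break
    }
  }
  list(par = theta, value = val, sweeps = sweeps, converged = converged,
       trace = trace, max_bisections = max_bis)
}

#' Convert expression level theta to RPKM
#'
#' theta is expected reads per transcript base per sequenced read, so reads
#' per kilobase per million reads is `theta * 1e3 * 1e6 = theta * 1e9`.
#'
#' @param theta non-negative expression level(s).
#' @return RPKM value(s).
#' @export
theta_to_rpkm <- function(theta) {
  stopifnot(all(theta >= 0))
  theta * 1e9
}

#' Maximum-likelihood isoform expression for one gene's counts
#'
#' Maximizes [gene_loglik()] over `theta >= 0` by coordinate binary search.
#' Isoforms whose row of `b` is all zero are unidentifiable and fixed at 0
#' with a warning; genes with zero total counts return `theta = 0`
#' directly. Initialization splits the gene's read mass equally across
#' isoforms (`theta_i = sum(x) / (m w sum_j l_j b_ij)`); by concavity the
#' start point only affects speed, not the optimum.
#'
#' @inheritParams gene_loglik
#' @param config an [optimizer_config()].
#' @return list with `theta`, `loglik`, `sweeps`, `converged`,
#'   `max_bisections`, `trace`, and `unidentifiable` (logical per isoform).
#' @export
maximize_loglik <- function(x, l, b, w, config = optimizer_config()) {
  stopifnot(inherits(config, "optimizer_config"))
  m <- nrow(b)
  n <- ncol(b)
  stopifnot(length(x) == n, length(l) == n, all(x >= 0), all(l >= 1))
  # doubles throughout: integer counts/lengths/w overflow in products
  x <- as.numeric(x)
  l <- as.numeric(l)
  w <- as.numeric(w)
  storage.mode(b) <- "double"
  unident <- rowSums(b > 0) == 0L
  if (any(unident))
    warning(sum(unident), " isoform(s) with all-zero structure row; theta fixed at 0",
            call. = FALSE)
  theta <- numeric(m)
  if (sum(x) == 0 || all(unident)) {
    ll <- gene_loglik(theta, x, l, b, w)
    return(list(theta = theta, loglik = ll, sweeps = 0L, converged = TRUE,
                max_bisections = 0L, trace = ll, unidentifiable = unident))
  }
  act <- which(!unident)
  ba <- b[act, , drop = FALSE]
  tot <- sum(x)
  upper <- vapply(seq_along(act), function(k) {
    inc <- ba[k, ] > 0
    config$theta_upper_factor * tot / (w * min(l[inc] * ba[k, inc]))
  }, numeric(1))
  start <- if (!is.null(config$start)) {
    rep_len(config$start, length(act))
  } else {
    vapply(seq_along(act), function(k)
      tot / (length(act) * w * sum(l * ba[k, ])), numeric(1))
  }
  res <- coordinate_search(
    grad = function(th, i) gene_gradient(th, i, x, l, ba, w),
    objective = function(th) gene_loglik(th, x, l, ba, w),
    start = start, lower = 0, upper = upper, eps = config$eps,
    max_sweeps = config$max_sweeps, tol = config$loglik_tol)
  theta[act] <- res$par
  list(theta = theta, loglik = res$value, sweeps = res$sweeps,
       converged = res$converged, max_bisections = res$max_bisections,
       trace = res$trace, unidentifiable = unident)
}

#' Fit isoform expression for one gene
#'
#' Wraps [maximize_loglik()] for a [gene_model()] plus its segment counts,
#' and derives RPKM. Genes where two isoforms have identical rows of `b`
#' are flagged `ambiguous`: their expression split is not identifiable and
#' downstream evaluation can exclude or tie-break them explicitly.
#'
#' @param gene a [gene_model()].
#' @param x integer segment counts for the gene.
#' @param w library total read count.
#' @param b weighted structure matrix; defaults to the 0/1 inclusion matrix
#'   (uniform model).
#' @param config an [optimizer_config()].
#' @return list of class `isoform_fit` with `gene_id`, `isoform_ids`,
#'   `theta`, `rpkm`, `loglik`, `sweeps`, `converged`, `ambiguous`,
#'   `unidentifiable`, `gene_read_count`.
#' @export
fit_gene <- function(gene, x, w, b = NULL, config = optimizer_config()) {
  if (is.null(b)) b <- gene$inclusion
  stopifnot(nrow(b) == length(gene$isoform_ids),
            ncol(b) == nrow(gene$segments))
  res <- maximize_loglik(x, gene$segments$length, b, w, config)
  dup <- duplicated(b) | duplicated(b, fromLast = TRUE)
  structure(
    list(gene_id = gene$gene_id, isoform_ids = gene$isoform_ids,
         theta = res$theta, rpkm = theta_to_rpkm(res$theta),
         loglik = res$loglik, sweeps = res$sweeps,
         converged = res$converged,
         ambiguous = any(dup & !res$unidentifiable),
         unidentifiable = res$unidentifiable,
         gene_read_count = sum(x)),
    class = "isoform_fit")
}

#' @export
print.isoform_fit <- function(x, ...) {
  cat(sprintf("isoform_fit %s: logL = %.4f, %d reads, converged = %s\n",
              x$gene_id, x$loglik, x$gene_read_count, x$converged))
  print(data.frame(isoform = x$isoform_ids, theta = x$theta,
                   rpkm = x$rpkm))
  invisible(x)
}
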