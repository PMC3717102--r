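test_that("the log-likelihood equals the sum of Poisson log-probabilities", {
  # two segments of 100 bp, w = 1000, x = (10, 10), theta = 1e-4: rates 10
  b <- matrix(1, 1, 2)
  ll <- gene_loglik(1e-4, x = c(10, 10), l = c(100, 100), b = b, w = 1000)
  expect_equal(ll, -4.15712, tolerance = 1e-4)

  # theta = 0 with observed counts is impossible
  expect_equal(gene_loglik(0, c(10, 10), c(100, 100), b, 1000), -Inf)
  expect_error(gene_loglik(-1e-5, c(10, 10), c(100, 100), b, 1000),
               "non-negative")

  # x_j = 0 segments keep only the -lambda penalty (Poisson pmf at 0)
  expect_equal(gene_loglik(1e-4, c(0, 10), c(100, 100), b, 1000),
               oracle_loglik(1e-4, c(0, 10), c(100, 100), b, 1000))

  set.seed(101)
  for (rep in 1:100) {
    inst <- random_instance()
    th <- inst$theta_true * runif(inst$m, 0.2, 3)
    expect_equal(gene_loglik(th, inst$x, inst$l, inst$b, inst$w),
                 oracle_loglik(th, inst$x, inst$l, inst$b, inst$w),
                 tolerance = 1e-10)
  }
})

test_that("the gradient matches algebra and finite differences", {
  b <- matrix(1, 1, 2)
  # vanishes exactly at theta = sum(x) / (w * sum(l))
  expect_equal(gene_gradient(1e-4, 1, c(10, 10), c(100, 100), b, 1000), 0)
  expect_equal(gene_gradient(2e-4, 1, c(10, 10), c(100, 100), b, 1000),
               -1e5)
  # with all counts zero the gradient is the negative rate slope
  expect_equal(gene_gradient(5e-5, 1, c(0, 0), c(100, 100), b, 1000),
               -1000 * 200)
  # zero denominator with counts present points inward
  b2 <- rbind(c(1, 0), c(0, 1))
  expect_equal(gene_gradient(c(0, 1e-4), 1, c(5, 5), c(100, 100), b2, 1000),
               Inf)

  set.seed(111)
  h <- 1e-7
  for (rep in 1:50) {
    inst <- random_instance()
    th <- inst$theta_true * runif(inst$m, 0.5, 2) + 1e-5  # O(1e-5) scale
    for (i in seq_len(inst$m)) {
      up <- replace(th, i, th[i] + h)
      dn <- replace(th, i, th[i] - h)
      fd <- (gene_loglik(up, inst$x, inst$l, inst$b, inst$w) -
             gene_loglik(dn, inst$x, inst$l, inst$b, inst$w)) / (2 * h)
      an <- gene_gradient(th, i, inst$x, inst$l, inst$b, inst$w)
      expect_equal(an, fd, tolerance = 1e-4)
    }
  }
})

test_that("bisection finds monotone roots within the iteration bound", {
  r <- bisect_root(function(v) 3 - v, 0, 10, 1e-6)
  expect_equal(r$root, 3, tolerance = 1e-6)
  expect_lte(r$iterations, 24L)

  # everywhere-negative gradient: boundary optimum at the left edge
  r <- bisect_root(function(v) -1 - v, 0, 10, 1e-6)
  expect_equal(r$root, 0)
  expect_equal(r$iterations, 0L)
  # everywhere-positive: right edge
  expect_equal(bisect_root(function(v) 1, 0, 10, 1e-6)$root, 10)

  expect_error(bisect_root(function(v) NaN, 0, 1, 1e-3), "NaN")

  set.seed(121)
  for (rep in 1:50) {
    root <- runif(1, 0, 10)
    lohi <- sort(c(root - runif(1, 0.1, 5), root + runif(1, 0.1, 5)))
    eps <- 10^runif(1, -9, -3)
    r <- bisect_root(function(v) root - v, lohi[1], lohi[2], eps)
    expect_lte(abs(r$root - root), eps)
    expect_lte(r$iterations,
               ceiling(log2((lohi[2] - lohi[1]) / eps)))
  }
})

test_that("single-isoform estimates equal the closed form", {
  set.seed(131)
  for (rep in 1:30) {
    inst <- random_instance(m_max = 1L)
    if (sum(inst$x) == 0) next
    closed <- sum(inst$x) / (inst$w * sum(inst$l * inst$b[1, ]))
    # start away from the optimum so the search itself is exercised
    cfg <- optimizer_config(eps = 1e-15,
                            start = closed * 3)
    fit <- maximize_loglik(inst$x, inst$l, inst$b, inst$w, cfg)
    expect_equal(fit$theta, closed, tolerance = 1e-6)
    expect_true(fit$converged)
  }
})

test_that("the likelihood is concave and coordinate search ascends monotonically", {
  set.seed(141)
  for (rep in 1:20) {
    inst <- random_instance()
    f <- function(th) gene_loglik(th, inst$x, inst$l, inst$b, inst$w)
    for (k in 1:15) {
      ta <- inst$theta_true * runif(inst$m, 0.1, 5)
      tb <- inst$theta_true * runif(inst$m, 0.1, 5)
      lam <- runif(1)
      expect_gte(f(lam * ta + (1 - lam) * tb),
                 lam * f(ta) + (1 - lam) * f(tb) - 1e-9)
    }
    fit <- maximize_loglik(inst$x, inst$l, inst$b, inst$w)
    expect_true(all(diff(fit$trace) >= -1e-9))
  }
})

test_that("coordinate search matches an independent concave maximizer", {
  set.seed(151)
  cfg <- optimizer_config(eps = 1e-14, loglik_tol = 1e-12,
                          max_sweeps = 500L)
  for (rep in 1:40) {
    inst <- random_instance()
    fit <- maximize_loglik(inst$x, inst$l, inst$b, inst$w, cfg)
    # oracle: quasi-Newton with box constraints on a scaled objective
    sc <- (sum(inst$x) + 1) / (inst$w * sum(inst$l))
    nobj <- function(phi) {
      v <- oracle_loglik(phi * sc, inst$x, inst$l, inst$b, inst$w)
      if (!is.finite(v)) 1e300 else -v
    }
    o <- stats::nlminb(rep(1, inst$m), nobj, lower = 0,
                       control = list(rel.tol = 1e-14, iter.max = 500))
    ll_pkg <- oracle_loglik(fit$theta, inst$x, inst$l, inst$b, inst$w)
    expect_lt(abs(ll_pkg - (-o$objective)), 1e-6)
  }
})

test_that("the two-dimensional toy maximum is found from an off-axis start", {
  # separable concave bowl with maximum at (1, 2); search starts at
  # (2.5, 0.5) moving first along y
  grad <- function(th, i) c(-2 * (th[1] - 1), -2 * (th[2] - 2))[i]
  obj <- function(th) -(th[1] - 1)^2 - (th[2] - 2)^2
  r <- coordinate_search(grad, obj, start = c(2.5, 0.5), lower = -10,
                         upper = 10, eps = 1e-9, tol = 1e-12,
                         order = c(2L, 1L))
  expect_equal(r$par, c(1, 2), tolerance = 1e-6)
  expect_true(r$converged)
  expect_true(all(diff(r$trace) >= -1e-12))
})

test_that("degenerate genes are handled: zero counts, zero rows, ties", {
  g <- cassette_gene()
  fit <- fit_gene(g, c(0L, 0L, 0L), w = 1000L)
  expect_equal(fit$theta, c(0, 0))
  expect_true(fit$converged)
  expect_true(is.finite(fit$loglik))

  b <- rbind(c(1, 1, 1), c(0, 0, 0))
  expect_warning(fit <- fit_gene(g, c(10L, 10L, 10L), 1000L, b = b),
                 "all-zero")
  expect_equal(fit$theta[2], 0)
  expect_gt(fit$theta[1], 0)

  # identical structure rows are flagged ambiguous
  b <- rbind(c(1, 0, 1), c(1, 0, 1))
  expect_true(fit_gene(g, c(10L, 0L, 10L), 1000L, b = b)$ambiguous)
  expect_false(fit_gene(g, c(10L, 5L, 10L), 1000L)$ambiguous)
})

test_that("theta converts to RPKM by 1e9", {
  expect_equal(theta_to_rpkm(1e-4), 1e5)
  expect_equal(theta_to_rpkm(0), 0)
  # 1 kb gene, 1e6 reads, 500 of them on the gene: 500 RPKM
  seg <- data.frame(start = 0L, end = 1000L, length = 1000L)
  g <- gene_model("g", "chr1", "+", "t", seg, matrix(1L, 1, 1))
  fit <- fit_gene(g, x = 500L, w = 1e6)
  direct <- 500 / ((1000 / 1e3) * (1e6 / 1e6))
  expect_equal(fit$rpkm, direct, tolerance = 1e-6)
})
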