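test_that("distribution function matches its closed form and inverts exactly", {
  # (1-x)/x = 1 at x = 0.5, so F(0.5) = exp(-alpha) for any shape
  expect_equal(pnbuw(0.5, 0.5, 0.75), exp(-0.5), tolerance = 1e-15)
  expect_equal(pnbuw(0.5, 2, 9), exp(-2), tolerance = 1e-15)
  # upper endpoint is in the support with F(1) = 1
  expect_identical(pnbuw(1, 0.3, 4), 1)
  # closed-form median for alpha = beta = 1: 1/(1 + log 2)
  expect_equal(qnbuw(0.5, 1, 1), 1 / (1 + log(2)), tolerance = 1e-12)
  expect_equal(pnbuw(0.5906161, 1, 1), 0.5, tolerance = 1e-3)
  # q = exp(-alpha) maps back to 0.5 for any shape
  for (b in c(0.4, 1, 3.7))
    expect_equal(qnbuw(exp(-1.3), 1.3, b), 0.5, tolerance = 1e-12)
  # quantile o cdf = identity; the deep lower tail (F(0.1) ~ exp(-3156) for
  # alpha = 2.5, beta = 3.25) only round-trips through the log scale, where
  # the probability is representable
  for (x in c(0.1, 0.35, 0.9))
    expect_equal(qnbuw(pnbuw(x, 2.5, 3.25, log.p = TRUE), 2.5, 3.25,
                       log.p = TRUE), x, tolerance = 1e-10)
  # monotone non-decreasing on a grid, for every study parameter set
  grid <- seq(0.01, 0.99, length.out = 97)
  for (p in mle_param_grid) {
    logF <- pnbuw(grid, p[1], p[2], log.p = TRUE)
    expect_true(all(diff(logF) > 0))
    expect_true(all(logF < 0))
    expect_equal(qnbuw(logF, p[1], p[2], log.p = TRUE), grid,
                 tolerance = 1e-10)
  }
})

test_that("density normalizes, differentiates the cdf, and handles x = 1", {
  expect_equal(dnbuw(0.5, 1, 1), 4 * exp(-1), tolerance = 1e-14)
  for (p in mle_param_grid) {
    total <- integrate(dnbuw, 0, 1, alpha = p[1], beta = p[2],
                       rel.tol = 1e-10)$value
    expect_equal(total, 1, tolerance = 1e-8)
  }
  # pdf = d/dx cdf at an interior point
  expect_equal(dnbuw(0.3, 2, 1.75),
               num_deriv(function(x) pnbuw(x, 2, 1.75), 0.3),
               tolerance = 1e-6)
  # boundary x = 1: limit is +Inf, alpha, or 0 by shape
  expect_identical(dnbuw(1, 1, 0.5), Inf)
  expect_identical(dnbuw(1, 2, 3), 0)
  expect_equal(dnbuw(1, 1.7, 1), 1.7)
  # log-density identity and value
  expect_equal(exp(dnbuw(0.7, 0.75, 0.5, log = TRUE)),
               dnbuw(0.7, 0.75, 0.5), tolerance = 1e-12)
  expect_equal(dnbuw(0.5, 1, 1, log = TRUE), log(4) - 1, tolerance = 1e-14)
  # no overflow for extreme shapes (evaluated in log space)
  expect_true(is.finite(dnbuw(0.45, 1, 80, log = TRUE)))
  expect_true(is.finite(pnbuw(0.45, 1, 80, log.p = TRUE)))
})

test_that("printed hazard formula equals f/F, not the classical hazard", {
  # the exponential factor of f cancels against F: h * F = f pointwise
  xs <- c(0.1, 0.4, 0.5, 0.85)
  expect_equal(hnbuw(xs, 1.75, 1.5) * pnbuw(xs, 1.75, 1.5),
               dnbuw(xs, 1.75, 1.5), tolerance = 1e-12)
  expect_equal(hnbuw(0.4, 1.75, 1.5),
               dnbuw(0.4, 1.75, 1.5) / pnbuw(0.4, 1.75, 1.5),
               tolerance = 1e-12)
  expect_equal(hnbuw(0.5, 1, 1), 4)
  classical <- dnbuw(0.5, 1, 1) / pnbuw(0.5, 1, 1, lower.tail = FALSE)
  expect_equal(classical, 4 * exp(-1) / (1 - exp(-1)), tolerance = 1e-12)
  expect_gt(abs(hnbuw(0.5, 1, 1) - classical), 1.5)
})

test_that("random generation is reproducible and follows the distribution", {
  set.seed(123)
  x1 <- rnbuw(1000, 0.5, 0.75)
  set.seed(123)
  x2 <- rnbuw(1000, 0.5, 0.75)
  expect_identical(x1, x2)
  expect_true(all(x1 > 0 & x1 < 1))

  set.seed(42)
  n <- 1e5
  x <- rnbuw(n, 0.5, 0.75)
  ks <- suppressWarnings(ks.test(x, function(t) pnbuw(t, 0.5, 0.75)))
  expect_lt(unname(ks$statistic), 1.63 / sqrt(n))  # 1% KS critical value

  set.seed(7)
  med <- median(rnbuw(1e5, 1, 1))
  expect_equal(med, 0.5906, tolerance = 0.005 / 0.5906)
})

test_that("variance shrinks as the shape grows (mass concentrates at 1/2)", {
  vars <- vapply(c(2, 4, 8, 16), function(b) {
    g <- seq(0.001, 0.999, length.out = 2001)
    w <- dnbuw(g, 1, b)
    m <- sum(g * w) / sum(w)
    sum((g - m)^2 * w) / sum(w)
  }, numeric(1))
  expect_true(all(diff(vars) < 0))
})

test_that("domain violations are rejected with clear errors", {
  expect_error(dnbuw(0, 1, 1), "\\(0,1")
  expect_error(dnbuw(1.2, 1, 1), "\\(0,1")
  expect_error(pnbuw(-0.1, 1, 1), "\\(0,1")
  expect_error(qnbuw(0, 1, 1), "strictly inside")
  expect_error(qnbuw(1, 1, 1), "strictly inside")
  expect_error(dnbuw(0.5, -1, 1), "alpha")
  expect_error(dnbuw(0.5, 1, 0), "beta")
  expect_error(hnbuw(1, 1, 1), "\\(0,1")
})
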