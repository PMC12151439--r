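test_that("quantile parameterization is a substitution of the base form", {
  grid <- c(0.05, 0.3, 0.5, 0.7, 0.95)
  for (q in c(0.1, 0.5, 0.9)) {
    a <- nbuwq_alpha(0.3, 2, q)
    expect_gt(a, 0)
    expect_equal(dnbuwq(grid, 0.3, 2, q), dnbuw(grid, a, 2),
                 tolerance = 1e-14)
    expect_equal(pnbuwq(grid, 0.3, 2, q), pnbuw(grid, a, 2),
                 tolerance = 1e-14)
  }
  # mu = 0.5, q = 0.5 gives alpha = log 2
  expect_equal(nbuwq_alpha(0.5, 1, 0.5), log(2), tolerance = 1e-12)
  # density still normalizes after the substitution
  expect_equal(integrate(dnbuwq, 0, 1, mu = 0.3, beta = 2, q = 0.5,
                         rel.tol = 1e-10)$value, 1, tolerance = 1e-8)
})

test_that("mu is anchored as the q-th quantile", {
  for (b in c(0.5, 1, 2, 7)) for (q in c(0.1, 0.5, 0.9)) {
    expect_equal(pnbuwq(0.37, mu = 0.37, beta = b, q = q), q,
                 tolerance = 1e-12)
    expect_equal(qnbuwq(q, mu = 0.37, beta = b, q = q), 0.37,
                 tolerance = 1e-12)
  }
  expect_identical(pnbuwq(1, 0.3, 2), 1)
  for (u in c(0.05, 0.5, 0.95))
    expect_equal(pnbuwq(qnbuwq(u, 0.3, 2, 0.5), 0.3, 2, 0.5), u,
                 tolerance = 1e-10)
  # cross-parameterization: reparameterized quantile equals the base quantile
  # through the alpha map
  expect_equal(qnbuwq(0.25, 0.3, 2, 0.5),
               qnbuw(0.25, nbuwq_alpha(0.3, 2, 0.5), 2), tolerance = 1e-12)
})

test_that("logistic link is stable and self-inverse", {
  expect_identical(link_mu(0), 0.5)
  expect_lt(abs(link_mu(40) - 1), 1e-15)
  expect_lt(link_mu(-40), 1e-15)
  expect_equal(link_mu(log(0.37 / 0.63)), 0.37, tolerance = 1e-12)
})

test_that("regression log-likelihood is the sum of reparameterized log-densities", {
  set.seed(21)
  dat <- simulate_nbuwreg(80, c(0.5, -1), beta = 1.8, q = 0.3)
  X <- cbind(1, dat$x1)
  for (r in 1:5) {
    psi <- c(rnorm(2), runif(1, 0.5, 4))
    mu <- plogis(drop(X %*% psi[1:2]))
    direct <- sum(dnbuwq(dat$y, mu, psi[3], 0.3, log = TRUE))
    expect_equal(nbuwreg_loglik(psi, X, dat$y, q = 0.3), direct,
                 tolerance = 1e-10)
  }
})

test_that("intercept-only regression reduces to the plain distribution fit", {
  set.seed(33)
  y <- rnbuw(400, 1.5, 1.25)
  dat <- data.frame(y = y)
  reg <- nbuwreg(y ~ 1, data = dat, q = 0.5)
  dist_fit <- nbuw_fit(y)
  # same model, different parameterization: identical maximized likelihood
  expect_equal(reg$loglik, dist_fit$loglik, tolerance = 1e-6)
  # and mu-hat maps to alpha-hat through the quantile relation
  a_implied <- nbuwq_alpha(fitted(reg)[[1]], reg$shape, 0.5)
  expect_equal(a_implied, coef(dist_fit)[["alpha"]], tolerance = 1e-3,
               ignore_attr = TRUE)
})

test_that("regression fit recovers the generating parameters at large n", {
  dat <- simulate_nbuwreg(2e4, c(1.3, 1.4), beta = 2, q = 0.5, seed = 101)
  fit <- nbuwreg(y ~ x1, data = dat, q = 0.5)
  expect_true(fit$converged)
  expect_lt(abs(coef(fit)[["(Intercept)"]] - 1.3), 0.05)
  expect_lt(abs(coef(fit)[["x1"]] - 1.4), 0.05)
  expect_lt(abs(fit$shape - 2), 0.1)
  # local optimality: perturbing the coefficients lowers the likelihood
  X <- cbind(1, dat$x1)
  psi_hat <- c(fit$coefficients, fit$shape)
  for (shift in list(c(0.05, 0, 0), c(0, -0.05, 0), c(0, 0, 0.1)))
    expect_lt(nbuwreg_loglik(psi_hat + shift, X, dat$y, 0.5), fit$loglik)
  # AIC/BIC identities with p + 1 parameters
  expect_equal(fit$aic, -2 * fit$loglik + 2 * 3)
  expect_equal(fit$bic, -2 * fit$loglik + 3 * log(fit$n))
  # fitted quantile coverage: about q of responses fall below mu-hat
  expect_lt(abs(mean(dat$y < fitted(fit)) - 0.5), 0.02)
})

test_that("regression fit is exchangeable over rows and validates input", {
  dat <- simulate_nbuwreg(300, c(0.7, 0.4), beta = 3, q = 0.5, seed = 55)
  f1 <- nbuwreg(y ~ x1, data = dat)
  perm <- sample(nrow(dat))
  f2 <- nbuwreg(y ~ x1, data = dat[perm, ])
  expect_equal(coef(f1), coef(f2), tolerance = 1e-6)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
  # rank-deficient design rejected
  dat$x2 <- 2 * dat$x1
  expect_error(nbuwreg(y ~ x1 + x2, data = dat), "rank deficient")
  # response on the boundary
  dat2 <- dat[1:50, c("y", "x1")]
  dat2$y[1] <- 1
  expect_warning(nbuwreg(y ~ x1, data = dat2), "clamped")
  dat2$y[2] <- 0
  expect_error(suppressWarnings(nbuwreg(y ~ x1, data = dat2)), "\\(0,1")
})

test_that("simulated regression data hit the requested conditional quantile", {
  d1 <- simulate_nbuwreg(200, c(-2, 1), beta = 1.5, q = 0.1, seed = 8)
  d2 <- simulate_nbuwreg(200, c(-2, 1), beta = 1.5, q = 0.1, seed = 8)
  expect_identical(d1, d2)
  expect_true(all(d1$y > 0 & d1$y < 1))
  big <- simulate_nbuwreg(1e5, c(-2, 1), beta = 1.5, q = 0.1, seed = 9)
  frac <- mean(big$y < plogis(-2 + 1 * big$x1))
  expect_lt(abs(frac - 0.1), 0.01)
})

test_that("summary, predict and accessor methods are coherent", {
  dat <- simulate_nbuwreg(300, c(1, 0.5), beta = 2, q = 0.5, seed = 13)
  fit <- nbuwreg(y ~ x1, data = dat)
  s <- summary(fit)
  expect_identical(rownames(s$coefficients), c("(Intercept)", "x1", "(shape)"))
  expect_true(all(s$coefficients[, "Std. Error"] > 0))
  expect_equal(unname(coef(fit)[1:2]), unname(fit$coefficients))
  expect_identical(dim(vcov(fit)), c(3L, 3L))
  expect_equal(predict(fit), fitted(fit))
  nd <- data.frame(x1 = c(-1, 0, 1))
  expect_equal(predict(fit, nd, type = "link"),
               unname(fit$coefficients[1] + fit$coefficients[2] * nd$x1),
               tolerance = 1e-12, ignore_attr = TRUE)
})
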