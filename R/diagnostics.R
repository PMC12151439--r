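#' Residuals for bounded unit Weibull quantile regression
#'
#' Quantile residuals \eqn{\hat r_i = \Phi^{-1}(G(y_i;\hat\beta,\hat\mu_i))}
#' and Cox-Snell residuals \eqn{\hat e_i = -\log[1 - G(y_i)]}, with \eqn{G}
#' the fitted reparameterized distribution function. Under a correctly
#' specified model the quantile residuals are standard normal and the
#' Cox-Snell residuals are unit exponential. Because the response is
#' continuous, no randomization is involved: the probability integral
#' transform is applied directly. Fitted probabilities numerically equal to 0
#' or 1 are clamped to `[1e-12, 1 - 1e-12]` with a warning. The two residual
#' types are deterministic monotone transforms of one another:
#' `cox_snell = -log(1 - pnorm(quantile_residual))`.
#'
#' @param object a fitted [nbuwreg()] model.
#' @param type `"quantile"` (default) or `"cox-snell"`.
#' @param ... unused.
#' @return A numeric vector of residuals.
#' @examples
#' dat <- simulate_nbuwreg(200, delta = c(1, 0.5), beta = 2, seed = 5)
#' fit <- nbuwreg(y ~ x1, data = dat)
#' qr <- residuals(fit)                  # approx N(0,1)
#' cs <- residuals(fit, "cox-snell")     # approx Exp(1)
#' @export
residuals.nbuwreg <- function(object, type = c("quantile", "cox-snell"),
                              ...) {
  type <- match.arg(type)
  G <- pnbuwq(object$y, object$fitted.values, object$shape, object$q)
  out_of_range <- G < 1e-12 | G > 1 - 1e-12
  if (any(out_of_range)) {
    warning(sum(out_of_range),
            " fitted probabilities clamped to [1e-12, 1 - 1e-12]",
            call. = FALSE)
    G <- pmin(pmax(G, 1e-12), 1 - 1e-12)
  }
  if (type == "quantile") qnorm(G) else -log1p(-G)
}

#' One-sample Kolmogorov-Smirnov goodness-of-fit test
#'
#' Convenience wrapper around [stats::ks.test()] against the references used
#' in this package's diagnostics: the standard normal (for quantile
#' residuals), the unit exponential (for Cox-Snell residuals), or a fitted
#' NBUW distribution function. The p-value is the naive asymptotic one; it
#' does not correct for parameters having been estimated from the same data.
#'
#' @param x numeric sample (at least 5 observations).
#' @param reference `"std_normal"`, `"unit_exponential"` or `"nbuw"`.
#' @param alpha,beta NBUW parameters, required when `reference = "nbuw"`.
#' @return An object of class `"htest"` with the statistic and p-value.
#' @examples
#' set.seed(2)
#' ks_gof(rnorm(100), "std_normal")
#' x <- rnbuw(100, alpha = 1, beta = 2)
#' ks_gof(x, "nbuw", alpha = 1, beta = 2)
#' @export
ks_gof <- function(x, reference = c("std_normal", "unit_exponential", "nbuw"),
                   alpha = NULL, beta = NULL) {
  reference <- match.arg(reference)
  if (length(x) < 5L)
    stop("need at least 5 observations for the KS test", call. = FALSE)
  switch(reference,
         std_normal = ks.test(x, "pnorm"),
         unit_exponential = ks.test(x, "pexp", 1),
         nbuw = {
           .check_positive(alpha, "alpha"); .check_positive(beta, "beta")
           ks.test(x, function(t) pnbuw(t, alpha, beta))
         })
}

#' Information criteria from a log-likelihood
#'
#' `aic = -2 loglik + 2 k` and `bic = -2 loglik + k log(n)` for a model with
#' `k` estimated parameters and `n` observations. For the quantile
#' regression, `k` is the number of regression coefficients plus one for the
#' shape.
#'
#' @param loglik maximized log-likelihood.
#' @param n_params number of estimated parameters `k`.
#' @param n_obs number of observations `n` (`n >= k`).
#' @return A named numeric vector `c(aic =, bic =)`.
#' @examples
#' information_criteria(37.18, 4, 41)
#' @export
information_criteria <- function(loglik, n_params, n_obs) {
  if (n_params < 1 || n_obs < n_params)
    stop("need n_obs >= n_params >= 1", call. = FALSE)
  c(aic = -2 * loglik + 2 * n_params,
    bic = -2 * loglik + n_params * log(n_obs))
}

#' Half-normal plot of absolute quantile residuals with simulated envelope
#'
#' Plots the ordered absolute quantile residuals against half-normal
#' quantiles, with a pointwise simulated envelope obtained by refitting the
#' model to responses simulated from the fitted model. A well-specified model
#' keeps most points inside the envelope.
#'
#' @param object a fitted [nbuwreg()] model.
#' @param nsim number of simulated datasets for the envelope.
#' @param level pointwise envelope level.
#' @param ... passed to [plot()].
#' @return Invisibly, a list with the ordered absolute residuals and the
#'   envelope bounds.
#' @export
halfnormal_plot <- function(object, nsim = 100L, level = 0.95, ...) {
  if (!inherits(object, "nbuwreg"))
    stop("'object' must be a fitted nbuwreg model", call. = FALSE)
  n <- object$n
  obs <- sort(abs(residuals(object)))
  sims <- matrix(NA_real_, nrow = nsim, ncol = n)
  for (s in seq_len(nsim)) {
    ysim <- rnbuwq(n, object$fitted.values, object$shape, object$q)
    f <- .nbuwreg_fit(object$x, ysim, object$q, hessian = FALSE)
    G <- pnbuwq(ysim, plogis(drop(object$x %*% f$delta)), f$beta, object$q)
    G <- pmin(pmax(G, 1e-12), 1 - 1e-12)
    sims[s, ] <- sort(abs(qnorm(G)))
  }
  lo <- apply(sims, 2L, quantile, probs = (1 - level) / 2)
  hi <- apply(sims, 2L, quantile, probs = 1 - (1 - level) / 2)
  hq <- qnorm((seq_len(n) + n - 0.125) / (2 * n + 0.5))
  graphics::plot(hq, obs, xlab = "Half-normal quantiles",
                 ylab = "|quantile residual|", ...)
  graphics::lines(hq, lo, lty = 2)
  graphics::lines(hq, hi, lty = 2)
  invisible(list(abs_residuals = obs, lower = lo, upper = hi,
                 half_normal_q = hq))
}
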