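#' The bounded unit Weibull distribution
#'
#' Density, distribution function, quantile function, random generation and
#' reversed hazard for the bounded unit Weibull (NBUW) distribution with scale
#' parameter `alpha` and shape parameter `beta`, supported on (0, 1].
#'
#' The distribution arises by mapping a Weibull variate \eqn{Y} on
#' \eqn{(0,\infty)} to \eqn{X = 1/(1+Y)}. Writing \eqn{w = (1-x)/x}, the
#' distribution function is
#' \deqn{F(x) = \exp\{-\alpha w^{\beta}\}, \quad 0 < x \le 1,}
#' with density
#' \deqn{f(x) = \alpha\beta\, w^{\beta-1} x^{-2} \exp\{-\alpha w^{\beta}\},}
#' and closed-form quantile function
#' \deqn{Q(p) = \left[1 + (-\log p/\alpha)^{1/\beta}\right]^{-1}.}
#'
#' All powers of \eqn{w} are evaluated through `exp(beta * log(w))` with
#' `log(w) = log1p(-x) - log(x)`, so large shape values do not overflow.
#'
#' At the upper endpoint `x = 1` the density is a boundary case: it diverges
#' for `beta < 1`, is zero for `beta > 1`, and equals `alpha` for `beta = 1`;
#' `dnbuw` returns these limits. Likelihood-based code in this package clamps
#' observations exactly equal to 1 to `1 - 1e-10` (with a warning) before
#' evaluating the log-density.
#'
#' `hnbuw` evaluates \eqn{\alpha\beta w^{\beta-1} x^{-2}}. Note that this
#' quantity equals \eqn{f(x)/F(x)}, the *reversed* hazard rate, not the
#' classical hazard \eqn{f/(1-F)}: the exponential factor of \eqn{f} cancels
#' against \eqn{F}, not against the survival function. It is exposed under the
#' conventional hazard-style name because that is how the formula is used for
#' this family, but users needing the classical hazard should compute
#' `dnbuw(x, ...) / pnbuw(x, ..., lower.tail = FALSE)`.
#'
#' @param x,q vector of quantiles in (0, 1] ((0, 1) for `dnbuw`/`hnbuw`).
#' @param p vector of probabilities in (0, 1).
#' @param n number of observations to generate.
#' @param alpha positive scale-like parameter \eqn{\alpha}.
#' @param beta positive shape parameter \eqn{\beta}.
#' @param log,log.p logical; if `TRUE`, probabilities/densities are returned
#'   on the log scale.
#' @param lower.tail logical; if `TRUE` (default), probabilities are
#'   \eqn{P(X \le x)}.
#'
#' @return `dnbuw` gives the density, `pnbuw` the distribution function,
#'   `qnbuw` the quantile function, `rnbuw` random deviates and `hnbuw` the
#'   reversed hazard \eqn{f/F}. Values outside the support raise an error
#'   rather than returning `NaN`, since proportions outside (0, 1] indicate a
#'   data problem upstream.
#'
#' @examples
#' pnbuw(0.5, alpha = 0.5, beta = 0.75)   # exp(-0.5), since (1-x)/x = 1
#' qnbuw(0.5, alpha = 1, beta = 1)        # 1/(1 + log 2)
#' integrate(dnbuw, 0, 1, alpha = 1.5, beta = 1.25)
#' set.seed(1)
#' x <- rnbuw(500, alpha = 2, beta = 1.75)
#' @name nbuw-distribution
NULL

.recycle3 <- function(a, b, c) {
  n <- max(length(a), length(b), length(c))
  list(rep_len(a, n), rep_len(b, n), rep_len(c, n))
}

#' @rdname nbuw-distribution
#' @export
dnbuw <- function(x, alpha, beta, log = FALSE) {
  .check_positive(alpha, "alpha"); .check_positive(beta, "beta")
  .check_unit_open(x, "x", upper_closed = TRUE)
  r <- .recycle3(x, alpha, beta)
  x <- r[[1L]]; alpha <- r[[2L]]; beta <- r[[3L]]
  lw <- .logw(x)
  logf <- log(alpha) + log(beta) + (beta - 1) * lw - 2 * log(x) -
    alpha * exp(beta * lw)
  ## boundary x = 1: lw = -Inf; the limit is +Inf (beta<1), alpha (beta=1),
  ## 0 (beta>1).  (beta-1)*(-Inf) yields NaN only when beta == 1.
  at1 <- x == 1
  if (any(at1)) {
    b1 <- at1 & beta == 1
    logf[b1] <- log(alpha[b1])
    logf[at1 & beta > 1] <- -Inf
    logf[at1 & beta < 1] <- Inf
  }
  if (log) logf else exp(logf)
}

#' @rdname nbuw-distribution
#' @export
pnbuw <- function(q, alpha, beta, lower.tail = TRUE, log.p = FALSE) {
  .check_positive(alpha, "alpha"); .check_positive(beta, "beta")
  .check_unit_open(q, "q", upper_closed = TRUE)
  r <- .recycle3(q, alpha, beta)
  q <- r[[1L]]; alpha <- r[[2L]]; beta <- r[[3L]]
  logF <- -alpha * exp(beta * .logw(q))  # 0 at q = 1 since exp(-Inf) = 0
  if (lower.tail) {
    if (log.p) logF else exp(logF)
  } else {
    s <- -expm1(logF)
    if (log.p) log(s) else s
  }
}

#' @rdname nbuw-distribution
#' @export
qnbuw <- function(p, alpha, beta, lower.tail = TRUE, log.p = FALSE) {
  .check_positive(alpha, "alpha"); .check_positive(beta, "beta")
  ## work with -log(P(X <= x)) throughout so deep-tail log probabilities
  ## (unrepresentable on the raw scale) still invert correctly
  if (log.p) {
    if (!is.numeric(p) || any(is.na(p)) || any(p >= 0))
      stop("log-probabilities must be negative", call. = FALSE)
    nlp <- if (lower.tail) -p else -log1p(-exp(p))
  } else {
    if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
      stop("probabilities must lie strictly inside (0,1)", call. = FALSE)
    nlp <- -log(if (lower.tail) p else 1 - p)
  }
  r <- .recycle3(nlp, alpha, beta)
  nlp <- r[[1L]]; alpha <- r[[2L]]; beta <- r[[3L]]
  ## Q(p) = 1 / (1 + (-log p / alpha)^(1/beta)), in log space
  1 / (1 + exp((log(nlp) - log(alpha)) / beta))
}

#' @rdname nbuw-distribution
#' @export
rnbuw <- function(n, alpha, beta) {
  .check_positive(alpha, "alpha"); .check_positive(beta, "beta")
  qnbuw(runif(n), alpha, beta)
}

#' @rdname nbuw-distribution
#' @export
hnbuw <- function(x, alpha, beta, log = FALSE) {
  .check_positive(alpha, "alpha"); .check_positive(beta, "beta")
  .check_unit_open(x, "x")
  r <- .recycle3(x, alpha, beta)
  x <- r[[1L]]; alpha <- r[[2L]]; beta <- r[[3L]]
  logh <- log(alpha) + log(beta) + (beta - 1) * .logw(x) - 2 * log(x)
  if (log) logh else exp(logh)
}
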