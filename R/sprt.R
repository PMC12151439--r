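#' Sequential probability ratio test for the bounded unit Weibull shape
#'
#' Wald's SPRT for `H0: beta = beta0` against `H1: beta = beta1`
#' (`beta1 > beta0`) with the scale parameter `alpha` treated as known.
#' Observations arrive one at a time; each contributes the log likelihood
#' ratio increment
#' \deqn{\xi_i = \log(\beta_1/\beta_0) + (\beta_1-\beta_0)\log w_i
#'       - \alpha w_i^{\beta_1} + \alpha w_i^{\beta_0}, \quad w_i = (1-x_i)/x_i,}
#' and sampling stops the first time the cumulative sum leaves the interval
#' `(log B, log A)` with Wald boundaries `A = (1-psi)/delta`,
#' `B = psi/(1-delta)`, where `delta` and `psi` are the nominal type-I and
#' type-II error probabilities. Boundary hits use `<=` / `>=`; overshoot is
#' not corrected, so realized error rates carry the usual Wald-approximation
#' slack.
#'
#' @param x numeric vector of observations in (0, 1), in arrival order.
#' @param alpha known positive scale parameter.
#' @param beta0,beta1 hypothesized shape values, `0 < beta0 < beta1`.
#' @param delta nominal type-I error probability in (0, 1).
#' @param psi nominal type-II error probability in (0, 1).
#'
#' @return `nbuw_sprt` returns an object of class `"nbuw_sprt"`: a list with
#'   `decision` (`"accept_H0"`, `"reject_H0"` or `"continue"`), `n_used`,
#'   `log_lambda` (cumulative statistic at stopping, 0 for an empty stream),
#'   `trace` (per-observation cumulative sums up to `n_used`), the boundaries
#'   and the configuration. `sprt_increment` returns the per-observation
#'   increments; `sprt_boundaries` returns `c(logA =, logB =)`.
#'
#' @examples
#' sprt_boundaries(0.05, 0.05)           # log(19), -log(19)
#' set.seed(7)
#' x <- rnbuw(200, alpha = 1, beta = 1.5)
#' nbuw_sprt(x, alpha = 1, beta0 = 0.75, beta1 = 1.5)
#' @export
nbuw_sprt <- function(x, alpha, beta0, beta1, delta = 0.05, psi = 0.05) {
  cfg <- .sprt_check(alpha, beta0, beta1, delta, psi)
  b <- sprt_boundaries(delta, psi)
  if (length(x) == 0L) {
    return(structure(list(decision = "continue", n_used = 0L, log_lambda = 0,
                          trace = numeric(0), logA = b[["logA"]],
                          logB = b[["logB"]], config = cfg),
                     class = "nbuw_sprt"))
  }
  cum <- cumsum(sprt_increment(x, alpha, beta0, beta1))
  hit <- which(cum >= b[["logA"]] | cum <= b[["logB"]])
  if (length(hit)) {
    n <- hit[1L]
    decision <- if (cum[n] >= b[["logA"]]) "reject_H0" else "accept_H0"
  } else {
    n <- length(x)
    decision <- "continue"
  }
  structure(list(decision = decision, n_used = n, log_lambda = cum[n],
                 trace = cum[seq_len(n)], logA = b[["logA"]],
                 logB = b[["logB"]], config = cfg),
            class = "nbuw_sprt")
}

.sprt_check <- function(alpha, beta0, beta1, delta, psi) {
  .check_positive(alpha, "alpha")
  .check_positive(beta0, "beta0"); .check_positive(beta1, "beta1")
  if (length(beta0) != 1L || length(beta1) != 1L || beta1 <= beta0)
    stop("'beta1' must exceed 'beta0'", call. = FALSE)
  for (nm in c("delta", "psi")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v >= 1)
      stop("'", nm, "' must be a single probability in (0,1)", call. = FALSE)
  }
  list(alpha = alpha, beta0 = beta0, beta1 = beta1, delta = delta, psi = psi)
}

#' @export
print.nbuw_sprt <- function(x, ...) {
  cat("Sequential probability ratio test (bounded unit Weibull shape)\n")
  cfg <- x$config
  cat(sprintf("  H0: beta = %g  vs  H1: beta = %g   (alpha = %g known)\n",
              cfg$beta0, cfg$beta1, cfg$alpha))
  cat(sprintf("  boundaries: log B = %.4f, log A = %.4f (delta = %g, psi = %g)\n",
              x$logB, x$logA, cfg$delta, cfg$psi))
  cat(sprintf("  decision: %s after %d observation(s), log lambda = %.4f\n",
              x$decision, x$n_used, x$log_lambda))
  invisible(x)
}

#' @rdname nbuw_sprt
#' @export
sprt_increment <- function(x, alpha, beta0, beta1) {
  .sprt_check(alpha, beta0, beta1, 0.5, 0.5)
  .check_unit_open(x, "x")
  lw <- .logw(x)
  log(beta1 / beta0) + (beta1 - beta0) * lw -
    alpha * exp(beta1 * lw) + alpha * exp(beta0 * lw)
}

#' @rdname nbuw_sprt
#' @export
sprt_boundaries <- function(delta, psi) {
  for (nm in c("delta", "psi")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v >= 1)
      stop("'", nm, "' must be a single probability in (0,1)", call. = FALSE)
  }
  c(logA = log((1 - psi) / delta), logB = log(psi / (1 - delta)))
}

#' Operating characteristic and average sample number of the SPRT
#'
#' `sprt_oc` gives the probability of accepting H0 as a function of the true
#' shape. At the hypothesized points the Wald nominal values are available in
#' closed form: `L(beta0) = 1 - delta` and `L(beta1) = psi`. No interpolation
#' between them is attempted; at any other shape value the OC is estimated by
#' Monte Carlo (`method = "monte_carlo"`), running the full sequential test on
#' simulated streams.
#'
#' `sprt_asn` gives Wald's approximate expected stopping time
#' \deqn{E_\beta(N) = \frac{L(\beta)\log B + (1-L(\beta))\log A}{E_\beta(\xi)}.}
#' Two variants of the numerator under H1 are reported: the `"printed"` form
#' \eqn{\delta\log B + (1-\psi)\log A} and the `"standard"` Wald form
#' \eqn{\psi\log B + (1-\psi)\log A} (weight `L(beta1) = psi` on `log B`);
#' they coincide when `delta == psi`. Under H0 both forms agree:
#' \eqn{(1-\delta)\log B + \delta\log A}. The denominator
#' \eqn{E_\beta(\xi) = \int_0^1 \xi(x) f(x;\alpha,\beta)\,dx} is computed by
#' adaptive quadrature.
#'
#' @inheritParams nbuw_sprt
#' @param beta_true true shape parameter at which to evaluate the OC.
#' @param method `"nominal"` (only at `beta0`/`beta1`) or `"monte_carlo"`.
#' @param nsim number of Monte Carlo streams.
#' @param max_n cap on the stream length per simulated test.
#' @param hypothesis `"H0"` or `"H1"`.
#' @param form which ASN numerator to return under H1 (see Details).
#'
#' @return `sprt_oc` returns a probability. `sprt_asn` returns the ASN with
#'   attributes `e_xi` (the expected increment) and `asn_standard` (the
#'   standard-form value, identical under H0).
#'
#' @examples
#' sprt_oc(0.75, alpha = 1, beta0 = 0.75, beta1 = 1.5)     # 1 - delta
#' sprt_asn("H0", alpha = 1, beta0 = 0.75, beta1 = 1.5)
#' @export
sprt_oc <- function(beta_true, alpha, beta0, beta1, delta = 0.05, psi = 0.05,
                    method = c("nominal", "monte_carlo"), nsim = 5000L,
                    max_n = 100000L) {
  method <- match.arg(method)
  .sprt_check(alpha, beta0, beta1, delta, psi)
  .check_positive(beta_true, "beta_true")
  if (method == "nominal") {
    if (isTRUE(all.equal(beta_true, beta0))) return(1 - delta)
    if (isTRUE(all.equal(beta_true, beta1))) return(psi)
    stop("nominal OC values are only defined at beta0 and beta1; ",
         "use method = \"monte_carlo\" for other shape values", call. = FALSE)
  }
  mc <- .sprt_mc(alpha, beta_true, beta0, beta1, delta, psi, nsim, max_n)
  mean(mc$decision == "accept_H0")
}

#' @rdname sprt_oc
#' @export
sprt_asn <- function(hypothesis = c("H0", "H1"), alpha, beta0, beta1,
                     delta = 0.05, psi = 0.05,
                     form = c("printed", "standard")) {
  hypothesis <- match.arg(hypothesis)
  form <- match.arg(form)
  .sprt_check(alpha, beta0, beta1, delta, psi)
  b <- sprt_boundaries(delta, psi)
  beta_true <- if (hypothesis == "H0") beta0 else beta1
  e_xi <- .sprt_e_xi(alpha, beta_true, beta0, beta1)
  if (abs(e_xi) < 1e-12)
    stop("E(xi) is numerically zero under ", hypothesis,
         "; the Wald ASN approximation is degenerate", call. = FALSE)
  if (hypothesis == "H0") {
    num_printed <- (1 - delta) * b[["logB"]] + delta * b[["logA"]]
    num_standard <- num_printed
  } else {
    num_printed <- delta * b[["logB"]] + (1 - psi) * b[["logA"]]
    num_standard <- psi * b[["logB"]] + (1 - psi) * b[["logA"]]
  }
  num <- if (form == "printed") num_printed else num_standard
  structure(num / e_xi, e_xi = e_xi, asn_standard = num_standard / e_xi)
}

## E_beta[xi] by quadrature in t = alpha * w^beta ~ Exp(1) space
.sprt_e_xi <- function(alpha, beta_true, beta0, beta1) {
  integrand <- function(t) {
    lw <- (log(t) - log(alpha)) / beta_true
    exp(-t) * (log(beta1 / beta0) + (beta1 - beta0) * lw -
                 alpha * exp(beta1 * lw) + alpha * exp(beta0 * lw))
  }
  integrate(integrand, 0, Inf, rel.tol = 1e-10)$value
}

## Vectorized Monte Carlo SPRT runner: simulates nsim streams under
## NBUW(alpha, beta_true) and runs each test to termination (or max_n).
.sprt_mc <- function(alpha, beta_true, beta0, beta1, delta, psi,
                     nsim, max_n = 100000L, chunk = 64L) {
  b <- sprt_boundaries(delta, psi)
  cum <- numeric(nsim)
  n_stop <- integer(nsim)
  decision <- character(nsim)
  active <- rep(TRUE, nsim)
  taken <- 0L
  while (any(active) && taken < max_n) {
    na <- sum(active)
    k <- min(chunk, max_n - taken)
    incr <- matrix(sprt_increment(rnbuw(na * k, alpha, beta_true),
                                  alpha, beta0, beta1), nrow = na)
    run <- cum[active]
    stopped_at <- integer(na)
    dec <- character(na)
    for (j in seq_len(k)) {
      open <- stopped_at == 0L
      if (!any(open)) break
      run[open] <- run[open] + incr[open, j]
      up <- open & run >= b[["logA"]]
      dn <- open & run <= b[["logB"]]
      stopped_at[up] <- j; dec[up] <- "reject_H0"
      stopped_at[dn] <- j; dec[dn] <- "accept_H0"
    }
    idx <- which(active)
    done <- stopped_at > 0L
    cum[idx] <- run
    n_stop[idx[done]] <- taken + stopped_at[done]
    decision[idx[done]] <- dec[done]
    active[idx[done]] <- FALSE
    taken <- taken + k
  }
  if (any(active)) {
    decision[active] <- "continue"
    n_stop[active] <- taken
  }
  list(decision = decision, n_stop = n_stop, log_lambda = cum)
}
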