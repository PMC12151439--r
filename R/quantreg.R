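#' Quantile-parameterized bounded unit Weibull distribution
#'
#' The NBUW distribution reparameterized so that `mu` is its `q`-th quantile.
#' Solving \eqn{Q_q(\alpha,\beta) = \mu} for the scale gives
#' \deqn{\alpha(\mu,\beta,q) = -\left(\tfrac{1}{\mu}-1\right)^{-\beta}\log q
#'   = -\log q \, e^{\beta\,\mathrm{logit}(\mu)},}
#' which is strictly positive since \eqn{\log q < 0}. All four functions are
#' thin wrappers that map `(mu, beta, q)` to `(alpha, beta)` and call the base
#' parameterization, so the two forms are a single code path and agree to
#' machine precision; in particular `pnbuwq(mu, mu, beta, q)` equals `q`
#' exactly for any shape. The quantile function
#' \deqn{Q(u) = \left[\left(\log u/\log q\right)^{1/\beta}
#'   (1/\mu - 1) + 1\right]^{-1}}
#' is used for inverse-transform random generation.
#'
#' @param x,y vector of quantiles in (0, 1] ((0, 1) for the density).
#' @param u vector of probabilities in (0, 1).
#' @param n number of draws.
#' @param mu the `q`-th quantile of the distribution, in (0, 1).
#' @param beta positive shape parameter.
#' @param q fixed, known quantile level in (0, 1); `q = 0.5` parameterizes by
#'   the median.
#' @param log,log.p,lower.tail as in [dnbuw()].
#'
#' @return Density, distribution function, quantile function and random
#'   deviates of the quantile-parameterized form. `nbuwq_alpha` returns the
#'   implied scale \eqn{\alpha(\mu,\beta,q)}.
#'
#' @examples
#' pnbuwq(0.3, mu = 0.3, beta = 2, q = 0.5)   # exactly 0.5
#' qnbuwq(0.5, mu = 0.3, beta = 2, q = 0.5)   # exactly 0.3
#' @name nbuwq-distribution
NULL

#' @rdname nbuwq-distribution
#' @export
nbuwq_alpha <- function(mu, beta, q = 0.5) {
  .check_unit_open(mu, "mu"); .check_positive(beta, "beta")
  .check_unit_open(q, "q")
  -log(q) * exp(beta * qlogis(mu))
}

#' @rdname nbuwq-distribution
#' @export
dnbuwq <- function(x, mu, beta, q = 0.5, log = FALSE) {
  dnbuw(x, nbuwq_alpha(mu, beta, q), beta, log = log)
}

#' @rdname nbuwq-distribution
#' @export
pnbuwq <- function(y, mu, beta, q = 0.5, lower.tail = TRUE, log.p = FALSE) {
  pnbuw(y, nbuwq_alpha(mu, beta, q), beta, lower.tail = lower.tail,
        log.p = log.p)
}

#' @rdname nbuwq-distribution
#' @export
qnbuwq <- function(u, mu, beta, q = 0.5, lower.tail = TRUE, log.p = FALSE) {
  qnbuw(u, nbuwq_alpha(mu, beta, q), beta, lower.tail = lower.tail,
        log.p = log.p)
}

#' @rdname nbuwq-distribution
#' @export
rnbuwq <- function(n, mu, beta, q = 0.5) {
  qnbuwq(runif(n), mu, beta, q)
}

#' Logistic link, evaluated stably
#'
#' Maps a linear predictor to (0, 1) via \eqn{e^\eta/(1+e^\eta)} without
#' overflow for large `|eta|` (delegates to [stats::plogis()]).
#'
#' @param eta numeric vector of linear predictors.
#' @return Values in (0, 1).
#' @examples
#' link_mu(0)     # 0.5
#' link_mu(40)    # 1 - 4.2e-18, no overflow
#' @export
link_mu <- function(eta) {
  if (!is.numeric(eta) || any(is.na(eta)))
    stop("'eta' must be numeric and non-missing", call. = FALSE)
  plogis(eta)
}

#' Bounded unit Weibull quantile regression
#'
#' Fits a parametric quantile regression for a response in (0, 1): the
#' response follows the quantile-parameterized NBUW distribution whose `q`-th
#' conditional quantile \eqn{\mu_i} is linked to covariates by
#' \eqn{\mathrm{logit}(\mu_i) = x_i^\top\delta}. All parameters
#' \eqn{(\delta, \beta)} are estimated jointly by maximum likelihood.
#'
#' Writing \eqn{\eta_i = x_i^\top\delta}, \eqn{w_i = (1-y_i)/y_i} and
#' \eqn{t_i = \eta_i + \log w_i}, the log-likelihood is
#' \deqn{\ell(\delta,\beta) = n\log\beta + n\log(-\log q) + \beta\sum\eta_i
#'   + (\beta-1)\sum\log w_i - 2\sum\log y_i + \log q\sum e^{\beta t_i},}
#' identically \eqn{\sum_i \log \pi(y_i;\beta,\mu_i,q)} with \eqn{\pi} the
#' reparameterized density (the last term carries the exponent \eqn{\beta} on
#' \eqn{w_i}, as the density requires). Optimization is BFGS over
#' \eqn{(\delta, \log\beta)} with the analytic gradient; standard errors come
#' from the analytic observed information in the natural parameterization.
#'
#' Responses exactly 0 are rejected; responses exactly 1 are clamped to
#' `1 - 1e-10` with a warning.
#'
#' @param formula a model formula for the response and covariates.
#' @param data a data frame containing the variables in the formula.
#' @param q quantile level being modeled, in (0, 1); default 0.5 (median
#'   regression).
#' @param start optional starting values `c(delta, beta)`; by default
#'   `delta` starts at the least-squares fit of `qlogis(y)` on the design and
#'   `beta` at 1.
#' @param ... currently unused.
#'
#' @return An object of class `"nbuwreg"`: a list with `coefficients`
#'   (regression coefficients \eqn{\hat\delta}), `shape` (\eqn{\hat\beta}),
#'   `vcov` ((p+1) x (p+1), shape last), `loglik`, `aic`, `bic`,
#'   `fitted.values` (fitted conditional quantiles \eqn{\hat\mu_i}),
#'   `linear.predictors`, `converged`, `q`, `n`, and the model ingredients.
#'   Methods: `print`, `summary` (Wald z tests), `coef`, `vcov`, `logLik`,
#'   `fitted`, `residuals` (see [residuals.nbuwreg()]), `predict`.
#'
#' @examples
#' dat <- simulate_nbuwreg(200, delta = c(1.3, 1.4), beta = 2, q = 0.5,
#'                         seed = 1)
#' fit <- nbuwreg(y ~ x1, data = dat, q = 0.5)
#' summary(fit)
#' @export
nbuwreg <- function(formula, data, q = 0.5, start = NULL, ...) {
  .check_unit_open(q, "q")
  mf <- model.frame(formula, data)
  y <- model.response(mf)
  X <- model.matrix(attr(mf, "terms"), mf)
  y <- .clamp_unit(y, name = "response")
  if (qr(X)$rank < ncol(X))
    stop("design matrix is rank deficient", call. = FALSE)
  if (nrow(X) <= ncol(X) + 1L)
    stop("need more observations than parameters", call. = FALSE)
  fit <- .nbuwreg_fit(X, y, q, start = start)
  k <- ncol(X) + 1L
  n <- nrow(X)
  structure(list(coefficients = setNames(fit$delta, colnames(X)),
                 shape = fit$beta, vcov = fit$vcov, se = fit$se,
                 loglik = fit$loglik,
                 aic = -2 * fit$loglik + 2 * k,
                 bic = -2 * fit$loglik + k * log(n),
                 fitted.values = fit$fitted_mu,
                 linear.predictors = fit$eta,
                 converged = fit$converged, q = q, n = n, df = k,
                 y = y, x = X, call = match.call(),
                 terms = attr(mf, "terms")),
            class = "nbuwreg")
}

## Core fitting routine on a prepared design matrix and response.
## Returns point estimates (and vcov when hessian = TRUE) without any of the
## formula/method scaffolding, for use in simulation loops.
.nbuwreg_fit <- function(X, y, q, start = NULL, hessian = TRUE) {
  n <- nrow(X); p <- ncol(X)
  lw <- .logw(y)
  slw <- sum(lw)
  sly <- sum(log(y))
  lq <- log(q)
  llnq <- log(-lq)
  negll <- function(par) {
    eta <- drop(X %*% par[seq_len(p)])
    b <- exp(par[p + 1L])
    bt <- b * (eta + lw)
    if (any(bt > 700)) return(1e10)  # e^{bt} would overflow; reject step
    -(n * par[p + 1L] + n * llnq + b * sum(eta) + (b - 1) * slw - 2 * sly +
        lq * sum(exp(bt)))
  }
  neggrad <- function(par) {
    eta <- drop(X %*% par[seq_len(p)])
    b <- exp(par[p + 1L])
    t <- eta + lw
    s <- exp(pmin(b * t, 700))
    gd <- b * drop(crossprod(X, 1 + lq * s))
    gb <- n + b * (sum(eta) + slw) + b * lq * sum(t * s)
    -c(gd, gb)
  }
  if (is.null(start)) {
    delta0 <- tryCatch(qr.solve(X, qlogis(y)), error = function(e) rep(0, p))
    par0 <- c(delta0, 0)
  } else {
    if (length(start) != p + 1L || start[p + 1L] <= 0)
      stop("'start' must be c(delta, beta) with beta > 0", call. = FALSE)
    par0 <- c(start[seq_len(p)], log(start[p + 1L]))
  }
  opt <- optim(par0, negll, neggrad, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  if (opt$convergence != 0) {
    ## one retry from a neutral start
    opt2 <- optim(c(rep(0, p), 0), negll, neggrad, method = "BFGS",
                  control = list(maxit = 500, reltol = 1e-12))
    if (opt2$value < opt$value) opt <- opt2
  }
  delta <- opt$par[seq_len(p)]
  b <- exp(opt$par[p + 1L])
  eta <- drop(X %*% delta)
  out <- list(delta = delta, beta = b, loglik = -opt$value,
              eta = eta, fitted_mu = plogis(eta),
              converged = opt$convergence == 0)
  if (hessian) {
    info <- .nbuwreg_obs_info(X, lw, eta, b, lq)
    vc <- tryCatch(solve(info),
                   error = function(e) matrix(NA_real_, p + 1L, p + 1L))
    nms <- c(colnames(X), "(shape)")
    dimnames(vc) <- list(nms, nms)
    out$vcov <- vc
    out$se <- setNames(sqrt(pmax(diag(vc), 0)), nms)
    out$converged <- out$converged && all(is.finite(out$se))
  }
  out
}

## analytic observed information in the natural (delta, beta) parameters
.nbuwreg_obs_info <- function(X, lw, eta, b, lq) {
  t <- eta + lw
  s <- exp(pmin(b * t, 700))
  n <- nrow(X)
  H_dd <- crossprod(X * (b^2 * lq * s), X)
  H_db <- drop(crossprod(X, 1 + lq * s * (1 + b * t)))
  H_bb <- -n / b^2 + lq * sum(t^2 * s)
  -rbind(cbind(H_dd, H_db), c(H_db, H_bb))
}

#' Log-likelihood of the quantile regression model
#'
#' Evaluates the NBUW quantile-regression log-likelihood at an arbitrary
#' parameter vector; equals `sum(dnbuwq(y, mu, beta, q, log = TRUE))` with
#' `mu = plogis(X delta)`.
#'
#' @param psi parameter vector `c(delta, beta)` (shape last, positive).
#' @param X design matrix (n x p, including the intercept column).
#' @param y response vector in (0, 1).
#' @param q quantile level in (0, 1).
#' @return The log-likelihood value.
#' @examples
#' dat <- simulate_nbuwreg(50, delta = c(0.5, 1), beta = 2, seed = 3)
#' X <- cbind(1, dat$x1)
#' nbuwreg_loglik(c(0.5, 1, 2), X, dat$y, q = 0.5)
#' @export
nbuwreg_loglik <- function(psi, X, y, q = 0.5) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (length(psi) != p + 1L)
    stop("'psi' must have length ncol(X) + 1 (shape last)", call. = FALSE)
  .check_positive(psi[p + 1L], "beta")
  .check_unit_open(q, "q")
  y <- .clamp_unit(y, name = "y")
  n <- length(y)
  lw <- .logw(y)
  eta <- drop(X %*% psi[seq_len(p)])
  b <- psi[p + 1L]
  n * log(b) + n * log(-log(q)) + b * sum(eta) + (b - 1) * sum(lw) -
    2 * sum(log(y)) + log(q) * sum(exp(b * (eta + lw)))
}

#' Simulate data from the quantile regression model
#'
#' Generates a regression dataset under the data-generating process used by
#' the parameter-recovery study: covariates are independent standard normal,
#' the conditional `q`-th quantile is `mu_i = plogis(delta[1] + delta[2]*x1 +
#' ...)`, and responses are drawn by inverse transform from the
#' quantile-parameterized NBUW distribution with shape `beta`.
#'
#' @param n sample size.
#' @param delta coefficient vector (intercept first); `length(delta) - 1`
#'   covariates are generated.
#' @param beta positive shape parameter.
#' @param q quantile level in (0, 1).
#' @param seed optional integer seed for reproducibility.
#' @return A data frame with columns `y`, `x1`, `x2`, ... and attributes
#'   `delta`, `beta`, `q`.
#' @examples
#' dat <- simulate_nbuwreg(100, delta = c(-2, 1), beta = 1.5, q = 0.1,
#'                         seed = 11)
#' mean(dat$y < plogis(-2 + 1 * dat$x1))  # close to q for large n
#' @export
simulate_nbuwreg <- function(n, delta, beta, q = 0.5, seed = NULL) {
  .check_positive(beta, "beta"); .check_unit_open(q, "q")
  if (length(delta) < 1L) stop("'delta' must be non-empty", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  ncov <- length(delta) - 1L
  Z <- matrix(rnorm(n * ncov), nrow = n)
  eta <- delta[1L] + if (ncov > 0L) drop(Z %*% delta[-1L]) else 0
  mu <- plogis(eta)
  y <- qnbuwq(runif(n), mu, beta, q)
  out <- data.frame(y = y)
  if (ncov > 0L) {
    colnames(Z) <- paste0("x", seq_len(ncov))
    out <- cbind(out, as.data.frame(Z))
  }
  attr(out, "delta") <- delta
  attr(out, "beta") <- beta
  attr(out, "q") <- q
  out
}

#' @export
print.nbuwreg <- function(x, digits = 4, ...) {
  cat(sprintf("Bounded unit Weibull quantile regression (q = %g)\n", x$q))
  cat("Coefficients (logit link on the conditional quantile):\n")
  print(round(x$coefficients, digits))
  cat(sprintf("Shape: %.*f   logLik: %.*f   AIC: %.*f   BIC: %.*f\n",
              digits, x$shape, digits, x$loglik, digits, x$aic,
              digits, x$bic))
  if (!x$converged) cat("Warning: optimizer did not converge\n")
  invisible(x)
}

#' @export
coef.nbuwreg <- function(object, ...) {
  c(object$coefficients, "(shape)" = object$shape)
}

#' @export
vcov.nbuwreg <- function(object, ...) object$vcov

#' @export
logLik.nbuwreg <- function(object, ...) {
  structure(object$loglik, df = object$df, nobs = object$n, class = "logLik")
}

#' @export
fitted.nbuwreg <- function(object, ...) object$fitted.values

#' @export
summary.nbuwreg <- function(object, ...) {
  est <- c(object$coefficients, "(shape)" = object$shape)
  z <- est / object$se
  tab <- cbind(Estimate = est, `Std. Error` = object$se, `z value` = z,
               `Pr(>|z|)` = 2 * pnorm(-abs(z)))
  structure(list(coefficients = tab, q = object$q, loglik = object$loglik,
                 aic = object$aic, bic = object$bic, n = object$n,
                 converged = object$converged),
            class = "summary.nbuwreg")
}

#' @export
print.summary.nbuwreg <- function(x, digits = 4, ...) {
  cat(sprintf("Bounded unit Weibull quantile regression (q = %g)\n\n", x$q))
  stats::printCoefmat(x$coefficients, digits = digits)
  cat(sprintf("\nn = %d, logLik = %.4f, AIC = %.4f, BIC = %.4f\n",
              x$n, x$loglik, x$aic, x$bic))
  if (!x$converged) cat("Warning: optimizer did not converge\n")
  invisible(x)
}

#' @export
predict.nbuwreg <- function(object, newdata = NULL,
                            type = c("quantile", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    eta <- object$linear.predictors
  } else {
    X <- model.matrix(delete.response(terms(object)), newdata)
    eta <- drop(X %*% object$coefficients)
  }
  if (type == "link") eta else plogis(eta)
}
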