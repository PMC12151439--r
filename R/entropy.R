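#' Entropies of the bounded unit Weibull distribution
#'
#' Renyi entropy of order `theta`, the q-entropy (Havrda-Charvat/Tsallis
#' style, log form) of order `q_order`, and the Shannon differential entropy.
#'
#' The Renyi entropy is \eqn{(1-\theta)^{-1} \log \int_0^1 f(x)^\theta dx}.
#' The integral is evaluated by adaptive quadrature after the substitution
#' \eqn{w = (1-x)/x}, under which
#' \eqn{\int f^\theta dx = (\alpha\beta)^\theta \int_0^\infty
#' w^{(\beta-1)\theta} (1+w)^{2\theta-2} e^{-\theta\alpha w^\beta} dw.}
#' The integral diverges when \eqn{\theta(\beta-1) \le -1} (the density's
#' singularity at \eqn{x=1} becomes non-integrable after raising to
#' \eqn{\theta}); this is detected and reported as an error rather than
#' silently truncated.
#'
#' The q-entropy is \eqn{(1-q)^{-1}\log[1 - \int f^q dx]}. For `q_order > 1`
#' the integral \eqn{\int f^q} is at least 1 by Jensen's inequality (it equals
#' 1 only for the uniform density), so the argument of the logarithm is
#' non-positive and the q-entropy is undefined for this family; the error
#' message reports the computed integral. Orders in (0, 1) are always valid.
#'
#' A diagnostic series representation of the Renyi integrand exists,
#' paralleling the moment series (see [nbuw_moment]); it is evaluated over
#' admissible beta-function terms only (`method = "series"`) and shares that
#' representation's term-wise divergence caveat. The series uses first beta
#' argument \eqn{i - \beta j - \beta\theta - \theta + 1}, the value implied by
#' integrating the expanded power of \eqn{x}.
#'
#' @param theta Renyi order; positive, not equal to 1.
#' @param q_order q-entropy order; positive, not equal to 1.
#' @param alpha,beta positive distribution parameters.
#' @param method `"quadrature"` (authoritative) or `"series"` (diagnostic).
#' @param max_terms,series_tol series truncation controls as in [nbuw_moment].
#'
#' @return A single numeric entropy value. The series method attaches
#'   `terms_used` and `tail_increment` attributes.
#'
#' @examples
#' nbuw_entropy_renyi(2, alpha = 1, beta = 2)
#' nbuw_entropy_q(0.5, alpha = 2, beta = 1.75)
#' nbuw_entropy_shannon(alpha = 1, beta = 1)
#' @export
nbuw_entropy_renyi <- function(theta, alpha, beta,
                               method = c("quadrature", "series"),
                               max_terms = 50L, series_tol = 1e-10) {
  method <- match.arg(method)
  .check_positive(alpha, "alpha"); .check_positive(beta, "beta")
  .check_positive(theta, "theta")
  if (length(theta) != 1L || theta == 1)
    stop("'theta' must be a single positive value different from 1",
         call. = FALSE)
  if (method == "series") {
    s <- .nbuw_renyi_series(theta, alpha, beta, max_terms, series_tol)
    return(structure(log(c(s)) / (1 - theta),
                     terms_used = attr(s, "terms_used"),
                     tail_increment = attr(s, "tail_increment")))
  }
  I <- .nbuw_int_f_pow(theta, alpha, beta)
  log(I) / (1 - theta)
}

## integral of f(x)^theta over (0,1), in w = (1-x)/x space
.nbuw_int_f_pow <- function(theta, alpha, beta) {
  if (theta * (beta - 1) <= -1)
    stop("integral of f^theta diverges: theta*(beta-1) = ",
         format(theta * (beta - 1)), " <= -1", call. = FALSE)
  a <- theta * (beta - 1)
  g <- function(w) exp(theta * (log(alpha) + log(beta)) + a * log(w) +
                         (2 * theta - 2) * log1p(w) - theta * alpha * w^beta)
  i1 <- integrate(g, 0, 1, rel.tol = 1e-11)$value
  i2 <- integrate(g, 1, Inf, rel.tol = 1e-11)$value
  i1 + i2
}

.nbuw_renyi_series <- function(theta, alpha, beta, max_terms, tol) {
  total <- 0
  used <- 0L
  last_inc <- 0
  for (i in 0:max_terms) {
    ci <- choose(beta * theta - theta, i)
    inc_i <- 0
    if (ci != 0) {
      for (j in 0:max_terms) {
        a1 <- i - beta * j - beta * theta - theta + 1
        if (a1 <= 0) next
        term <- (-1)^(i + j) / factorial(j) * ci * (alpha * theta)^j *
          (alpha * beta)^theta * beta(a1, beta * j + 1)
        if (!is.finite(term))
          stop("series evaluation produced a non-finite term at (i,j) = (",
               i, ",", j, ")", call. = FALSE)
        inc_i <- inc_i + term
        used <- used + 1L
      }
    }
    total <- total + inc_i
    last_inc <- abs(inc_i)
  }
  if (used > 0L && last_inc > tol)
    stop("series did not converge within the truncation bound", call. = FALSE)
  structure(total, terms_used = used, tail_increment = last_inc)
}

#' @rdname nbuw_entropy_renyi
#' @export
nbuw_entropy_q <- function(q_order, alpha, beta) {
  .check_positive(alpha, "alpha"); .check_positive(beta, "beta")
  .check_positive(q_order, "q_order")
  if (length(q_order) != 1L || q_order == 1)
    stop("'q_order' must be a single positive value different from 1",
         call. = FALSE)
  I <- .nbuw_int_f_pow(q_order, alpha, beta)
  if (1 - I <= 0)
    stop("q-entropy undefined: integral of f^q = ", format(I),
         " is >= 1, so log(1 - integral) does not exist", call. = FALSE)
  log(1 - I) / (1 - q_order)
}

#' @rdname nbuw_entropy_renyi
#' @export
nbuw_entropy_shannon <- function(alpha, beta) {
  .check_positive(alpha, "alpha"); .check_positive(beta, "beta")
  ## -E[log f(X)] with X = (1 + (t/alpha)^(1/beta))^{-1}, t ~ Exp(1);
  ## log f expressed directly in t to avoid underflow of X for large t:
  ## log f = log(alpha*beta) + (beta-1)/beta * (log t - log alpha)
  ##         + 2*log(1+w) - t,   w = (t/alpha)^(1/beta)
  integrand <- function(t) {
    lw <- (log(t) - log(alpha)) / beta
    softplus <- pmax(lw, 0) + log1p(exp(-abs(lw)))   # log(1 + e^lw), stable
    logf <- log(alpha) + log(beta) + (beta - 1) * lw + 2 * softplus - t
    -exp(-t) * logf
  }
  integrate(integrand, 0, Inf, rel.tol = 1e-10)$value
}
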