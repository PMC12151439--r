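# central finite difference of a scalar function
num_deriv <- function(f, x, h = 1e-6) (f(x + h) - f(x - h)) / (2 * h)

# numerical gradient of a multivariate scalar function
num_grad <- function(f, par, h = 1e-6) {
  vapply(seq_along(par), function(i) {
    hi <- h * max(1, abs(par[i]))
    up <- par; up[i] <- up[i] + hi
    dn <- par; dn[i] <- dn[i] - hi
    (f(up) - f(dn)) / (2 * hi)
  }, numeric(1))
}

# parameter grid spanning the settings of the MLE recovery study
mle_param_grid <- list(c(0.5, 0.75), c(0.75, 0.5), c(1.5, 1.25),
                       c(1.75, 1.5), c(2.0, 1.75), c(2.5, 3.25))

# closed-form E_beta[xi] for the SPRT increment: with t = alpha*w^beta ~ Exp(1),
# E[log t] = -gamma and E[t^r] = Gamma(1+r), so
# E[xi] = log(b1/b0) + (b1-b0)(-gamma - log a)/b
#         - a^(1-b1/b) Gamma(1+b1/b) + a^(1-b0/b) Gamma(1+b0/b)
sprt_e_xi_closed <- function(alpha, beta_true, beta0, beta1) {
  g <- -digamma(1)
  log(beta1 / beta0) +
    (beta1 - beta0) * (-g - log(alpha)) / beta_true -
    alpha^(1 - beta1 / beta_true) * gamma(1 + beta1 / beta_true) +
    alpha^(1 - beta0 / beta_true) * gamma(1 + beta0 / beta_true)
}
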