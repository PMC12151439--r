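# nbuw

Tools for modeling proportions and other responses confined to the unit
interval: the **bounded unit Weibull distribution** on (0, 1], its
quantile-parameterized form, a **parametric quantile regression** model with a
logit link, a **sequential probability ratio test** (SPRT) for the shape
parameter, and Monte Carlo harnesses for parameter-recovery studies.

The package is aimed at analysts of rates, fractions and percentages —
educational attainment shares, cost ratios, risk proportions — who need a
two-parameter alternative to the beta and Kumaraswamy families with
closed-form distribution and quantile functions, robust (median or general
quantile) regression for bounded responses, and sequential hypothesis testing
that can stop data collection early.

## The model

Mapping a Weibull variate Y on (0, ∞) through X = 1/(1+Y) gives a
distribution on (0, 1] with, writing w = (1−x)/x,

    F(x; α, β) = exp{−α w^β},                        α, β > 0
    f(x; α, β) = α β w^{β−1} x^{−2} exp{−α w^β}
    Q(p; α, β) = [1 + (−log p / α)^{1/β}]^{−1}

The density can be bathtub-shaped, right-skewed or unimodal. Because Q is
closed-form, the distribution reparameterizes cleanly by any quantile: fixing
a level q ∈ (0, 1) and writing μ for the q-th quantile,

    α(μ, β, q) = −(1/μ − 1)^{−β} log q,

which yields a regression model in which the conditional q-th quantile of a
response y_i ∈ (0, 1) is linked to covariates by logit(μ_i) = x_iᵀδ and all
parameters (δ, β) are estimated by maximum likelihood. For q = 0.5 this is a
median regression that is robust to outlying responses in a way conditional-
mean models (e.g. beta regression) are not.

For sequential testing of H0: β = β0 against H1: β = β1 (> β0) with α known,
the log likelihood-ratio increments are accumulated until they leave Wald's
interval (log B, log A), A = (1−ψ)/δ, B = ψ/(1−δ); operating-characteristic
and average-sample-number functions are provided.

## Worked example

```r
library(nbuw)

## median regression on simulated data with a known truth
dat <- simulate_nbuwreg(200, delta = c(1.3, 1.4), beta = 2, q = 0.5, seed = 1)
fit <- nbuwreg(y ~ x1, data = dat, q = 0.5)
summary(fit)
#> Bounded unit Weibull quantile regression (q = 0.5)
#>
#>             Estimate Std. Error z value Pr(>|z|)
#> (Intercept)  1.33697    0.04425   30.21   <2e-16 ***
#> x1           1.41165    0.04193   33.67   <2e-16 ***
#> (shape)      1.87751    0.10236   18.34   <2e-16 ***
#>
#> n = 200, logLik = 253.3276, AIC = -500.6552, BIC = -490.7603
```

The intercept and slope estimates sit within two standard errors of the
generating values (1.3, 1.4), as does the shape (2.0). Residual diagnostics
follow the usual probability-integral-transform logic — quantile residuals
are standard normal and Cox–Snell residuals unit exponential when the model
is correctly specified:

```r
ks_gof(residuals(fit), "std_normal")$p.value     # 0.55: no misfit signal
mean(residuals(fit, "cox-snell"))                # 0.988, close to 1
```

A sequential test run on a stream of observations:

```r
set.seed(7)
x <- rnbuw(200, alpha = 1, beta = 1.5)
nbuw_sprt(x, alpha = 1, beta0 = 0.75, beta1 = 1.5)
#> Sequential probability ratio test (bounded unit Weibull shape)
#>   H0: beta = 0.75  vs  H1: beta = 1.5   (alpha = 1 known)
#>   boundaries: log B = -2.9444, log A = 2.9444 (delta = 0.05, psi = 0.05)
#>   decision: reject_H0 after 13 observation(s), log lambda = 3.0091
```

Thirteen observations sufficed where a fixed-sample test would have committed
to a much larger n in advance.

A shell entry point wrapping the same functions is installed at
`inst/cli/nbuw` (subcommands `fit-dist`, `quantreg`, `sprt`, `simulate`,
`entropy`). For published datasets of the kind this model targets, the
expected CSV schemas are: educational attainment — response `attainment`
with covariates `satisfaction`, `homicide`; firm risk-management cost —
response `firmcost` with covariates `assume`, `cap`, `sizelog`, `indcost`,
`central`, `soph`. Those datasets are not redistributed here.

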