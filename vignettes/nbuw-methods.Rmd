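---
title: "Methods: the bounded unit Weibull model, its quantile regression, and the Monte Carlo studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the bounded unit Weibull model, its quantile regression, and the Monte Carlo studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbuw)
```

This vignette records the package's modeling assumptions, numerical choices,
and the design of its simulation studies — the information a maintainer or a
careful user needs and the function reference does not carry.

## The distribution

A Weibull variate $Y$ on $(0,\infty)$ mapped through $X = 1/(1+Y)$ gives a
distribution on $(0,1]$ with, for $w = (1-x)/x$,

$$F(x;\alpha,\beta) = e^{-\alpha w^\beta}, \qquad
  f(x;\alpha,\beta) = \alpha\beta\, w^{\beta-1} x^{-2} e^{-\alpha w^\beta},
  \qquad \alpha,\beta > 0.$$

Both the distribution and quantile functions are closed-form, which is what
makes the quantile reparameterization and regression below possible without
numeric inversion. The density is bathtub-shaped for small $\beta$, and
unimodal with mass concentrating near $x = 1/2$ as $\beta \to \infty$ when
$\alpha = 1$.

Assumptions worth stating explicitly:

* the support is $(0,1]$ — exact zeros cannot occur under the model and are
  rejected as data errors. Responses exactly equal to 1 are legal support
  points where the density is singular ($\beta < 1$) or zero ($\beta > 1$),
  so likelihood code clamps them to $1 - 10^{-10}$ with a warning. Data with
  structural zeros or ones need a different (inflated) model.
* observations are independent; there is no provision for correlated or
  clustered responses.

### Numerical policy

Every power $w^\beta$ is evaluated as $\exp(\beta \log w)$ with
$\log w = \mathrm{log1p}(-x) - \log x$, so shapes in the hundreds neither
overflow nor lose the endpoints. The quantile function accepts
log-probabilities directly (`log.p = TRUE`) *without* exponentiating them
first: deep lower-tail probabilities such as $F(0.1)$ at
$(\alpha,\beta) = (2.5, 3.25)$ — about $e^{-3156}$ — are unrepresentable as
doubles but invert exactly on the log scale. The package's round-trip
identity $Q(F(x)) = x$ is therefore guaranteed (to $10^{-10}$) through the
log-scale interface; on the raw probability scale it necessarily fails
wherever $F$ underflows.

The quantity $\alpha\beta w^{\beta-1}x^{-2}$, exposed as `hnbuw()`, equals
$f/F$ — the *reversed* hazard rate — because the exponential factor of $f$
cancels against $F$. It is provided under the hazard-style name this family
conventionally uses, with the classical hazard available as
`dnbuw(x)/pnbuw(x, lower.tail = FALSE)`.

## Moments and entropies: quadrature, not series

All moments, the MGF and the entropies are computed by adaptive quadrature
and this is the authoritative method. Two useful substitutions make the
integrands smooth: with $T = \alpha W^\beta \sim \mathrm{Exp}(1)$,

$$E[X^m] = \int_0^\infty \bigl(1 + (t/\alpha)^{1/\beta}\bigr)^{-m} e^{-t}\,dt,$$

which has no endpoint singularity at all, and for entropies the $w$-space
form $\int f^\theta dx = (\alpha\beta)^\theta \int_0^\infty w^{(\beta-1)\theta}
(1+w)^{2\theta-2} e^{-\theta\alpha w^\beta} dw$.

A beta-function double-series representation of the moments exists on paper
(expand the exponential, then the power $(1-x)^{\beta-1}$), but it is not a
valid computational route: most individual terms correspond to divergent
integrals $\int_0^1 x^{a-1}(1-x)^{b-1}dx$ with $a \le 0$, where the beta
function is undefined — the expansion converges only as a whole, not
term-wise. The package evaluates the series as a *diagnostic* restricted to
admissible terms ($a > 0$), with both indices capped at 50, a
$10^{-10}$ tail-increment tolerance, and truncation metadata attached to the
result. For integer shapes the binomial terminates and the guarded sum is
exact over its admissible set (often empty — e.g. $\beta = 2$, first moment —
in which case it honestly returns 0 with `terms_used = 0`); for non-integer
shapes the alternating tail decays like a power and the evaluation raises a
convergence error rather than returning a half-summed number.

Two entropy-domain facts are enforced rather than papered over:

* $\int f^\theta$ diverges when $\theta(\beta-1) \le -1$ (the singularity at
  $x = 1$ stops being integrable); this raises an error.
* the q-entropy $(1-q)^{-1}\log[1 - \int f^q]$ is undefined for every
  $q > 1$ in this family, because $\int f^q \ge (\int f)^q = 1$ by Jensen's
  inequality — e.g. $\int f^2 = 1.25$ at $\alpha=\beta=1$. The error message
  reports the computed integral. Orders in $(0,1)$ are always valid.

## Maximum likelihood

For an i.i.d. sample the scale has a closed-form profile maximizer
$\hat\alpha(\beta) = n / \sum w_i^\beta$, so `nbuw_fit()` performs a
one-dimensional golden-section search over $\log\beta \in [-12, 12]$ on the
profile log-likelihood — unimodal for this family, since it is the Weibull
shape profile in the transformed variable. This is faster and more robust
than a two-dimensional quasi-Newton search and gives the same optimum; the
positivity of both parameters is enforced by the log parameterization, not by
constraints. Standard errors come from the analytic observed information,
inverted in closed form. The score is numerically zero at the reported
optimum (asserted in the tests at relative norm $10^{-5}$).

Replicate-level summaries (the recovery studies below) report *empirical
percentile* confidence intervals of the Monte Carlo estimates; the
per-fit Wald intervals are also available (`confint`). Percentile intervals
are the interpretation consistent with asymmetric intervals around a mean
estimate, such as those the recovery study produces at small $n$.

## Quantile reparameterization and regression

Fixing a known quantile level $q$ and writing $\mu$ for the $q$-th quantile,
$\alpha(\mu,\beta,q) = -(1/\mu-1)^{-\beta}\log q = -\log q\,
e^{\beta\,\mathrm{logit}(\mu)}$, strictly positive since $\log q < 0$. The
reparameterized density/CDF/quantile functions are one code path with the
base parameterization (the substitution is applied, then the base function
called), so the two forms agree to machine precision and
$G(\mu) = q$ holds by construction.

The regression model links $\mathrm{logit}(\mu_i) = x_i^\top\delta$ and
estimates $(\delta, \beta)$ jointly by maximum likelihood. With
$t_i = \eta_i + \log w_i$ the log-likelihood is

$$\ell = n\log\beta + n\log(-\log q) + \beta\textstyle\sum\eta_i
  + (\beta-1)\sum\log w_i - 2\sum\log y_i + \log q \sum e^{\beta t_i},$$

where the final term carries the exponent $\beta$ on $w_i$ — required for
$\ell$ to equal $\sum_i \log \pi(y_i)$, an identity the tests assert at
$10^{-10}$. Optimization is BFGS over $(\delta, \log\beta)$ with the analytic
gradient; steps where some $\beta t_i > 700$ (overflow of $e^{\beta t_i}$)
are rejected with a large objective value. Starting values are the
least-squares fit of $\mathrm{logit}(y)$ on the design for $\delta$ and
$\beta = 1$; a failed start is retried once from zero. Standard errors use
the analytic observed information in the natural parameterization. Wald $z$
tests and two-sided p-values are reported per coefficient; the AIC/BIC
parameter count is $p + 1$ (coefficients plus shape).

Quantile residuals $\Phi^{-1}(G(y_i))$ need no randomization because the
response is continuous; Cox–Snell residuals are the complementary-log
transform of the same probability-integral values, and the two are asserted
to be exact monotone transforms of each other. The KS statistics reported
against the residual references use the naive asymptotic p-value; no
correction is made for parameters estimated from the same data, which makes
the test mildly conservative under a correct model.

## Sequential probability ratio test

The SPRT for the shape treats $\alpha$ as known and accumulates
log-likelihood-ratio increments until they leave $(\log B, \log A)$ with
$A = (1-\psi)/\delta$, $B = \psi/(1-\delta)$. Three deliberate choices:

* boundary hits use $\le$/$\ge$ and overshoot is not corrected. Realized
  error rates are therefore *conservative* — below the nominal $(\delta,
  \psi)$ — and the calibration checks are one-sided (realized rate below
  nominal plus Monte Carlo slack), since Wald's argument bounds the rates
  from above only.
* the expected increment $E_\beta(\xi)$ in the ASN denominator is computed by
  adaptive quadrature (in the exponential-variable substitution, where the
  integrand is smooth); the test suite cross-checks it against an independent
  closed form in terms of $\Gamma$ and digamma values.
* the ASN numerator under $H_1$ is reported in two forms that coincide when
  $\delta = \psi$: the form weighting $\log B$ by $\delta$, and the standard
  Wald form weighting it by $L(\beta_1) = \psi$. Both are attached to the
  returned value, because published presentations differ here.

The Wald ASN is accurate when increments are small relative to the
boundaries (close hypotheses). For widely separated hypotheses — for example
$\beta_0 = 0.75$ vs $\beta_1 = 1.5$ at $\delta = \psi = 0.05$, where the
nominal ASN under $H_0$ is about 3 observations — overshoot dominates and
the formula undershoots the true mean stopping time by roughly 40%; the
package documents the value as a lower bound in that regime rather than
pretending to 15% accuracy.

## The Monte Carlo recovery studies

`sim_mle_study()` and `sim_quantreg_study()` regenerate the two
parameter-recovery studies. Their defaults *are* the study conditions: the
distribution study uses sample sizes $20, 45, \dots, 195$ at six
$(\alpha,\beta)$ settings with 1000 replications; the regression study uses
one standard-normal covariate (redrawn every replication), sample sizes
$25, 75, 150, 300$, quantile levels $q \in \{0.1, 0.5, 0.9\}$, four
intercept/slope/shape schemes, and 10,000 replications. Per-replication
seeds derive deterministically from the master seed and the cell index, so
every cell is independently re-runnable and full tables are bit-identical
under a fixed seed. Replications whose fit fails to converge are dropped and
counted (`n_fail`); in practice the count is zero at these settings.

Reported summaries: bias, MSE and percentile intervals per parameter
(distribution study); relative percentage bias
$100(\overline{\hat\theta}-\theta)/\theta$ and RMSE about the true value
(regression study), each with its Monte Carlo standard error. The shape
parameter's RMSE is *additionally* reported relative to the true shape
(`rmse_rel_shape`): the likelihood depends on $\beta$ only through products
$\beta\log w$ and $\beta\eta$, so $\hat\beta/\beta$ has a distribution free
of the true shape, and the relative RMSE is the scale-free summary that is
comparable across schemes — empirically constant (about $0.046$ at $n=300$)
where the absolute RMSE scales proportionally to $\beta$.

Two caveats delimit what these studies can show. First, the synthetic
generator emulates exactly the stated data-generating process — independent
Gaussian covariates, correctly specified link and distribution. Passing
recovery tests therefore demonstrates internal consistency of estimator and
generator, not robustness to misspecification, dependence, or real-data
artifacts like rounding and boundary values. Second, the acceptance suite
compares the regenerated tables against external reference values at a
tolerance of three combined Monte Carlo standard errors. Most cells agree
comfortably; a block of reference values for two schemes at $q = 0.5$, and
the slope column at the largest sample size, sit above what the analytic
observed-information (Cramér–Rao) bound permits for this data-generating
process — our simulated values agree with that bound (e.g. empirical slope
RMSE $0.0290$ at $n = 300$ in the first scheme against an information bound
of $0.0289$, where the reference prints $0.0306$), so the corresponding
comparisons are expected to fail and are reported as such rather than
absorbed by a widened tolerance.

## Problem sizes used by the checked runs

The test suite runs the distribution study at the full 1000 replications for
all six parameter settings and the regression study at 2000 replications per
(scheme, q) cell; the reproduction script (`scripts/acceptance.R`) uses 1000
and 10,000 replications respectively. These sizes keep each summary's Monte
Carlo standard error in the low single-digit percent range, which is the
resolution at which the comparisons above are meaningful.

## Known limitations

* No provision for exact zeros (or a point mass at 1): data with structural
  boundary values need an inflated extension.
* The SPRT covers the shape only, with the scale known; composite or
  two-parameter sequential tests are out of scope.
* The regression assumes independent responses; no random effects.
* KS p-values for residual diagnostics ignore parameter estimation.
* The moment/entropy series representations are diagnostics only; quadrature
  is the supported computational path.
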