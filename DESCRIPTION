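Package: nbuw
Title: The Bounded Unit Weibull Distribution with Quantile Regression and
    Sequential Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Density, distribution function, quantile function and random
    generation for the bounded unit Weibull distribution on (0,1], obtained by
    mapping a Weibull variate Y to X = 1/(1+Y). Provides moments, moment
    generating function and Renyi/q-entropies via adaptive quadrature, maximum
    likelihood estimation with observed-information standard errors, a Wald
    sequential probability ratio test for the shape parameter with operating
    characteristic and average sample number functions, a quantile-parameterized
    form of the distribution and a parametric quantile regression model for
    responses in (0,1) with a logit link, randomized quantile and Cox-Snell
    residual diagnostics, and Monte Carlo harnesses for parameter-recovery
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
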