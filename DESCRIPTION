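Package: mbcolrt
Title: Model-Based Constrained Optimization Tests of Indirect Effects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Likelihood-ratio tests of indirect effects in recursive path
    (mediation) models via model-based constrained optimization (MBCO):
    the null model maximizes the multivariate-normal likelihood subject to
    a nonlinear equality constraint on a product of path coefficients, and
    the test statistic is referred to a chi-square distribution
    (asymptotic variant) or to a bootstrap null distribution obtained by
    parametric resampling from the fitted null model or by semi-parametric
    resampling from data linearly transformed to match the null model's
    implied covariance. Also provides the three confidence-interval tests
    commonly used for indirect effects (percentile bootstrap, profile
    likelihood, Monte Carlo), a Vale-Maurelli/Fleishman generator for
    non-normal model residuals, and a simulation harness for Type I error
    and power experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, yaml
Suggests: testthat (>= 3.0.0), jsonlite, parallel, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
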