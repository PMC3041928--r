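Package: biasblend
Title: Combining Small-Area Prevalence Estimates from Multiple Biased Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Evidence synthesis for small-area prevalence when only aggregate
    estimates from several surveys are available.  Implements Bayesian
    hierarchical models with additive source-specific biases (independent,
    correlated via a scaled inverse-Wishart covariance, and linear time-trend
    variants), fitted by MCMC through JAGS, together with a classical
    counterpart based on an iterative weighted two-way ANOVA with a
    DerSimonian-Laird moment estimator of the bias variances and a REML
    mixed-model formulation.  Provides pooled area estimates anchored to an
    external regional mean, per-source bias summaries, inverse-variance
    pooling weights, bias-adjusted estimates, standardized-residual and DIC
    diagnostics, forecasts from the trend model, and a synthetic-data
    generator with known truth for calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    coda,
    rjags,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
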