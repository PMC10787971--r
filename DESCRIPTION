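Package: baftcr
Title: Bayesian Accelerated Failure Time Models for Competing Risks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Cause-specific Bayesian accelerated failure time (AFT) modelling
    for right-censored survival data with competing event causes, as used in
    registry studies of heart-failure mortality. Fits Weibull, log-logistic
    and log-normal AFT regressions by adaptive random-walk Metropolis
    sampling under diffuse normal priors, reports covariate effects as time
    ratios with equal-tailed credible intervals, and compares candidate
    distributions by DIC, WAIC and LPML. Includes the surrounding study
    pipeline (univariable screening, multivariable modelling, prior-variance
    sensitivity analysis), descriptive survival summaries (person-time
    mortality rates with exact Poisson intervals, Kaplan-Meier curves,
    log-rank and trend tests), and a seeded generator of registry-like
    cohorts with known cause-specific AFT structure for validation.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    survival
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
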