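Package: survite
Title: Meta-Learners for Individualized Treatment Effects with Survival Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates individualized treatment effects (ITE) on the
    survival-probability scale from right-censored two-arm randomized
    trials using T-learner and X-learner meta-algorithms with pluggable
    base learners (correctly specified parametric accelerated failure
    time models, random survival forests, a pseudo-value neural
    regressor, and a Laplace-approximation Bayesian AFT). Includes a
    simulation engine for Weibull and log-logistic data-generating
    processes with calibrated exponential censoring and three
    randomization designs, quantile-binned error and
    treatment-recommendation accuracy metrics, Kaplan-Meier cohort
    effect summaries, cross-validated ITE estimation, and a Boruta
    shadow-feature algorithm for identifying covariates that drive
    treatment heterogeneity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    nnet,
    purrr,
    randomForest,
    ranger,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
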