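Package: tevim
Title: Treatment Effect Variable Importance Measures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonparametric variable importance measures for heterogeneous
    treatment effects (TE-VIMs). Quantifies the increase in mean-squared error
    of conditional average treatment effect (CATE) prediction when covariate
    subsets are removed from the conditioning set, together with the variance
    of the treatment effect (VTE) and an R-squared-like scaled importance.
    Provides efficient influence-curve estimators with Wald inference, AIPW
    pseudo-outcomes, cross-fitted T-learner and DR-learner CATE metalearners,
    leave-one-out, keep-one-in, Shapley-value and grouped comparison modes, a
    pluggable learner registry, and a simulation harness with closed-form
    truth oracles for benchmarking bias, variance, coverage and covariate
    ranking accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mgcv,
    pracma,
    withr
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    ranger,
    xgboost,
    optparse,
    jsonlite
Config/testthat/edition: 3
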