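Package: cohortrules
Title: Rule-Based Subgroup Discovery for Study-Withdrawal Risk in Cohort Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies subgroups of cohort participants at heterogeneous risk
    of early study withdrawal using a two-stage rule-ensemble analysis:
    candidate risk-predictive rules are harvested from bootstrapped,
    feature-subsampled recursive-partitioning trees, then pruned to a sparse
    predictive set with L1-penalized logistic regression tuned by
    cross-validation. Selected subgroups are profiled by withdrawal rate,
    population coverage and pairwise endorsement redundancy, alongside a
    complete-case multivariable logistic-regression baseline. Includes a
    synthetic cohort generator emulating a multinational pediatric cohort
    (mixed categorical/continuous/count covariates, controllable missingness,
    planted rule effects) so the whole pipeline is testable without access to
    confidential participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    tools,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    glmnet,
    optparse,
    rpart,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
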