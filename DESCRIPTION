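Package: perilasso
Title: Adaptive LASSO Selection of Pregnancy-Stress Predictors of
    Postpartum Mental Health Across Multiply Imputed Datasets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for machine-learning variable selection on weekly
    pregnancy stress trajectories: chained-equations proportional-odds
    multiple imputation of ordinal weekly stress (gestational weeks 15-41),
    person-mean-centered feature construction (person mean, person SD and 27
    weekly deviation scores), adaptive LASSO with cross-validated tuning fit
    to each imputed dataset by coordinate descent, and pooling of results by
    selection frequency across imputations, run for the full cohort and for
    subgroups split at four or more adverse childhood experiences (ACEs).
    Includes a calibrated synthetic-cohort generator with ground truth for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    glmnet,
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
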