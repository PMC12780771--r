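Package: demtransfer
Title: Transfer Learning for Penalized Logistic Dementia Classification
    Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimation of "probable dementia" status by transfer learning
    between a large source cohort carrying an imprecise algorithmic dementia
    probability and a small target cohort carrying a gold-standard dementia
    classification. A logistic LASSO is fitted to the dichotomized source
    outcome; its coefficients are then refined on the target cohort by
    minimizing the logistic loss under an L1 penalty on the deviation from
    the source coefficients. Includes stratified model development (per
    race/ethnicity self-respondent models and a pooled proxy-respondent
    model), bootstrap internal validation with Brier score, calibration
    intercept and slope, AUC and area under the precision-recall curve,
    detection of predictors whose coefficients deviate between cohorts, a
    negative-transfer guard, and a synthetic cohort generator emulating the
    source/target structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp, RcppArmadillo
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml,
    ranger,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    withr
Config/testthat/edition: 3
SystemRequirements: C++17
NeedsCompilation: yes
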