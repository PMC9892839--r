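Package: psytrans
Title: Prognostic Modelling of Transition to Psychosis in At-Risk Mental
    State Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Evaluates whether baseline structural-MRI, genetic, and
    environmental features predict transition to psychosis in an At-Risk
    Mental State (ARMS) cohort. Implements matched balanced bootstrapped
    subsampling, nested cross-validation under three schemes (leave-site-out,
    leave-one-pair-out, stratified k-fold), per-fold feature preparation
    (intracranial-volume normalisation, min-max scaling, robust PCA, greedy
    forward selection), linear support vector machine, logistic and
    elastic-net classifiers, permutation-tested balanced accuracy with a
    3-of-5 bootstrap aggregation rule, and composite polygenic, brain-eQTL
    and environmental risk scores. A seeded synthetic-cohort generator
    emulates the cohort structure so the whole pipeline is testable without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
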