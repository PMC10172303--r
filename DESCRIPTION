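Package: plaqmir
Title: Circulating MicroRNA Signatures of Lipid-Rich Coronary Plaques
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable statistical pipeline for circulating microRNA (miRNA)
    biomarker studies of lipid-rich coronary plaques assessed by near-infrared
    spectroscopy. Covers qPCR quantification-cycle (Cq) quality control and
    global-mean normalization with limit-of-detection imputation, NormFinder-style
    reference stability ranking, univariable screening with Benjamini-Hochberg
    false-discovery-rate control, elastic-net penalized logistic regression fitted
    by coordinate descent with penalty selection by repeated stratified
    cross-validation, bootstrap stability selection, and cross-validated ROC/AUC
    evaluation with DeLong confidence intervals. Includes a synthetic-cohort
    generator emulating the data structure of a dichotomized maxLCBI4mm
    case-control design so the full workflow is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    pROC,
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
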