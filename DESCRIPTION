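Package: mirpanel
Title: Serum miRNA Biomarker Panel Discovery from Absolute RT-qPCR Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end workflow for discovering and validating circulating
    microRNA diagnostic panels from serum RT-qPCR profiles. Converts raw
    threshold-cycle (Ct) observations to absolute copies per ml via
    standard-curve interpolation and spike-in recovery correction, selects
    stable endogenous reference miRNAs (geNORM and NormFinder stability
    measures) for normalization, screens differentially abundant markers
    across discovery and validation cohorts, optimizes multi-miRNA logistic
    panels by sequential forward floating search inside repeated
    source-stratified two-fold cross-validation, and evaluates the frozen
    panel on a held-out cohort (ROC/AUC with confidence intervals,
    maximum-accuracy operating point, source- and stage-stratified
    performance). Includes a synthetic-cohort generator emulating the
    multi-centre case-control structure the workflow assumes, so every stage
    is testable without access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pROC,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
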