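Package: gxenet
Title: Penalized Factorial Regression for Genotype-by-Environment Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits genotype-specific linear reaction norms to environmental
    covariates by factorial regression with selective elastic-net shrinkage:
    genotype and environment main effects stay unpenalized while the
    genotype-by-covariate sensitivity slopes are shrunk along a ridge, lasso
    or elastic-net path, with the penalty strength chosen by random or
    environment-stratified cross-validation. Predicts environment-centred
    performance of tested genotypes in new environments from covariates
    alone, evaluates per-environment Pearson accuracy averaged over
    environments, extends to untested genotypes through a two-stage marker
    ridge, and ships a multi-environment-trial simulator with envirotype
    structure and heritability-calibrated noise for offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    optparse,
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
    Rcpp
Suggests:
    glmnet,
    purrr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
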