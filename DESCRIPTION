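Package: squashgs
Title: Genomic Selection Analysis for Winter Squash Fruit Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for recurrent genomic selection in a
    biparental winter squash (Cucurbita moschata) breeding population. Provides a
    gamete-level simulator of F2-derived populations with repeated fruit-level
    phenotypes and GBS-style genotype degradation; genotype quality-control filters,
    set merging, mean imputation and the VanRaden genomic relationship matrix;
    EM-REML engines for the univariate repeatability model, multi-trait GBLUP with
    unstructured or diagonal genetic covariance, and a multi-site realized-gain
    model with heterogeneous variances; quantitative-genetic summaries
    (repeatability, narrow-sense heritability, accuracy gain from repeated
    measures, index heritability, environment-adjusted phenotypic and genetic
    correlations); Smith-Hazel and equal-weight GEBV selection indices with
    independent-culling and truncation selection; and cross-validation schemes
    (within-set, across-set, stratified) measuring predictive ability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    knitr,
    rmarkdown
Config/testthat/edition: 3
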