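Package: hcngp
Title: Genomic Prediction for Cyanogenic Potential in Cassava
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Whole-genome prediction toolkit for fresh cassava root cyanogenic
    potential (HCN, scored 1-9 by picrate assay) and similar ordinal-scored
    traits in clonal crops. Covers SNP dosage quality control, REML estimation
    of clone BLUEs and broad-sense heritability from multi-location augmented
    trials, the VanRaden genomic relationship matrix with kinship diagnostics
    and PCA, and seven prediction models: GBLUP by EM-REML, Bayes A, Bayes B,
    Bayes C, Bayesian ridge regression and the Bayesian Lasso by single-site
    Gibbs sampling, and Gaussian-kernel RKHS regression. Models are compared
    under repeated k-fold cross-validation with accuracy defined as predictive
    ability divided by the square root of validation-set narrow-sense
    heritability. A gene-dropping simulator generates family-structured
    genotypes and oligogenic trait data so the whole pipeline is testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    lme4,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
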