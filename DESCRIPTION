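Package: stratpred
Title: Stratified Multi-Omics Prediction of Drug Response in Family Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stratified drug-response prediction for family-structured cohorts.
    Screens SNPs with a generalized estimating equation (GEE) logistic scan and
    CpG methylation sites with a kinship linear mixed model, prunes markers by
    linkage disequilibrium, estimates an empirical genomic relationship matrix,
    and integrates the selected genetic, epigenetic and clinical predictors in a
    three-layer neural network (tansig hidden layer, linear output) trained by
    adaptive gradient descent with momentum. Models are compared stepwise under
    family-blocked 5-fold cross-validation with exact Wilcoxon rank-sum tests.
    Includes a synthetic sibship-cohort generator with planted SNP, CpG and
    clinical effects so every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    MASS,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
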