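Package: cogburden
Title: Rare Coding-Variant Burden Association Pipeline for Cognitive Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Gene-, gene-set- and exome-wide rare coding-variant burden
    association testing for quantitative and binary cognitive phenotypes.
    Implements variant functional classification (protein-truncating,
    MPC-tiered missense, synonymous) stratified by loss-of-function
    intolerance (pLI), two-step whole-genome regression with stacked block
    ridge regression and leave-one-chromosome-out offsets, Firth penalized
    logistic regression with phenome-wide scanning, inverse-variance-weighted
    random-effects meta-analysis, and joint modelling of polygenic scores
    with rare damaging-variant carrier status. A synthetic-cohort generator
    provides genotypes, annotations and phenotypes with the statistical
    structure these analyses assume, so the full pipeline is testable
    without access-controlled biobank data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    data.table,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    fgsea,
    metafor,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
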