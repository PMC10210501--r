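Package: kidneyPGS
Title: Polygenic Score Analysis of Kidney Function Across Age-Structured Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing the variance in estimated glomerular
    filtration rate (eGFR) explained by polygenic scores (PGS) between a
    general-adult and an elderly cohort. Implements PGS construction from
    effect-allele dosages in alleles-of-average-effect units, the CKD-EPI 2009
    creatinine and 2012 cystatin C eGFR equations with exact piecewise
    inversion, a covariate-adjustment model ladder with explained-variance
    (R squared) decomposition, cross-cohort allele-frequency difference and
    exact-binomial enrichment tests for survival-bias screening, and a
    calibrated two-cohort genotype-phenotype simulator for end-to-end
    validation without access to individual-level study data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    yaml,
    knitr
Config/testthat/edition: 3
biocViews: StatisticalMethod, GenomeWideAssociation, SNP, Regression
RoxygenNote: 7.3.3
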