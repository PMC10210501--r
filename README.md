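# kidneyPGS

Polygenic scores (PGS) for kidney function explain roughly twice as much
variance in estimated glomerular filtration rate (eGFR) among general
adults as among the elderly. kidneyPGS is an R package for dissecting that
gap. It implements the complete comparative analysis between a
general-adult and an elderly cohort for two kidney biomarkers — creatinine
(eGFR~crea~, CKD-EPI 2009) and cystatin C (eGFR~cys~, CKD-EPI 2012) — and
is aimed at genetic epidemiologists who want to decompose PGS performance
differences across study populations.

The core quantity is the explained variance of the two-stage model

    Y_i = beta0 + beta1 * PGS_i + eps_i,      R^2 = beta1^2 * Var(PGS) / Var(Y)

where `Y` is eGFR residualized on age, sex and ten genetic principal
components (plus, in higher ladder models, BMI, diabetes, hypertension,
CAD and high-ceiling diuretics), and the PGS counts eGFR-lowering alleles
weighted by GWAS effect sizes, normalized by the mean weight so one unit is
one allele of average effect. Any difference in `R^2` between cohorts must
come through `beta1`, `Var(PGS)` or `Var(Y)` — the package computes all
three, screens per-variant allele frequencies between cohorts for
survival/selection bias (Pearson chi-square on best-guess genotypes, exact
binomial enrichment and direction tests), and ships a calibrated two-cohort
simulator so the whole pipeline is testable end to end without any
individual-level study data.

## Worked example

Score a small cohort from the bundled demo files:

```r
library(kidneyPGS)

scoring <- readScoringFile(system.file("extdata", "demo_scoring.tsv",
                                       package = "kidneyPGS"))
dosages <- readDosageMatrix(system.file("extdata", "demo_dosages.tsv",
                                        package = "kidneyPGS"), format = "tsv")
h <- harmonizeVariants(scoring, dosages, r2Threshold = 0.8)
h$report
#>   variant_id  action                 reason
#> 1     rs1003    kept              ambiguous
#> 2     rs1004 dropped low imputation quality

pgs <- computePgs(h$score, h$geno)
as.data.frame(pgs)
#>   sample_id weighted unweighted n_variants_used
#> 1     ind01 5.513846       4.82               4
#> 2     ind02 3.965315       3.66               4
#> 3     ind03 5.108811       5.04               4
#> 4     ind04 5.171469       4.03               4
```

One variant (rs1004, imputation r² = 0.77) is removed by the quality
filter; the C/G variant rs1003 is kept but flagged strand-ambiguous. The
weighted score is in alleles-of-average-effect units: ind01 carries the
equivalent of about 5.5 average-effect eGFR-lowering alleles across the 4
scored variants (unweighted count 4.8).

The full two-cohort comparison runs from simulated, calibrated cohorts:

```r
report <- runComparison(comparisonConfig(seed = 11))
report
#> kidneyPGS comparison report (seed 11 )
#>
#> eGFRcrea (634 variants):
#>   general_adults  model 1: var  157.65  beta -0.289 [-0.322, -0.257]  R2 9.6%
#>   elderly         model 1: var  228.93  beta -0.248 [-0.295, -0.202]  R2 4.6%
#>   freq tests: 528 variants, 28 nominal (enrichment p = 0.402)
#>
#> eGFRcys (204 variants):
#>   general_adults  model 1: var  186.38  beta -0.356 [-0.414, -0.298]  R2 4.7%
#>   elderly         model 1: var  234.68  beta -0.351 [-0.426, -0.276]  R2 3.6%
#>   freq tests: 170 variants, 17 nominal (enrichment p = 0.005)
```

Reading the creatinine rows: the elderly cohort has a much larger
age-/sex-adjusted outcome variance (228.93 vs 157.65 (mL/min/1.73m²)²) and
a somewhat smaller PGS coefficient, and the explained variance drops from
9.6% to 4.6% — the two-fold gap the package is built to dissect. The
frequency lines summarize the per-variant cross-cohort screen after the
imputation-quality filter. `writeReport(report, "out/")` writes the JSON
master report plus ladder/screen/profile/frequency TSV tables, and
`inst/scripts/run_comparison.R` wraps the same calls for shell use.

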