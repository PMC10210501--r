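#' CKD-EPI equation constants
#'
#' Returns the published constants of the CKD-EPI 2009 creatinine or 2012
#' cystatin C equation: biomarker knot (kappa), below-/above-knot exponents,
#' intercept, age base, female factor, and (creatinine only) the race factor.
#'
#' @param equation `"crea2009"` or `"cys2012"`.
#' @return a list of constants.
#' @export
ckdEpiParams <- function(equation = c("crea2009", "cys2012")) {
    equation <- match.arg(equation)
    if (equation == "crea2009") {
        list(equation = equation,
             kappa = c(female = 0.7, male = 0.9),
             alpha = c(female = -0.329, male = -0.411),
             beta = -1.209, intercept = 141, ageBase = 0.993,
             femaleFactor = 1.018, raceFactor = 1.159)
    } else {
        list(equation = equation,
             kappa = c(female = 0.8, male = 0.8),
             alpha = c(female = -0.499, male = -0.499),
             beta = -1.328, intercept = 133, ageBase = 0.996,
             femaleFactor = 0.932, raceFactor = 1)
    }
}

.sexKey <- function(sex) {
    s <- tolower(as.character(sex))
    s[s %in% c("f", "female", "w", "2")] <- "female"
    s[s %in% c("m", "male", "1")] <- "male"
    if (!all(s %in% c("female", "male")))
        stop("sex must be coded female/male (or F/M)")
    s
}

.egfrForward <- function(x, age, sex, black, p) {
    if (any(!is.finite(x) | x <= 0)) stop("biomarker must be positive")
    if (any(!is.finite(age) | age <= 0)) stop("age must be positive")
    s <- .sexKey(sex)
    kappa <- p$kappa[s]
    alpha <- p$alpha[s]
    ratio <- x / kappa
    unname(p$intercept * pmin(ratio, 1)^alpha * pmax(ratio, 1)^p$beta *
        p$ageBase^age * ifelse(s == "female", p$femaleFactor, 1) *
        ifelse(black, p$raceFactor, 1))
}

#' eGFR from serum creatinine (CKD-EPI 2009)
#'
#' `eGFR = 141 * min(Scr/k, 1)^a * max(Scr/k, 1)^-1.209 * 0.993^age *
#' 1.018 [if female] * 1.159 [if black]`, with knot `k` = 0.7 (female) / 0.9
#' (male) mg/dL and below-knot exponent `a` = -0.329 / -0.411.
#'
#' @param scr serum creatinine, mg/dL (vectorized).
#' @param age age in years.
#' @param sex `"female"`/`"male"` (or `"F"`/`"M"`).
#' @param black logical; apply the 1.159 coefficient. The cohorts this package
#'   targets are European, so the default is `FALSE`; the coefficient is kept
#'   because the identifying GWAS effect sizes were estimated on this scale.
#' @return eGFR in mL/min/1.73m2.
#' @examples
#' egfrCrea2009(0.9, 50, "male")   # ~99.2
#' @export
egfrCrea2009 <- function(scr, age, sex, black = FALSE) {
    .egfrForward(scr, age, sex, black, ckdEpiParams("crea2009"))
}

#' eGFR from serum cystatin C (CKD-EPI 2012)
#'
#' `eGFR = 133 * min(Scys/0.8, 1)^-0.499 * max(Scys/0.8, 1)^-1.328 *
#' 0.996^age * 0.932 [if female]`.
#'
#' @param scys serum cystatin C, mg/L.
#' @inheritParams egfrCrea2009
#' @return eGFR in mL/min/1.73m2.
#' @examples
#' egfrCys2012(0.8, 50, "male")   # ~108.8
#' @export
egfrCys2012 <- function(scys, age, sex) {
    .egfrForward(scys, age, sex, FALSE, ckdEpiParams("cys2012"))
}

#' Invert a CKD-EPI equation
#'
#' Closed-form piecewise inversion: with prefactor
#' `P = intercept * ageBase^age * sexFactor * raceFactor`, the eGFR at the
#' biomarker knot is exactly `P`; for `egfr <= P` the above-knot branch is
#' solved, otherwise the below-knot branch. Round-trip relative error is at
#' machine precision. Used by the cohort simulator to emit serum
#' concentrations whose recomputed eGFR reproduces the latent value.
#'
#' @param egfr target eGFR, mL/min/1.73m2 (positive).
#' @inheritParams egfrCrea2009
#' @param equation `"crea2009"` or `"cys2012"`.
#' @return biomarker concentration (mg/dL for creatinine, mg/L for cystatin).
#' @export
invertEgfr <- function(egfr, age, sex, equation = c("crea2009", "cys2012"),
                       black = FALSE) {
    equation <- match.arg(equation)
    if (any(!is.finite(egfr) | egfr <= 0)) stop("egfr must be positive")
    if (any(!is.finite(age) | age <= 0)) stop("age must be positive")
    p <- ckdEpiParams(equation)
    s <- .sexKey(sex)
    pref <- p$intercept * p$ageBase^age *
        ifelse(s == "female", p$femaleFactor, 1) *
        ifelse(black & equation == "crea2009", p$raceFactor, 1)
    kappa <- p$kappa[s]
    alpha <- p$alpha[s]
    expo <- ifelse(egfr <= pref, p$beta, alpha)
    unname(kappa * (egfr / pref)^(1 / expo))
}

#' Phenotype quality control and analysis flags
#'
#' Applies the study rules: individuals with cystatin validity category 2-4
#' (below/above assay detection limits) are excluded from cystatin analyses
#' but retained for creatinine; the general-adult preset caps age at < 70
#' years to keep the two cohorts' age ranges disjoint; and a CKD flag
#' (`eGFRcrea < 60`, strict) is annotated.
#'
#' @param pheno data.frame with at least `age`, `sex`, `creatinine`,
#'   `cystatin`, `cystatin_validity` columns (see [simulateCohort()] for the
#'   full dialect).
#' @param study `"general_adults"` (applies the `< 70` age cap) or
#'   `"elderly"`.
#' @return list with `data` (the retained rows, plus logical `use_crea`,
#'   `use_cys` and `ckd` columns and computed `egfr_crea`, `egfr_cys`) and
#'   `report` (exclusion counts by reason).
#' @export
phenotypeQc <- function(pheno, study = c("general_adults", "elderly")) {
    study <- match.arg(study)
    n0 <- nrow(pheno)
    report <- data.frame(reason = character(), n = integer(),
                         stringsAsFactors = FALSE)
    if (study == "general_adults") {
        drop <- pheno$age >= 70
        report <- rbind(report, data.frame(reason = "age >= 70 (age cap)",
                                           n = sum(drop)))
        pheno <- pheno[!drop, , drop = FALSE]
    }
    if (nrow(pheno) == 0L) warning("phenotype QC removed every record")
    valid <- pheno$cystatin_validity
    badCys <- !is.na(valid) & valid %in% 2:4
    report <- rbind(report,
        data.frame(reason = "cystatin validity category 2-4 (cys analyses)",
                   n = sum(badCys)))
    pheno$use_crea <- !is.na(pheno$creatinine)
    pheno$use_cys <- !is.na(pheno$cystatin) & !badCys
    pheno$egfr_crea <- ifelse(pheno$use_crea,
        egfrCrea2009(pmax(pheno$creatinine, 1e-12), pheno$age, pheno$sex),
        NA_real_)
    pheno$egfr_cys <- ifelse(pheno$use_cys,
        egfrCys2012(pmax(pheno$cystatin, 1e-12), pheno$age, pheno$sex),
        NA_real_)
    pheno$ckd <- !is.na(pheno$egfr_crea) & pheno$egfr_crea < 60
    report <- rbind(report, data.frame(reason = "records retained",
                                       n = nrow(pheno)))
    attr(report, "n_input") <- n0
    list(data = pheno, report = report)
}
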