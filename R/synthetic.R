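#' Synthetic two-cohort study presets
#'
#' A preset bundles the conditions under which the synthetic cohorts are
#' generated: sample size and age range of the general-adult (n = 2,900,
#' 24-69 years) and elderly (n = 2,272, 70-95 years) study, the panel size
#' (634 creatinine variants, 204 cystatin variants), and the calibration
#' constants — target weighted-PGS SD, target age-/sex-adjusted outcome
#' variance and target model-1 R^2 — together with covariate prevalences and
#' effect sizes. The four named presets encode the two-study, two-biomarker
#' design; `"custom"` starts from a small toy configuration.
#'
#' Covariate effect sizes were fixed once from the published cohort
#' descriptives: age effects reproduce the univariable age R^2 pattern
#' (roughly 34%/43% of raw eGFR variance in general adults for
#' creatinine/cystatin, 10%/17% in the elderly), and comorbidity effects
#' reproduce the residual-variance drops across adjustment models 2-4
#' together with the cohort prevalences (e.g. diabetes 3.1% in general
#' adults vs 20.9% in the elderly).
#'
#' @param preset preset name.
#' @param ... named overrides of any preset field.
#' @return an object of class `"SyntheticPreset"` (a list).
#' @export
syntheticPreset <- function(preset = c("general_adults_crea",
        "general_adults_cys", "elderly_crea", "elderly_cys", "custom"), ...) {
    name <- match.arg(preset)
    base <- list(
        name = name, study = "general_adults", trait = "eGFRcrea",
        n = 200L, age_range = c(30, 60), female_fraction = 0.5,
        m_variants = 50L, freq_min = 0.02, weight_jitter_offset = 2,
        target_pgs_sd = 4.0, target_outcome_variance = 150,
        target_r2 = 0.05, mu_egfr = 95,
        beta_age = -0.5, beta_female = 2,
        bmi_mean = 27, bmi_sd = 4.5, bmi_effect = -0.3,
        education_mean = 12, education_sd = 3,
        smoking_probs = c(never = 0.5, former = 0.3, current = 0.2),
        comorbidities = list(
            diabetes = c(prevalence = 0.05, effect = -2),
            hypertension = c(prevalence = 0.3, effect = -1),
            cad = c(prevalence = 0.05, effect = -2),
            high_ceiling_diuretics = c(prevalence = 0.02, effect = -5)),
        age_logit_slope = 0.06,
        apoe_like_gap = NULL,
        cystatin_contamination = 0)
    tweak <- switch(name,
        general_adults_crea = list(study = "general_adults",
            trait = "eGFRcrea", n = 2900L, age_range = c(24, 69),
            female_fraction = 0.528, m_variants = 634L,
            target_pgs_sd = 13.3, target_outcome_variance = 157.65,
            target_r2 = 0.096, mu_egfr = 95.3,
            beta_age = -0.72, bmi_mean = 26.8, bmi_sd = 4.7,
            bmi_effect = -0.15,
            education_mean = 11.8, education_sd = 2.6,
            smoking_probs = c(never = 0.411, former = 0.317,
                              current = 0.272),
            comorbidities = list(
                diabetes = c(prevalence = 0.031, effect = -1),
                hypertension = c(prevalence = 0.320, effect = -0.4),
                cad = c(prevalence = 0.017, effect = -3),
                high_ceiling_diuretics = c(prevalence = 0.013,
                                           effect = -7)),
            age_logit_slope = 0.08),
        general_adults_cys = list(study = "general_adults",
            trait = "eGFRcys", n = 2900L, age_range = c(24, 69),
            female_fraction = 0.528, m_variants = 204L,
            target_pgs_sd = 8.4, target_outcome_variance = 186.38,
            target_r2 = 0.047, mu_egfr = 99.2,
            beta_age = -0.95, bmi_mean = 26.8, bmi_sd = 4.7,
            bmi_effect = -0.63,
            education_mean = 11.8, education_sd = 2.6,
            smoking_probs = c(never = 0.411, former = 0.317,
                              current = 0.272),
            comorbidities = list(
                diabetes = c(prevalence = 0.031, effect = -2),
                hypertension = c(prevalence = 0.320, effect = -0.4),
                cad = c(prevalence = 0.017, effect = -4.6),
                high_ceiling_diuretics = c(prevalence = 0.013,
                                           effect = -9)),
            age_logit_slope = 0.08),
        elderly_crea = list(study = "elderly", trait = "eGFRcrea",
            n = 2272L, age_range = c(70, 95), female_fraction = 0.515,
            m_variants = 634L,
            target_pgs_sd = 14.0, target_outcome_variance = 228.93,
            target_r2 = 0.046, mu_egfr = 67.7,
            beta_age = -0.69, bmi_mean = 27.7, bmi_sd = 4.5,
            bmi_effect = -0.70,
            education_mean = 12.3, education_sd = 3.4,
            smoking_probs = c(never = 0.555, former = 0.392,
                              current = 0.053),
            comorbidities = list(
                diabetes = c(prevalence = 0.209, effect = -4),
                hypertension = c(prevalence = 0.727, effect = -3.3),
                cad = c(prevalence = 0.155, effect = -5),
                high_ceiling_diuretics = c(prevalence = 0.128,
                                           effect = -10)),
            age_logit_slope = 0.04),
        elderly_cys = list(study = "elderly", trait = "eGFRcys",
            n = 2272L, age_range = c(70, 95), female_fraction = 0.515,
            m_variants = 204L,
            target_pgs_sd = 8.5, target_outcome_variance = 234.68,
            target_r2 = 0.036, mu_egfr = 60.9,
            beta_age = -1.02, bmi_mean = 27.7, bmi_sd = 4.5,
            bmi_effect = -0.96,
            education_mean = 12.3, education_sd = 3.4,
            smoking_probs = c(never = 0.555, former = 0.392,
                              current = 0.053),
            comorbidities = list(
                diabetes = c(prevalence = 0.209, effect = -3.5),
                hypertension = c(prevalence = 0.727, effect = -3),
                cad = c(prevalence = 0.155, effect = -5.7),
                high_ceiling_diuretics = c(prevalence = 0.128,
                                           effect = -12)),
            age_logit_slope = 0.04),
        custom = list())
    preset <- utils::modifyList(base, tweak)
    preset <- utils::modifyList(preset, list(...))
    stopifnot(preset$n > 0, preset$m_variants >= 1,
              preset$female_fraction >= 0, preset$female_fraction <= 1,
              preset$target_outcome_variance > 0,
              preset$target_r2 >= 0, preset$target_r2 < 1)
    class(preset) <- "SyntheticPreset"
    preset
}

#' @export
print.SyntheticPreset <- function(x, ...) {
    cat(sprintf("SyntheticPreset '%s' (%s, %s): n = %d, %d variants\n",
                x$name, x$study, x$trait, x$n, x$m_variants))
    cat(sprintf("  targets: PGS SD %.1f, outcome variance %.2f, R2 %.1f%%\n",
                x$target_pgs_sd, x$target_outcome_variance,
                100 * x$target_r2))
    invisible(x)
}

#' Simulate a calibrated variant panel
#'
#' Generates a [ScoringFile-class] of `m_variants` with effect-allele
#' frequencies from a uniform law on `[freq_min, 1 - freq_min]` and positive
#' weights of the form `w_j = (w0 + |u_j|) * h_j^(-gamma/2)` (with `u` half-
#' normal and `h_j = 2 f_j (1 - f_j)` the heterozygosity). The inverse
#' weight-frequency coupling mirrors power-limited GWAS discovery — variants
#' reach genome-wide significance near a constant `beta^2 * h` — and is the
#' degree of freedom that lets the expected weighted-PGS variance match
#' `target_pgs_sd^2`; `gamma` is solved numerically per preset. Frequency and
#' weight values are taken on quantile (stratified) grids of their laws, with
#' a seeded random pairing, which stabilizes the panel moments across
#' replicates. Per-variant imputation-quality metadata follows a Beta(8, 1)
#' law, so roughly 84% of variants survive the conventional r2 > 0.8 filter.
#'
#' When the preset's `apoe_like_gap` is set, the last variant is the planted
#' APOE-like marker `rs_apoe_like`: its base frequency is the first element
#' of the gap (the general-adult value) and [simulateGenotypes()] can plant
#' the second element in the elderly cohort via `freqOverride`.
#'
#' @param preset a [syntheticPreset()].
#' @param seed integer seed; the panel is deterministic given the seed.
#' @return a [ScoringFile-class].
#' @export
simulatePanel <- function(preset, seed = 1L) {
    M <- as.integer(preset$m_variants)
    fmin <- preset$freq_min
    if (fmin <= 0 || fmin >= 0.5) stop("freq_min must lie in (0, 0.5)")
    w0 <- preset$weight_jitter_offset
    if (w0 < 0) stop("weight_jitter_offset must be non-negative")
    fGrid <- fmin + (seq_len(M) - 0.5) / M * (1 - 2 * fmin)
    uGrid <- stats::qnorm(0.5 + (seq_len(M) - 0.5) / (2 * M))
    cGrid <- w0 + uGrid
    gamma <- .solvePanelGamma(fGrid, cGrid, preset$target_pgs_sd, M)
    .withSeed(seed, {
        f <- sample(fGrid)
        cc <- sample(cGrid)
        h <- 2 * f * (1 - f)
        w <- cc * h^(-gamma / 2)
        w <- w * 0.0025 / mean(w)       # GWAS-scale magnitudes, cosmetic
        r2 <- sample(stats::qbeta((seq_len(M) - 0.5) / M, 8, 1))
        ids <- sprintf("sv%05d", seq_len(M))
        chr <- as.character(sort(sample(1:22, M, replace = TRUE)))
        pos <- stats::ave(seq_len(M), chr, FUN = seq_along) * 10000L
        df <- data.frame(variant_id = ids, chr = chr, pos = pos,
                         effect_allele = "A", other_allele = "G",
                         effect_weight = w, effect_allele_freq = f,
                         imputation_r2 = r2, stringsAsFactors = FALSE)
        if (!is.null(preset$apoe_like_gap)) {
            df$variant_id[M] <- "rs_apoe_like"
            df$effect_allele_freq[M] <- preset$apoe_like_gap[1]
            df$imputation_r2[M] <- 0.99
        }
        sf <- ScoringFile(df, trait = preset$trait)
        metadata(sf@variants)$gamma <- gamma
        sf
    })
}

# solve the coupling exponent so the pairing-expected weighted-PGS variance,
# M * E[c^2] * E[h^(1-gamma)] / (E[c] * E[h^(-gamma/2)])^2, hits the target
.solvePanelGamma <- function(fGrid, cGrid, targetSd, M) {
    if (is.null(targetSd) || !is.finite(targetSd))
        return(0)
    h <- 2 * fGrid * (1 - fGrid)
    expVar <- function(g) {
        k <- h^(-g / 2)
        M * mean(cGrid^2) * mean(k^2 * h) / (mean(cGrid) * mean(k))^2
    }
    target <- targetSd^2
    lo <- 0; hi <- 12
    vlo <- expVar(lo)
    if (vlo <= target) return(lo)     # already at/below target: no coupling
    # expVar decreases from vlo towards a minimum and rises again; find a
    # bracket on the decreasing limb
    gs <- seq(0.1, hi, by = 0.1)
    vs <- vapply(gs, expVar, numeric(1))
    below <- which(vs <= target)
    if (!length(below))
        stop(sprintf(paste0("target PGS SD %.2f unreachable for this panel ",
            "(minimum attainable %.2f); widen freq_min or lower the target"),
            targetSd, sqrt(min(vs))))
    hi <- gs[below[1]]
    stats::uniroot(function(g) expVar(g) - target, c(lo, hi),
                   tol = 1e-10)$root
}

#' Simulate effect-allele dosages under Hardy-Weinberg equilibrium
#'
#' Hard genotypes are drawn per variant as Binomial(2, f) allele counts
#' (Hardy-Weinberg proportions). With `imputationR2 < 1`, zero-mean Gaussian
#' noise with variance `h (1 - r2) / r2` is added so that the squared
#' correlation between dosage and genotype is approximately `r2`, and the
#' result is clipped to `[0, 2]` (the clipping slightly attenuates the
#' realized variance at low quality; calibrated presets therefore use
#' `imputationR2 = 1`).
#'
#' @param panel a [ScoringFile-class] from [simulatePanel()] (its
#'   `effect_allele_freq` column supplies the frequencies).
#' @param n number of individuals.
#' @param imputationR2 scalar or per-variant vector in (0, 1]; 1 = exact
#'   genotypes.
#' @param seed integer seed.
#' @param freqOverride optional named numeric vector of per-variant frequency
#'   overrides (used to plant cohort-specific frequencies, e.g. the
#'   APOE-like gap).
#' @param sampleIdPrefix prefix for generated sample identifiers.
#' @return a [DosageMatrix-class] with allele annotations matching the panel.
#' @export
simulateGenotypes <- function(panel, n, imputationR2 = 1, seed = 1L,
                              freqOverride = NULL, sampleIdPrefix = "S") {
    stopifnot(n >= 1)
    v <- as.data.frame(panel)
    f <- v$effect_allele_freq
    if (is.null(f) || anyNA(f))
        stop("panel must carry effect_allele_freq for every variant")
    if (!is.null(freqOverride)) {
        idx <- match(names(freqOverride), v$variant_id)
        if (anyNA(idx)) stop("freqOverride names unknown to the panel")
        f[idx] <- freqOverride
    }
    M <- length(f)
    r2 <- rep_len(imputationR2, M)
    if (any(!is.finite(r2) | r2 <= 0 | r2 > 1))
        stop("imputationR2 must lie in (0, 1]")
    .withSeed(seed, {
        g <- matrix(stats::rbinom(as.double(n) * M, 2L, rep(f, each = n)),
                    nrow = n, ncol = M)
        d <- g * 1.0
        noisy <- which(r2 < 1)
        if (length(noisy)) {
            h <- 2 * f * (1 - f)
            for (j in noisy) {
                s <- sqrt(h[j] * (1 - r2[j]) / r2[j])
                d[, j] <- pmin(2, pmax(0, g[, j] +
                                           stats::rnorm(n, 0, s)))
            }
        }
        dimnames(d) <- list(
            sprintf("%s%05d", sampleIdPrefix, seq_len(n)), v$variant_id)
        DosageMatrix(d, samplesInRows = TRUE,
                     counted_allele = v$effect_allele,
                     other_allele = v$other_allele)
    })
}

#' Simulate a phenotyped cohort calibrated to the preset targets
#'
#' Generates demographics, comorbidities, principal components and a latent
#' eGFR of the form
#' `eGFR = mu + b_age (age - mean) + b_sex female + comorbidity effects +
#' b_PGS (PGS - mean) + eps`,
#' then emits the serum biomarker by exact inversion of the trait's CKD-EPI
#' equation so that the biomarker -> equation -> analysis round trip is
#' exercised downstream.
#'
#' Two calibration modes govern the PGS effect and the noise:
#' \describe{
#' \item{`"exact"` (default)}{the preset's model-1 targets are imposed as
#'   realized sample moments (in the spirit of
#'   `MASS::mvrnorm(empirical = TRUE)`): the noise is orthogonalized against
#'   the design, the PGS residual and the comorbidity residual, and scaled so
#'   that the age-/sex-/PC-adjusted residual variance equals
#'   `target_outcome_variance` exactly and the fitted second-stage
#'   coefficient equals `-sqrt(target_r2 * target_outcome_variance /
#'   var(PGS))` exactly. Every replicate then reproduces the target R^2 by
#'   construction, and replicate-to-replicate spread in the coefficient
#'   reflects only panel and genotype sampling.}
#' \item{`"sampling"`}{the textbook generative version: `b_PGS` is fixed at
#'   the same formula value and `eps` is iid Gaussian with variance
#'   `target_outcome_variance * (1 - target_r2) - var(comorbidity residual)`.
#'   Fitted quantities then scatter around the targets with the usual OLS
#'   sampling noise; use this mode for coverage and closure experiments.}
#' }
#'
#' Draws whose latent eGFR falls at or below 1 mL/min/1.73m2 trigger a
#' bounded redraw of the noise vector (the inversion requires positive eGFR).
#'
#' @param preset a [syntheticPreset()].
#' @param panel the [ScoringFile-class] for the preset's trait.
#' @param geno the cohort's [DosageMatrix-class].
#' @param seed integer seed.
#' @param mode `"exact"` or `"sampling"` (see Details).
#' @return a phenotype `data.frame` (one row per individual) with columns
#'   `sample_id`, `age`, `sex` ("F"/"M"), `creatinine`, `cystatin`,
#'   `cystatin_validity`, `bmi`, comorbidity flags, `smoking`,
#'   `education_years`, `pc1`..`pc10`, `study`; attributes `egfr_latent`
#'   (the latent eGFR) and `beta_pgs_true` (the PGS effect used).
#' @export
simulateCohort <- function(preset, panel, geno, seed = 1L,
                           mode = c("exact", "sampling")) {
    mode <- match.arg(mode)
    ids <- colnames(dosages(geno))
    n <- length(ids)
    stopifnot(n > 30)
    P <- computePgs(panel, geno)@weighted
    .withSeed(seed, {
        age <- stats::runif(n, preset$age_range[1], preset$age_range[2])
        female <- stats::rbinom(n, 1, preset$female_fraction)
        bmi <- pmin(60, pmax(15, stats::rnorm(n, preset$bmi_mean,
                                              preset$bmi_sd)))
        education <- round(pmin(25, pmax(6, stats::rnorm(n,
            preset$education_mean, preset$education_sd))), 1)
        smoking <- sample(names(preset$smoking_probs), n, replace = TRUE,
                          prob = preset$smoking_probs)
        pcs <- matrix(stats::rnorm(n * 10), n, 10,
                      dimnames = list(NULL, paste0("pc", 1:10)))
        flags <- lapply(preset$comorbidities, function(cm) {
            .drawComorbidity(age, cm[["prevalence"]],
                             preset$age_logit_slope)
        })
        C <- preset$bmi_effect * (bmi - preset$bmi_mean)
        for (nm in names(flags))
            C <- C + preset$comorbidities[[nm]][["effect"]] * flags[[nm]]

        X <- cbind(1, age = age, female = female, pcs)
        Qr <- .olsResid(P, X)
        vP <- stats::var(P)
        vQ <- sum(Qr^2) / (n - 1)
        A <- .olsResid(C, X)
        aCoef <- if (vQ > 0) sum(A * Qr) / sum(Qr^2) else 0
        Aperp <- A - aCoef * Qr
        vA <- sum(Aperp^2) / (n - 1)
        Vt <- preset$target_outcome_variance
        betaStar <- -sqrt(preset$target_r2 * Vt / vP)

        egfr <- NULL
        for (attempt in seq_len(30)) {
            if (mode == "exact") {
                betaC <- betaStar * vP / vQ
                tt <- betaC^2 * vQ
                sig2 <- Vt - tt - vA
                if (sig2 <= 0)
                    stop("comorbidity effects exceed the target outcome ",
                         "variance; reduce preset effect sizes")
                z <- stats::rnorm(n)
                u <- .olsResid(z, cbind(X, Qr, Aperp))
                u <- u / stats::sd(u)
                eps <- sqrt(sig2) * u
                betaUse <- betaC - aCoef
            } else {
                sig2 <- Vt * (1 - preset$target_r2) - vA
                if (sig2 <= 0)
                    stop("comorbidity effects exceed the target outcome ",
                         "variance; reduce preset effect sizes")
                eps <- stats::rnorm(n, 0, sqrt(sig2))
                betaUse <- betaStar
            }
            egfr <- preset$mu_egfr +
                preset$beta_age * (age - mean(age)) +
                preset$beta_female * (female - mean(female)) +
                (C - mean(C)) + betaUse * (P - mean(P)) + eps
            if (min(egfr) > 1) break
            egfr <- NULL
        }
        if (is.null(egfr))
            stop("could not draw an all-positive latent eGFR in 30 attempts")

        sexChr <- ifelse(female == 1, "F", "M")
        crea <- cys <- rep(NA_real_, n)
        if (preset$trait == "eGFRcrea") {
            crea <- invertEgfr(egfr, age, sexChr, "crea2009")
        } else {
            cys <- invertEgfr(egfr, age, sexChr, "cys2012")
        }
        validity <- rep(1L, n)
        if (preset$cystatin_contamination > 0) {
            k <- round(preset$cystatin_contamination * n)
            if (k > 0)
                validity[sample.int(n, k)] <- sample(2:4, k, replace = TRUE)
        }
        out <- data.frame(sample_id = ids, age = age, sex = sexChr,
            creatinine = crea, cystatin = cys, cystatin_validity = validity,
            bmi = bmi, diabetes = flags$diabetes,
            hypertension = flags$hypertension, cad = flags$cad,
            high_ceiling_diuretics = flags$high_ceiling_diuretics,
            smoking = smoking, education_years = education,
            stringsAsFactors = FALSE)
        out <- cbind(out, as.data.frame(pcs))
        out$study <- preset$study
        attr(out, "egfr_latent") <- egfr
        attr(out, "beta_pgs_true") <- if (mode == "exact") betaStar else
            betaStar
        attr(out, "mode") <- mode
        out
    })
}

# Bernoulli comorbidity with logistic age dependence; intercept solved so the
# realized-age marginal prevalence matches the preset value
.drawComorbidity <- function(age, prevalence, slope) {
    n <- length(age)
    if (prevalence <= 0) return(integer(n))
    if (prevalence >= 1) return(rep(1L, n))
    ac <- age - mean(age)
    a <- stats::uniroot(function(a0) mean(stats::plogis(a0 + slope * ac)) -
                            prevalence, c(-30, 30))$root
    stats::rbinom(n, 1, stats::plogis(a + slope * ac))
}

.olsResid <- function(y, X) {
    fit <- stats::lm.fit(as.matrix(X), y)
    unname(fit$residuals)
}

#' Write a synthetic fixture bundle
#'
#' Writes the scoring TSV, dosage TSV and phenotype TSV plus a JSON manifest
#' recording the seed and preset, such that [readFixtures()] reproduces the
#' in-memory objects exactly (numerics are serialized at full precision).
#'
#' @param panel a [ScoringFile-class].
#' @param geno a [DosageMatrix-class].
#' @param pheno phenotype data.frame from [simulateCohort()].
#' @param dir output directory (created if needed).
#' @param seed,preset recorded in the manifest for provenance.
#' @return named character vector of the written paths, invisibly.
#' @export
writeFixtures <- function(panel, geno, pheno, dir, seed = NULL,
                          preset = NULL) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(scoring = file.path(dir, "scoring.tsv"),
               dosages = file.path(dir, "dosages.tsv"),
               phenotypes = file.path(dir, "phenotypes.tsv"),
               manifest = file.path(dir, "manifest.json"))
    writeScoringFile(panel, paths["scoring"])
    writeDosageMatrix(geno, paths["dosages"])
    ph <- pheno
    attr(ph, "egfr_latent") <- NULL
    attr(ph, "beta_pgs_true") <- NULL
    attr(ph, "mode") <- NULL
    .writeTsvFull(ph, paths["phenotypes"])
    manifest <- list(seed = seed, trait = traitLabel(panel),
                     n_samples = ncol(dosages(geno)),
                     m_variants = nVariants(panel),
                     files = as.list(basename(paths[1:3])))
    if (!is.null(preset))
        manifest$preset <- unclass(preset)
    jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(paths)
}

#' Read a fixture bundle written by [writeFixtures()]
#'
#' @param dir directory containing the bundle.
#' @return list with `panel`, `geno`, `pheno`, `manifest`.
#' @export
readFixtures <- function(dir) {
    manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                    simplifyVector = TRUE)
    panel <- readScoringFile(file.path(dir, "scoring.tsv"),
                             trait = manifest$trait %||% "eGFRcrea")
    geno <- readDosageMatrix(file.path(dir, "dosages.tsv"), format = "tsv")
    pheno <- utils::read.delim(file.path(dir, "phenotypes.tsv"),
                               stringsAsFactors = FALSE)
    list(panel = panel, geno = geno, pheno = pheno, manifest = manifest)
}
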