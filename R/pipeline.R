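#' Assemble a run configuration
#'
#' Builds the configuration for [runComparison()]: which traits to analyze,
#' cohort sizes (defaulting to the preset values), the imputation-quality
#' filter for the frequency comparison, bootstrap replicates, the planted
#' APOE-like frequency gap, sensitivity exclusions, and the master seed. A
#' YAML file with the same keys can be passed instead (requires the `yaml`
#' package); unspecified keys keep their defaults.
#'
#' @param traits character subset of `c("eGFRcrea", "eGFRcys")`.
#' @param nGeneral,nElderly cohort sizes; `NULL` keeps the preset defaults
#'   (2,900 and 2,272).
#' @param mVariants panel size override for reduced-scale runs; `NULL` keeps
#'   the preset panels (634 creatinine, 204 cystatin variants). Small panels
#'   cannot reach the preset PGS-SD targets; the panel then falls back to
#'   uncoupled weights and the R^2 calibration still holds.
#' @param r2Filter imputation-quality threshold for the allele-frequency
#'   comparison (the PGS itself uses the full panel).
#' @param nBoot bootstrap replicates for R^2 CIs.
#' @param apoeLikeGap length-2 frequencies (general, elderly) for the planted
#'   APOE-like variant, or `NULL` to plant none.
#' @param excludeVariants variant ids for the sensitivity rerun (the planted
#'   APOE-like variant is always included when planted).
#' @param dosageScreen logical; run the per-variant pooled dosage association
#'   screen (slowest stage).
#' @param mode calibration mode passed to [simulateCohort()].
#' @param seed master seed; every stage derives its stream from it.
#' @return a list of class `"kidneyPGSConfig"`.
#' @export
comparisonConfig <- function(traits = c("eGFRcrea", "eGFRcys"),
                             nGeneral = NULL, nElderly = NULL,
                             mVariants = NULL,
                             r2Filter = 0.8, nBoot = 200,
                             apoeLikeGap = c(0.87, 0.89),
                             excludeVariants = character(),
                             dosageScreen = FALSE,
                             mode = "exact", seed = 1L) {
    cfg <- list(traits = match.arg(traits, several.ok = TRUE),
                nGeneral = nGeneral, nElderly = nElderly,
                mVariants = mVariants,
                r2Filter = r2Filter, nBoot = nBoot,
                apoeLikeGap = apoeLikeGap,
                excludeVariants = excludeVariants,
                dosageScreen = isTRUE(dosageScreen),
                mode = mode, seed = as.integer(seed))
    class(cfg) <- "kidneyPGSConfig"
    cfg
}

.loadConfig <- function(config) {
    if (is.character(config) && length(config) == 1L) {
        if (!requireNamespace("yaml", quietly = TRUE))
            stop("reading a YAML config requires the 'yaml' package")
        config <- yaml::read_yaml(config)
    }
    if (inherits(config, "kidneyPGSConfig")) return(config)
    do.call(comparisonConfig, config)
}

#' Run the full two-cohort comparison
#'
#' Executes the end-to-end analysis for each requested trait: simulate a
#' calibrated variant panel shared by both cohorts, simulate genotypes and
#' phenotypes for the general-adult and the elderly cohort, apply phenotype
#' QC, compute the PGS, fit the four-model adjustment ladder, run the
#' univariable covariate screen and the stepwise variance profile, compare
#' the PGS distributions between cohorts (Mann-Whitney), compare per-variant
#' allele frequencies (best-guess genotypes, imputation-quality filtered)
#' with enrichment and direction binomial tests and QQ data, and rerun the
#' model-1 fits with the configured variants (including the planted APOE-like
#' variant) excluded from the score.
#'
#' The run is fully deterministic given `config$seed`, and every reported
#' R^2 satisfies the decomposition identity
#' `R^2 = beta^2 Var(PGS) / Var(outcome)` (asserted programmatically).
#'
#' @param config a [comparisonConfig()], plain list, or YAML path.
#' @return a list of class `"kidneyPGSReport"`.
#' @export
runComparison <- function(config = comparisonConfig()) {
    cfg <- .loadConfig(config)
    seed <- cfg$seed
    report <- list(config = unclass(cfg), traits = list(),
                   r_version = as.character(getRversion()))
    for (ti in seq_along(cfg$traits)) {
        trait <- cfg$traits[ti]
        suffix <- if (trait == "eGFRcrea") "crea" else "cys"
        sG <- seed + 100L * ti
        presetG <- syntheticPreset(paste0("general_adults_", suffix),
                                   apoe_like_gap = cfg$apoeLikeGap)
        presetE <- syntheticPreset(paste0("elderly_", suffix),
                                   apoe_like_gap = cfg$apoeLikeGap)
        if (!is.null(cfg$nGeneral)) presetG$n <- as.integer(cfg$nGeneral)
        if (!is.null(cfg$nElderly)) presetE$n <- as.integer(cfg$nElderly)
        if (!is.null(cfg$mVariants)) {
            presetG$m_variants <- as.integer(cfg$mVariants)
            presetE$m_variants <- as.integer(cfg$mVariants)
        }
        panel <- simulatePanel(presetG, seed = sG)
        ovE <- if (!is.null(cfg$apoeLikeGap))
            c(rs_apoe_like = cfg$apoeLikeGap[2]) else NULL
        genoG <- simulateGenotypes(panel, presetG$n, seed = sG + 1L,
                                   sampleIdPrefix = "G")
        genoE <- simulateGenotypes(panel, presetE$n, seed = sG + 2L,
                                   freqOverride = ovE,
                                   sampleIdPrefix = "E")
        cohorts <- list(
            general_adults = list(preset = presetG, geno = genoG,
                pheno = simulateCohort(presetG, panel, genoG,
                                       seed = sG + 3L, mode = cfg$mode)),
            elderly = list(preset = presetE, geno = genoE,
                pheno = simulateCohort(presetE, panel, genoE,
                                       seed = sG + 4L, mode = cfg$mode)))

        tr <- list(panel_size = nVariants(panel))
        for (st in names(cohorts)) {
            co <- cohorts[[st]]
            qc <- phenotypeQc(co$pheno, study = st)
            pgs <- computePgs(panel, co$geno)
            ladder <- runModelLadder(qc$data, pgs, trait = trait,
                                     nBoot = cfg$nBoot,
                                     seed = sG + 10L + match(st, names(cohorts)))
            .assertDecomposition(ladder, qc$data, pgs, trait)
            screen <- covariateScreen(qc$data, trait = trait)
            profile <- stepwiseVarianceProfile(qc$data, pgs, trait = trait)
            sumPgs <- summarizePgs(pgs)
            varPgs <- sumPgs$sd[sumPgs$score == "weighted"]^2
            decomp <- data.frame(model = ladder$model,
                beta = ladder$beta1, var_pgs = varPgs,
                var_outcome = ladder$outcome_variance, r2 = ladder$r2)
            cohorts[[st]]$pgs <- pgs
            cohorts[[st]]$qc <- qc
            tr[[st]] <- list(summary = .cohortSummary(qc$data, sumPgs),
                             ladder = ladder, screen = screen,
                             profile = profile, decomposition = decomp,
                             qc_report = qc$report)
        }

        pgsG <- cohorts$general_adults$pgs
        pgsE <- cohorts$elderly$pgs
        tr$mann_whitney <- list(
            weighted = mannWhitneyTest(pgsG@weighted, pgsE@weighted),
            unweighted = mannWhitneyTest(pgsG@unweighted, pgsE@unweighted))

        hG <- harmonizeVariants(panel, genoG, r2Threshold = cfg$r2Filter)
        hE <- harmonizeVariants(panel, genoE, r2Threshold = cfg$r2Filter)
        shared <- intersect(variantIds(hG$score), variantIds(hE$score))
        bgG <- bestGuessGenotypes(hG$geno)[shared, , drop = FALSE]
        bgE <- bestGuessGenotypes(hE$geno)[shared, , drop = FALSE]
        fd <- freqDiffTest(bgE, bgG)   # study1 = elderly, study2 = general
        names(fd)[names(fd) == "eaf_study1"] <- "eaf_elderly"
        names(fd)[names(fd) == "eaf_study2"] <- "eaf_general"
        nominal <- fd$p_diff < 0.05
        enrich <- binomEnrichment(sum(nominal), nrow(fd), 0.05, "greater")
        lowerInElderly <- fd$eaf_elderly < fd$eaf_general
        direction <- if (sum(nominal) > 0)
            binomEnrichment(sum(nominal & lowerInElderly), sum(nominal),
                            0.5, "two_sided") else NULL
        tr$freq_comparison <- list(
            n_tested = nrow(fd), table = fd,
            enrichment = enrich, direction = direction,
            qq = qqPoints(fd$p_diff)$n_below_0.05,
            bonferroni_threshold = bonferroniThreshold(nrow(fd)))
        if (cfg$dosageScreen) {
            pooled <- cbind(dosages(genoE)[shared, , drop = FALSE],
                            dosages(genoG)[shared, , drop = FALSE])
            labels <- c(rep("elderly", ncol(dosages(genoE))),
                        rep("general", ncol(dosages(genoG))))
            ages <- c(cohorts$elderly$pheno$age,
                      cohorts$general_adults$pheno$age)
            tr$dosage_screen <- dosageAssociationScreen(pooled, labels, ages)
        }

        excl <- unique(c(cfg$excludeVariants,
                         if (!is.null(cfg$apoeLikeGap)) "rs_apoe_like"))
        excl <- intersect(excl, variantIds(panel))
        if (length(excl)) {
            panel2 <- excludeVariants(panel, excl)
            sens <- lapply(names(cohorts), function(st) {
                co <- cohorts[[st]]
                pgs2 <- computePgs(panel2, co$geno)
                lad2 <- runModelLadder(co$qc$data, pgs2, trait = trait,
                                       nBoot = 0)
                data.frame(study = st, model = lad2$model,
                           r2 = lad2$r2, beta1 = lad2$beta1,
                           r2_original = tr[[st]]$ladder$r2,
                           r2_change_pp = 100 * (lad2$r2 -
                                                 tr[[st]]$ladder$r2))
            })
            tr$sensitivity <- list(excluded = excl,
                                   ladder = do.call(rbind, sens))
        }
        report$traits[[trait]] <- tr
    }
    class(report) <- "kidneyPGSReport"
    report
}

.assertDecomposition <- function(ladder, pheno, pgs, trait) {
    prep <- .alignTraitData(pheno, pgs, trait)
    vp <- stats::var(prep$score)
    err <- abs(ladder$r2 -
               decomposeR2(ladder$beta1, vp, ladder$outcome_variance))
    if (any(err > 1e-10))
        stop("internal error: R^2 decomposition identity violated")
    invisible(TRUE)
}

.cohortSummary <- function(pheno, sumPgs) {
    num <- function(x) c(mean = mean(x, na.rm = TRUE),
                         sd = stats::sd(x, na.rm = TRUE))
    list(n = nrow(pheno),
         age = num(pheno$age),
         female_fraction = mean(pheno$sex == "F"),
         bmi = num(pheno$bmi),
         egfr_crea = num(pheno$egfr_crea),
         egfr_cys = num(pheno$egfr_cys),
         ckd_fraction = mean(pheno$ckd),
         diabetes = mean(pheno$diabetes),
         hypertension = mean(pheno$hypertension),
         cad = mean(pheno$cad),
         high_ceiling_diuretics = mean(pheno$high_ceiling_diuretics),
         pgs = sumPgs)
}

#' @export
print.kidneyPGSReport <- function(x, ...) {
    cat("kidneyPGS comparison report (seed", x$config$seed, ")\n")
    for (trait in names(x$traits)) {
        tr <- x$traits[[trait]]
        cat(sprintf("\n%s (%d variants):\n", trait, tr$panel_size))
        for (st in c("general_adults", "elderly")) {
            l1 <- tr[[st]]$ladder[1, ]
            cat(sprintf(
                "  %-15s model 1: var %7.2f  beta %+.3f [%.3f, %.3f]  R2 %.1f%%\n",
                st, l1$outcome_variance, l1$beta1, l1$ci_lo, l1$ci_hi,
                100 * l1$r2))
        }
        fc <- tr$freq_comparison
        cat(sprintf(
            "  freq tests: %d variants, %d nominal (enrichment p = %.3f)\n",
            fc$n_tested, fc$enrichment$k, fc$enrichment$p_bin))
    }
    invisible(x)
}

#' Write a comparison report to disk
#'
#' Emits the machine-readable master report (`report.json`), the ladder,
#' screen, profile and frequency tables as TSV, and a plain-text log with
#' stage names and the seed. Rerunning [runComparison()] with the seed
#' recorded in the report reproduces it.
#'
#' @param report a `"kidneyPGSReport"` from [runComparison()].
#' @param dir output directory (created if needed).
#' @return named vector of written paths, invisibly.
#' @export
writeReport <- function(report, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(json = file.path(dir, "report.json"),
               ladder = file.path(dir, "table2_ladder.tsv"),
               screen = file.path(dir, "fig2_screen.tsv"),
               profile = file.path(dir, "fig3_profile.tsv"),
               freq = file.path(dir, "fig4_freqdiff.tsv"),
               log = file.path(dir, "run.log"))
    jsonlite::write_json(.stripBulky(report), paths["json"],
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null", force = TRUE)
    collect <- function(what) {
        do.call(rbind, unlist(lapply(names(report$traits), function(trait) {
            lapply(c("general_adults", "elderly"), function(st) {
                df <- report$traits[[trait]][[st]][[what]]
                cbind(data.frame(trait = trait, study = st), df)
            })
        }), recursive = FALSE))
    }
    utils::write.table(collect("ladder"), paths["ladder"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(collect("screen"), paths["screen"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(collect("profile"), paths["profile"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    freq <- do.call(rbind, lapply(names(report$traits), function(trait) {
        cbind(data.frame(trait = trait),
              report$traits[[trait]]$freq_comparison$table)
    }))
    utils::write.table(freq, paths["freq"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    writeLines(c(
        sprintf("kidneyPGS run, seed %d", report$config$seed),
        sprintf("written %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
        sprintf("traits: %s", paste(names(report$traits), collapse = ", ")),
        sprintf("stages: simulate, score, egfr, associate, freqdiff, report")),
        paths["log"])
    invisible(paths)
}

# drop the large per-variant table from the JSON master (kept in the TSV)
.stripBulky <- function(report) {
    out <- unclass(report)
    for (trait in names(out$traits))
        out$traits[[trait]]$freq_comparison$table <- NULL
    out
}
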