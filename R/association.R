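#' Residualize an outcome on covariates
#'
#' Ordinary least-squares residuals of `y` on the given design columns, with
#' an intercept always included. This is the first stage of the two-stage
#' association model: eGFR is residualized on age, sex and ten genetic
#' principal components (plus, in later ladder models, comorbidities), and
#' the residuals are carried forward as the analysis outcome.
#'
#' @param y numeric outcome vector.
#' @param covariates data.frame or matrix of design columns (may have zero
#'   columns, in which case residuals are `y - mean(y)`).
#' @return numeric residual vector, orthogonal to every design column.
#' @export
residualize <- function(y, covariates = NULL) {
    y <- as.numeric(y)
    n <- length(y)
    if (is.null(covariates) || NCOL(covariates) == 0L)
        return(y - mean(y))
    X <- cbind(`(Intercept)` = 1, as.matrix(covariates))
    if (n <= ncol(X))
        stop("need more observations than design columns")
    fit <- stats::lm.fit(X, y)
    if (fit$rank < ncol(X)) {
        dropped <- colnames(X)[is.na(fit$coefficients)]
        stop("rank-deficient design; collinear column(s): ",
             paste(dropped, collapse = ", "))
    }
    unname(fit$residuals)
}

#' Explained-variance decomposition
#'
#' The single-predictor identity `R^2 = beta^2 * Var(PGS) / Var(outcome)`:
#' the variance a PGS explains is driven by three components — the squared
#' association coefficient, the PGS variance, and the outcome variance. The
#' identity holds exactly for a simple regression when all variances use the
#' same (n-1) convention.
#'
#' @param beta1 regression coefficient of the outcome on the PGS.
#' @param varPgs sample variance of the PGS.
#' @param varOutcome sample variance of the outcome (> 0).
#' @return the explained-variance fraction.
#' @export
decomposeR2 <- function(beta1, varPgs, varOutcome) {
    if (any(varPgs < 0)) stop("varPgs must be non-negative")
    if (any(varOutcome <= 0)) stop("varOutcome must be positive")
    beta1^2 * varPgs / varOutcome
}

#' Fit the second-stage PGS regression
#'
#' Simple OLS of the (covariate-adjusted) outcome residuals on the weighted
#' PGS: `Y_i = beta0 + beta1 * PGS_i + eps_i`. Reports the coefficient with
#' t-based 95% CI and two-sided p-value, the R^2 of the PGS, the outcome
#' variance (n-1 sample variance of the residual outcome — the "residual
#' variance" column of the ladder table), and a seeded nonparametric pairs
#' bootstrap percentile CI for R^2.
#'
#' @param residuals numeric outcome vector (typically from [residualize()]).
#' @param pgs numeric PGS vector or a [PgsVector-class] (weighted score used).
#' @param nBoot bootstrap replicates for the R^2 CI (0 disables).
#' @param seed integer seed for the bootstrap (RNG state is restored).
#' @return one-row data.frame: `n`, `outcome_variance`, `beta0`, `beta1`,
#'   `se`, `ci_lo`, `ci_hi`, `pvalue`, `r2`, `r2_lo`, `r2_hi`.
#' @export
fitPgsModel <- function(residuals, pgs, nBoot = 1000, seed = 1L) {
    x <- if (methods::is(pgs, "PgsVector")) pgs@weighted else as.numeric(pgs)
    y <- as.numeric(residuals)
    ok <- stats::complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    n <- length(y)
    if (n < 3L) stop("need at least 3 paired observations")
    if (stats::var(x) == 0) stop("degenerate predictor: PGS is constant")
    sxx <- stats::var(x)
    syy <- stats::var(y)
    beta1 <- stats::cov(x, y) / sxx
    beta0 <- mean(y) - beta1 * mean(x)
    res <- y - beta0 - beta1 * x
    sigma2 <- sum(res^2) / (n - 2)
    se <- sqrt(sigma2 / ((n - 1) * sxx))
    tval <- beta1 / se
    pvalue <- 2 * stats::pt(-abs(tval), df = n - 2)
    tcrit <- stats::qt(0.975, df = n - 2)
    r2 <- decomposeR2(beta1, sxx, syy)
    r2ci <- c(NA_real_, NA_real_)
    if (nBoot > 0) {
        r2b <- .withSeed(seed, {
            vapply(seq_len(nBoot), function(b) {
                i <- sample.int(n, n, replace = TRUE)
                xb <- x[i]; yb <- y[i]
                vb <- stats::var(xb)
                if (vb == 0) return(NA_real_)
                decomposeR2(stats::cov(xb, yb) / vb, vb, stats::var(yb))
            }, numeric(1))
        })
        r2ci <- unname(stats::quantile(r2b, c(0.025, 0.975), na.rm = TRUE))
    }
    data.frame(n = n, outcome_variance = syy, beta0 = beta0, beta1 = beta1,
               se = se, ci_lo = beta1 - tcrit * se, ci_hi = beta1 + tcrit * se,
               pvalue = pvalue, r2 = r2, r2_lo = r2ci[1], r2_hi = r2ci[2])
}

# evaluate expr under a temporary seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
    hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (hadSeed) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (hadSeed) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

.ladderCovariates <- list(
    `1` = character(),
    `2` = "bmi",
    `3` = c("bmi", "diabetes", "hypertension"),
    `4` = c("bmi", "diabetes", "hypertension", "cad",
            "high_ceiling_diuretics"))

.designMatrix <- function(pheno, extra = character()) {
    pcs <- paste0("pc", 1:10)
    need <- c("age", "sex", pcs, extra)
    miss <- setdiff(need, c(colnames(pheno), "sex"))
    if (length(miss))
        stop("phenotype table lacks covariate column(s): ",
             paste(miss, collapse = ", "))
    X <- cbind(age = pheno$age,
               female = as.numeric(.sexKey(pheno$sex) == "female"),
               as.matrix(pheno[, pcs, drop = FALSE]))
    if (length(extra))
        X <- cbind(X, as.matrix(pheno[, extra, drop = FALSE]))
    X
}

#' Run the four-model covariate-adjustment ladder
#'
#' Reproduces the ladder of adjustment models: model 1 residualizes eGFR on
#' age, sex and ten principal components; model 2 adds BMI; model 3 adds
#' diabetes and hypertension; model 4 adds CAD and high-ceiling diuretics
#' intake. Each stage's residuals are then regressed on the weighted PGS via
#' [fitPgsModel()]. Principal components enter the residualization stage, so
#' the second stage is strictly the simple regression of residuals on PGS.
#'
#' @param pheno phenotype data.frame (see [phenotypeQc()]; must carry the
#'   trait's eGFR column `egfr_crea` / `egfr_cys` and its `use_*` flag, or a
#'   raw biomarker from which they can be derived).
#' @param pgs a [PgsVector-class] aligned with `pheno$sample_id`.
#' @param trait `"eGFRcrea"` or `"eGFRcys"`.
#' @param nBoot,seed bootstrap settings passed to [fitPgsModel()].
#' @return data.frame with one row per model (`model` = 1..4) and the
#'   [fitPgsModel()] columns: the residual eGFR variance, beta with 95% CI
#'   and p-value, and R^2 with bootstrap CI.
#' @export
runModelLadder <- function(pheno, pgs, trait = c("eGFRcrea", "eGFRcys"),
                           nBoot = 1000, seed = 1L) {
    trait <- match.arg(trait)
    prep <- .alignTraitData(pheno, pgs, trait)
    out <- lapply(names(.ladderCovariates), function(m) {
        X <- .designMatrix(prep$pheno, .ladderCovariates[[m]])
        resid <- residualize(prep$egfr, X)
        fit <- fitPgsModel(resid, prep$score, nBoot = nBoot,
                           seed = seed + as.integer(m))
        cbind(data.frame(model = as.integer(m), trait = trait), fit)
    })
    do.call(rbind, out)
}

.alignTraitData <- function(pheno, pgs, trait) {
    stopifnot(is.data.frame(pheno))
    col <- if (trait == "eGFRcrea") "egfr_crea" else "egfr_cys"
    if (!col %in% colnames(pheno)) {
        qc <- phenotypeQc(pheno, study = "elderly")  # no age cap re-applied
        pheno <- qc$data
    }
    useCol <- if (trait == "eGFRcrea") "use_crea" else "use_cys"
    keep <- if (useCol %in% colnames(pheno)) pheno[[useCol]] else
        !is.na(pheno[[col]])
    pheno <- pheno[keep, , drop = FALSE]
    sdf <- as.data.frame(pgs)
    idx <- match(pheno$sample_id, sdf$sample_id)
    if (anyNA(idx))
        stop("PGS missing for some phenotype samples")
    list(pheno = pheno, egfr = pheno[[col]], score = sdf$weighted[idx])
}

#' Univariable covariate screen
#'
#' One simple linear regression of the raw (unadjusted) trait eGFR on each
#' covariable — age, sex, BMI, diabetes, hypertension, CAD, high-ceiling
#' diuretics, smoking (two dummies: former, current, sharing the joint two-
#' dummy R^2) and education — reporting beta, 95% CI and the explained
#' variance R^2 per covariable.
#'
#' @inheritParams runModelLadder
#' @return data.frame `covariable`, `beta`, `ci_lo`, `ci_hi`, `r2`, `n`.
#' @export
covariateScreen <- function(pheno, trait = c("eGFRcrea", "eGFRcys")) {
    trait <- match.arg(trait)
    col <- if (trait == "eGFRcrea") "egfr_crea" else "egfr_cys"
    if (!col %in% colnames(pheno))
        stop("phenotype table lacks computed eGFR column '", col,
             "'; run phenotypeQc() first")
    y <- pheno[[col]]
    vars <- list(
        age = pheno$age,
        female = as.numeric(.sexKey(pheno$sex) == "female"),
        bmi = pheno$bmi,
        diabetes = pheno$diabetes,
        hypertension = pheno$hypertension,
        cad = pheno$cad,
        high_ceiling_diuretics = pheno$high_ceiling_diuretics,
        education_years = pheno$education_years)
    rows <- list()
    for (nm in names(vars)) {
        x <- vars[[nm]]
        if (is.null(x)) next
        ok <- stats::complete.cases(x, y)
        if (stats::var(x[ok]) == 0) {
            warning("covariable '", nm, "' is constant; skipped")
            next
        }
        f <- stats::lm(y[ok] ~ x[ok])
        s <- summary(f)
        ci <- stats::confint(f)[2, ]
        rows[[nm]] <- data.frame(covariable = nm,
            beta = stats::coef(f)[2], ci_lo = ci[1], ci_hi = ci[2],
            r2 = s$r.squared, n = sum(ok), stringsAsFactors = FALSE)
    }
    if (!is.null(pheno$smoking)) {
        sm <- factor(pheno$smoking, levels = c("never", "former", "current"))
        ok <- stats::complete.cases(sm, y)
        if (nlevels(droplevels(sm[ok])) > 1) {
            f <- stats::lm(y[ok] ~ sm[ok])
            s <- summary(f)
            co <- summary(f)$coefficients
            ci <- stats::confint(f)
            for (lev in c("former", "current")) {
                rn <- paste0("sm[ok]", lev)
                if (rn %in% rownames(co))
                    rows[[paste0("smoking_", lev)]] <- data.frame(
                        covariable = paste0("smoking_", lev),
                        beta = co[rn, 1], ci_lo = ci[rn, 1], ci_hi = ci[rn, 2],
                        r2 = s$r.squared, n = sum(ok),
                        stringsAsFactors = FALSE)
            }
        } else warning("covariable 'smoking' is constant; skipped")
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Stepwise residual-variance profile
#'
#' Residual variance of the trait eGFR after cumulatively adding covariates
#' in a fixed order (default: age, sex, BMI, diabetes, hypertension, CAD,
#' high-ceiling diuretics), with the PGS always added last. Ten principal
#' components accompany the first step. The sequence is non-increasing (a
#' nested-OLS property with the fixed n-1 denominator).
#'
#' @inheritParams runModelLadder
#' @param order character vector of covariate columns to add stepwise.
#' @return data.frame `step`, `added`, `residual_variance`.
#' @export
stepwiseVarianceProfile <- function(pheno, pgs,
        trait = c("eGFRcrea", "eGFRcys"),
        order = c("age", "sex", "bmi", "diabetes", "hypertension", "cad",
                  "high_ceiling_diuretics")) {
    trait <- match.arg(trait)
    prep <- .alignTraitData(pheno, pgs, trait)
    ph <- prep$pheno
    pcs <- paste0("pc", 1:10)
    cols <- list()
    rows <- data.frame(step = 0L, added = "none",
                       residual_variance = stats::var(prep$egfr))
    step <- 0L
    for (nm in order) {
        step <- step + 1L
        newcol <- if (nm == "sex")
            cbind(female = as.numeric(.sexKey(ph$sex) == "female"))
        else cbind(stats::setNames(ph[, nm, drop = FALSE], nm))
        cols[[nm]] <- as.matrix(newcol)
        if (step == 1L) cols[["pcs"]] <- as.matrix(ph[, pcs, drop = FALSE])
        X <- do.call(cbind, cols)
        rv <- stats::var(residualize(prep$egfr, X))
        rows <- rbind(rows, data.frame(step = step, added = nm,
                                       residual_variance = rv))
    }
    cols[["pgs"]] <- cbind(pgs = prep$score)
    X <- do.call(cbind, cols)
    rows <- rbind(rows, data.frame(step = step + 1L, added = "pgs",
        residual_variance = stats::var(residualize(prep$egfr, X))))
    rows
}

#' Mann-Whitney U test for two PGS distributions
#'
#' Compares the score distributions of two cohorts. For small samples
#' (`min(n1, n2) <= 8`) the permutation null is enumerated exactly over all
#' `choose(n1+n2, n1)` group assignments; otherwise a tie-corrected normal
#' approximation (no continuity correction) is used. The two-sided p-value is
#' `P(|U - n1*n2/2| >= |u_obs - n1*n2/2|)`.
#'
#' @param x,y numeric vectors (e.g. weighted PGS per cohort).
#' @param exact force (`TRUE`) or forbid (`FALSE`) exact enumeration;
#'   `NULL` (default) chooses by sample size.
#' @return list with `U` (statistic for `x`), `pvalue`, `method`.
#' @export
mannWhitneyTest <- function(x, y, exact = NULL) {
    x <- as.numeric(x[!is.na(x)])
    y <- as.numeric(y[!is.na(y)])
    n1 <- length(x); n2 <- length(y)
    if (n1 == 0L || n2 == 0L) stop("both samples must be non-empty")
    pooled <- c(x, y)
    r <- rank(pooled)
    U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    doExact <- if (is.null(exact)) min(n1, n2) <= 8L else isTRUE(exact)
    if (doExact) {
        dev <- abs(U - mu)
        combs <- utils::combn(n1 + n2, n1)
        devs <- apply(combs, 2L, function(i) {
            abs(sum(r[i]) - n1 * (n1 + 1) / 2 - mu)
        })
        p <- mean(devs >= dev - 1e-9)
        list(U = U, pvalue = p, method = "exact enumeration")
    } else {
        N <- n1 + n2
        ties <- table(pooled)
        tieCorr <- sum(ties^3 - ties) / (N * (N - 1))
        sigma <- sqrt(n1 * n2 / 12 * (N + 1 - tieCorr))
        if (sigma == 0) return(list(U = U, pvalue = 1,
                                    method = "normal approximation"))
        z <- (U - mu) / sigma
        list(U = U, pvalue = 2 * stats::pnorm(-abs(z)),
             method = "normal approximation (tie-corrected)")
    }
}
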