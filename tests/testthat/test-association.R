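test_that("residualize matches the normal-equations solution", {
    # 6-point fixture solved via the normal equations in the test itself
    age <- c(31, 45, 52, 60, 38, 49)
    y <- c(101, 88, 84, 70, 95, 86)
    X <- cbind(1, age)
    betaHat <- solve(t(X) %*% X, t(X) %*% y)
    expect_equal(residualize(y, cbind(age = age)),
                 as.numeric(y - X %*% betaHat), tolerance = 1e-10)
    # no covariates -> centering
    expect_equal(residualize(y), y - mean(y))
    # exact linear outcome -> zero residuals
    expect_equal(residualize(3 * age + 1, cbind(age = age)),
                 rep(0, 6), tolerance = 1e-10)
})

test_that("residuals are orthogonal to the design and collinearity is named", {
    set.seed(11)
    n <- 150
    X <- cbind(a = rnorm(n), b = runif(n), c = rbinom(n, 1, 0.4))
    y <- 2 + X %*% c(1, -2, 0.5) + rnorm(n)
    r <- residualize(y, X)
    expect_lt(max(abs(crossprod(cbind(1, X), r))), 1e-8 * n)
    Xbad <- cbind(X, dup = X[, "a"] * 2)
    expect_error(residualize(y, Xbad), "dup")
})

test_that("the PGS regression reproduces hand-computed OLS", {
    x <- c(0, 1, 2, 3, 4)
    y <- c(1, 0, 2, 1, 3)
    fit <- fitPgsModel(y, x, nBoot = 0)
    expect_equal(fit$beta1, 0.5)
    expect_equal(fit$r2, 0.25 * 10 / 5.2, tolerance = 1e-10)  # 0.4808
    expect_equal(fit$outcome_variance, var(y))
    # cross-check against stats::lm
    lmfit <- lm(y ~ x)
    expect_equal(fit$se, summary(lmfit)$coefficients[2, 2])
    expect_equal(fit$pvalue, summary(lmfit)$coefficients[2, 4])
    expect_equal(unname(c(fit$ci_lo, fit$ci_hi)),
                 unname(confint(lmfit)[2, ]))
    # exact linear relation
    pgs <- 1:20
    fit2 <- fitPgsModel(2 - 0.5 * pgs, pgs, nBoot = 0)
    expect_equal(fit2$beta1, -0.5)
    expect_equal(fit2$r2, 1)
    expect_lt(fit2$pvalue, 1e-200)
    expect_error(fitPgsModel(rnorm(10), rep(1, 10)), "constant")
})

test_that("every fit satisfies the R2 decomposition identity", {
    set.seed(23)
    for (i in 1:25) {
        n <- sample(10:200, 1)
        x <- rnorm(n, sd = runif(1, 0.5, 20))
        y <- rnorm(n, mean = -0.3 * x, sd = runif(1, 0.5, 15))
        fit <- fitPgsModel(y, x, nBoot = 0)
        expect_equal(fit$r2, decomposeR2(fit$beta1, var(x), var(y)),
                     tolerance = 1e-10)
    }
})

test_that("decomposeR2 computes beta^2 Var(PGS) / Var(outcome)", {
    expect_equal(decomposeR2(0, 100, 50), 0)
    expect_equal(decomposeR2(1, 7, 7), 1)
    # printed-scale example: beta -0.23, PGS SD 14.0, outcome variance 228.93
    expect_equal(decomposeR2(-0.23, 14^2, 228.93), 0.0453, tolerance = 1e-3)
    expect_error(decomposeR2(1, 1, 0), "positive")
    expect_error(decomposeR2(1, -1, 1), "non-negative")
})

test_that("bootstrap R2 intervals are seeded and leave the RNG untouched", {
    set.seed(99)
    x <- rnorm(300); y <- -0.4 * x + rnorm(300)
    before <- .Random.seed
    f1 <- fitPgsModel(y, x, nBoot = 200, seed = 7)
    expect_identical(.Random.seed, before)
    f2 <- fitPgsModel(y, x, nBoot = 200, seed = 7)
    expect_equal(f1$r2_lo, f2$r2_lo)
    expect_true(f1$r2_lo < f1$r2 && f1$r2 < f1$r2_hi)
})

test_that("the model ladder has the Table-2 shape and reacts to injected effects", {
    p <- syntheticPreset("custom", n = 900L, m_variants = 30L,
                         target_r2 = 0.05)
    panel <- simulatePanel(p, seed = 31)
    geno <- simulateGenotypes(panel, p$n, seed = 32)
    pgs <- computePgs(panel, geno)
    pheno <- simulateCohort(p, panel, geno, seed = 33)
    qc <- phenotypeQc(pheno, study = "general_adults")
    lad <- runModelLadder(qc$data, pgs, "eGFRcrea", nBoot = 0)
    expect_equal(lad$model, 1:4)
    expect_equal(nrow(lad), 4L)
    # model 2 must reduce the residual variance when BMI truly affects eGFR
    pBmi <- syntheticPreset("custom", n = 900L, m_variants = 30L,
                            bmi_effect = -1.5)
    phB <- simulateCohort(pBmi, panel, geno, seed = 34)
    ladB <- runModelLadder(phenotypeQc(phB, "general_adults")$data, pgs,
                           "eGFRcrea", nBoot = 0)
    expect_lt(ladB$outcome_variance[2], ladB$outcome_variance[1] - 5)
    # with all covariate effects null the ladder variances barely move
    p0 <- syntheticPreset("custom", n = 900L, m_variants = 30L,
        bmi_effect = 0,
        comorbidities = list(diabetes = c(prevalence = 0.2, effect = 0),
            hypertension = c(prevalence = 0.3, effect = 0),
            cad = c(prevalence = 0.1, effect = 0),
            high_ceiling_diuretics = c(prevalence = 0.1, effect = 0)))
    ph0 <- simulateCohort(p0, panel, geno, seed = 35)
    lad0 <- runModelLadder(phenotypeQc(ph0, "general_adults")$data, pgs,
                           "eGFRcrea", nBoot = 0)
    spread <- diff(range(lad0$outcome_variance)) / lad0$outcome_variance[1]
    expect_lt(spread, 0.01)
    expect_lt(diff(range(lad0$beta1)), 0.05)
    # missing covariate column is named
    broken <- qc$data; broken$bmi <- NULL
    expect_error(runModelLadder(broken, pgs, "eGFRcrea", nBoot = 0), "bmi")
})

test_that("the univariable screen recovers analytic R2 and orderings", {
    set.seed(55)
    n <- 1500
    bmi <- rnorm(n, 27, 4.5)
    egfr <- 120 - 5 * bmi + rnorm(n, sd = 10)
    ph <- data.frame(sample_id = seq_len(n), age = runif(n, 30, 60),
                     sex = "M", bmi = bmi, diabetes = 0L,
                     hypertension = rbinom(n, 1, 0.3), cad = 0L,
                     high_ceiling_diuretics = 0L,
                     education_years = rnorm(n, 12, 3),
                     smoking = sample(c("never", "former", "current"), n,
                                      replace = TRUE),
                     egfr_crea = egfr, stringsAsFactors = FALSE)
    sc <- suppressWarnings(covariateScreen(ph, "eGFRcrea"))
    expect_false("diabetes" %in% sc$covariable)   # constant -> skipped
    r2Expected <- 25 * var(bmi) / var(egfr)
    expect_equal(sc$r2[sc$covariable == "bmi"], r2Expected,
                 tolerance = 0.02)
    # a covariable made orthogonal to eGFR explains ~nothing
    ortho <- residualize(rnorm(n), cbind(egfr))
    ph$education_years <- ortho
    sc2 <- suppressWarnings(covariateScreen(ph, "eGFRcrea"))
    expect_lt(sc2$r2[sc2$covariable == "education_years"], 3 / n)
    # smoking enters as two dummies sharing the joint R2
    expect_equal(sc2$r2[sc2$covariable == "smoking_former"],
                 sc2$r2[sc2$covariable == "smoking_current"])
})

test_that("elderly preset puts age above education in the screen", {
    p <- syntheticPreset("elderly_crea", n = 1200L, m_variants = 40L)
    panel <- simulatePanel(p, seed = 61)
    geno <- simulateGenotypes(panel, p$n, seed = 62)
    pheno <- simulateCohort(p, panel, geno, seed = 63)
    qc <- phenotypeQc(pheno, study = "elderly")
    sc <- covariateScreen(qc$data, "eGFRcrea")
    expect_gt(sc$r2[sc$covariable == "age"],
              sc$r2[sc$covariable == "education_years"])
})

test_that("the stepwise variance profile is non-increasing with PGS last", {
    p <- syntheticPreset("custom", n = 700L, m_variants = 25L,
                         target_r2 = 0.08)
    panel <- simulatePanel(p, seed = 71)
    geno <- simulateGenotypes(panel, p$n, seed = 72)
    pgs <- computePgs(panel, geno)
    pheno <- simulateCohort(p, panel, geno, seed = 73)
    qc <- phenotypeQc(pheno, study = "general_adults")
    prof <- stepwiseVarianceProfile(qc$data, pgs, "eGFRcrea")
    expect_true(all(diff(prof$residual_variance) <= 1e-10))
    expect_equal(prof$added[nrow(prof)], "pgs")
    # the final PGS step removes ~R2 of the preceding residual variance
    lad <- runModelLadder(qc$data, pgs, "eGFRcrea", nBoot = 0)
    m4 <- lad[lad$model == 4, ]
    before <- prof$residual_variance[nrow(prof) - 1]
    after <- prof$residual_variance[nrow(prof)]
    expect_equal((before - after) / before, m4$r2, tolerance = 0.05)
})

test_that("Mann-Whitney matches enumeration, ties and the normal reference", {
    r <- mannWhitneyTest(c(1, 2), c(3, 4))
    expect_equal(r$U, 0)
    expect_equal(r$pvalue, 1 / 3)       # 2/6 arrangements as extreme
    # identical multisets
    expect_equal(mannWhitneyTest(c(5, 6, 7), c(7, 5, 6))$pvalue, 1)
    expect_equal(mannWhitneyTest(rnorm(40) * 0 + 1, rep(1, 50))$pvalue, 1)
    # large-sample path vs the exact Wilcoxon distribution (no ties)
    set.seed(17)
    x <- runif(50); y <- runif(50)
    r2 <- mannWhitneyTest(x, y)
    exact <- {
        u <- r2$U
        mu <- 50 * 50 / 2
        lo <- min(u, 2 * mu - u)
        2 * pwilcox(lo, 50, 50)
    }
    expect_lt(abs(r2$pvalue - exact), 0.02)
    # and against R's implementation without continuity correction
    w <- wilcox.test(x, y, exact = FALSE, correct = FALSE)
    expect_equal(r2$pvalue, w$p.value, tolerance = 1e-10)
    expect_error(mannWhitneyTest(numeric(0), 1), "non-empty")
})

test_that("beta CIs cover the simulated truth at the nominal rate", {
    # sampling mode: iid noise, fixed true coefficient
    p <- syntheticPreset("custom", n = 400L, m_variants = 15L,
                         target_r2 = 0.06)
    panel <- simulatePanel(p, seed = 81)
    nrep <- 400
    covered <- logical(nrep)
    for (i in seq_len(nrep)) {
        geno <- simulateGenotypes(panel, p$n, seed = 1000 + i)
        pheno <- simulateCohort(p, panel, geno, seed = 5000 + i,
                                mode = "sampling")
        qc <- phenotypeQc(pheno, study = "general_adults")
        pgs <- computePgs(panel, geno)
        X <- cbind(age = qc$data$age,
                   female = as.numeric(qc$data$sex == "F"),
                   as.matrix(qc$data[, paste0("pc", 1:10)]))
        fit <- fitPgsModel(residualize(qc$data$egfr_crea, X),
                           pgs@weighted, nBoot = 0)
        truth <- attr(pheno, "beta_pgs_true")
        covered[i] <- fit$ci_lo <= truth && truth <= fit$ci_hi
    }
    # 99% binomial band around 0.95 at 400 replicates
    expect_gt(mean(covered), 0.95 - 2.58 * sqrt(0.95 * 0.05 / nrep))
    expect_lt(mean(covered), 0.95 + 2.58 * sqrt(0.95 * 0.05 / nrep))
})
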