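# in-code fixtures shared across test files

makeScoringDf <- function(m = 3, weights = c(0.001, 0.002, 0.003),
                          freqs = NULL, r2 = NULL) {
    df <- data.frame(variant_id = paste0("rs", seq_len(m)),
                     chr = "1", pos = seq_len(m) * 100L,
                     effect_allele = "A", other_allele = "G",
                     effect_weight = rep_len(weights, m),
                     stringsAsFactors = FALSE)
    if (!is.null(freqs)) df$effect_allele_freq <- rep_len(freqs, m)
    if (!is.null(r2)) df$imputation_r2 <- rep_len(r2, m)
    df
}

writeScoringTsv <- function(df, path = tempfile(fileext = ".tsv")) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
}

makeDosage <- function(values, sampleIds = NULL, variantIds = NULL) {
    m <- as.matrix(values)
    rownames(m) <- sampleIds %||% paste0("s", seq_len(nrow(m)))
    colnames(m) <- variantIds %||% paste0("rs", seq_len(ncol(m)))
    DosageMatrix(m, samplesInRows = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one small simulated cohort + fitted model-1, via the exported surface only
model1Fit <- function(presetName, seed, mode = "exact", ...) {
    p <- syntheticPreset(presetName, ...)
    panel <- simulatePanel(p, seed = seed)
    geno <- simulateGenotypes(panel, p$n, seed = seed + 1L)
    pheno <- simulateCohort(p, panel, geno, seed = seed + 2L, mode = mode)
    qc <- phenotypeQc(pheno, study = p$study)
    pgs <- computePgs(panel, geno)
    X <- cbind(age = qc$data$age,
               female = as.numeric(qc$data$sex == "F"),
               as.matrix(qc$data[, paste0("pc", 1:10)]))
    y <- if (p$trait == "eGFRcrea") qc$data$egfr_crea else qc$data$egfr_cys
    fit <- fitPgsModel(residualize(y, X), pgs@weighted, nBoot = 0)
    fit$beta_true <- attr(pheno, "beta_pgs_true")
    fit
}

# independent oracles ------------------------------------------------------

# textbook Pearson statistic on a 2x2 table
pearsonOracle <- function(tab) {
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - E)^2 / E)
}

# exact binomial tails by direct enumeration of the pmf
binomOracle <- function(k, n, p0, alternative) {
    probs <- exp(lchoose(n, 0:n) + (0:n) * log(p0) +
                 (n - (0:n)) * log(1 - p0))
    if (alternative == "greater") {
        sum(probs[(k:n) + 1])
    } else {
        sum(probs[probs <= probs[k + 1] * (1 + 1e-7)])
    }
}

# Mann-Whitney permutation p by brute force over all n! orderings
allPerms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
        out <- c(out, lapply(allPerms(v[-i]), function(p) c(v[i], p)))
    out
}

mannWhitneyOracle <- function(x, y) {
    n1 <- length(x); n2 <- length(y)
    pooled <- c(x, y)
    uStat <- function(a, b) {
        sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
    }
    mu <- n1 * n2 / 2
    obs <- abs(uStat(x, y) - mu)
    devs <- vapply(allPerms(seq_along(pooled)), function(ord) {
        p <- pooled[ord]
        abs(uStat(p[seq_len(n1)], p[-seq_len(n1)]) - mu)
    }, numeric(1))
    mean(devs >= obs - 1e-9)
}
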