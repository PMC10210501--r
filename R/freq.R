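#' Best-guess genotypes from dosages
#'
#' Rounds imputed dosages to hard genotypes {0, 1, 2} by nearest integer,
#' with half-values rounded up (0.5 -> 1, 1.5 -> 2); missing stays missing.
#'
#' @param d a [DosageMatrix-class] or numeric dosage matrix.
#' @return an integer matrix in the same orientation.
#' @export
bestGuessGenotypes <- function(d) {
    m <- if (methods::is(d, "DosageMatrix")) dosages(d) else as.matrix(d)
    if (any(!is.na(m) & (m < 0 | m > 2)))
        stop("dosages must lie in [0, 2]")
    g <- floor(m + 0.5)          # round-half-up
    g[!is.na(g) & g > 2] <- 2
    storage.mode(g) <- "integer"
    g
}

#' Per-variant allele-frequency difference test
#'
#' For each variant, builds the 2x2 effect/other allele-count table (2N
#' alleles per study) from best-guess genotypes and applies Pearson's
#' chi-squared test with 1 df. No Yates continuity correction is applied by
#' default (a documented switch is provided). Variants whose test has an
#' expected cell below 1 are flagged; variants with zero total alleles in a
#' study are skipped with a warning.
#'
#' @param genos1,genos2 integer genotype matrices (variants x samples) for
#'   study 1 and study 2, e.g. from [bestGuessGenotypes()]; rows matched by
#'   rownames.
#' @param correct logical; apply the continuity correction (default FALSE).
#' @param alpha nominal significance level for the tiers.
#' @return data.frame per variant: `variant_id`, `eaf_study1`, `eaf_study2`,
#'   allele counts, `chi2`, `p_diff`, `low_expected` flag and `tier`
#'   (`"none"`, `"nominal"`, `"bonferroni"`; the Bonferroni threshold is
#'   `alpha` over the number of tested variants).
#' @export
freqDiffTest <- function(genos1, genos2, correct = FALSE, alpha = 0.05) {
    ids <- intersect(rownames(genos1), rownames(genos2))
    if (!length(ids)) stop("no shared variants between the two studies")
    rows <- lapply(ids, function(id) {
        g1 <- genos1[id, ]; g2 <- genos2[id, ]
        n1 <- 2L * sum(!is.na(g1)); n2 <- 2L * sum(!is.na(g2))
        if (n1 == 0L || n2 == 0L) {
            warning("variant ", id, " has no genotyped alleles; skipped")
            return(NULL)
        }
        e1 <- sum(g1, na.rm = TRUE); e2 <- sum(g2, na.rm = TRUE)
        tab <- rbind(c(e1, n1 - e1), c(e2, n2 - e2))
        degenerate <- any(colSums(tab) == 0)
        if (degenerate) {
            chi2 <- 0; p <- 1; lowExp <- TRUE
        } else {
            ct <- suppressWarnings(
                stats::chisq.test(tab, correct = correct))
            chi2 <- unname(ct$statistic); p <- ct$p.value
            lowExp <- any(ct$expected < 1)
        }
        data.frame(variant_id = id, eaf_study1 = e1 / n1, eaf_study2 = e2 / n2,
                   eff1 = e1, oth1 = n1 - e1, eff2 = e2, oth2 = n2 - e2,
                   chi2 = chi2, p_diff = p, low_expected = lowExp,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) stop("no testable variants")
    thr <- bonferroniThreshold(nrow(out), alpha)
    out$tier <- ifelse(out$p_diff < thr, "bonferroni",
                       ifelse(out$p_diff < alpha, "nominal", "none"))
    rownames(out) <- NULL
    out
}

#' Bonferroni-corrected significance threshold
#'
#' @param m number of tests (>= 1).
#' @param alpha family-wise level.
#' @return `alpha / m` (e.g. 0.05/534 = 9.36e-5, 0.05/186 = 2.69e-4).
#' @export
bonferroniThreshold <- function(m, alpha = 0.05) {
    if (length(m) != 1L || !is.finite(m) || m < 1) stop("m must be >= 1")
    alpha / m
}

#' Exact binomial enrichment / direction test
#'
#' Wraps the exact binomial test for the two survival-bias screens: (i)
#' one-sided enrichment of nominally significant frequency differences
#' beyond the null rate (`p0 = 0.05`, alternative `"greater"`, p =
#' `P(X >= k)`), and (ii) the two-sided direction test among the nominally
#' significant variants (`p0 = 0.5`), using the minimum-likelihood two-sided
#' definition (sum of all outcome probabilities not exceeding the observed
#' point probability, with a small relative tolerance).
#'
#' @param k observed successes.
#' @param n trials.
#' @param p0 null success probability in (0, 1).
#' @param alternative `"greater"` or `"two_sided"`.
#' @return data.frame `k`, `n`, `p0`, `alternative`, `p_bin`.
#' @examples
#' binomEnrichment(37, 534, 0.05, "greater")   # p_bin ~0.030
#' @export
binomEnrichment <- function(k, n, p0 = 0.05,
                            alternative = c("greater", "two_sided")) {
    alternative <- match.arg(alternative)
    if (!is.finite(p0) || p0 <= 0 || p0 >= 1)
        stop("p0 must lie strictly between 0 and 1")
    if (k < 0 || k > n) stop("k must lie in [0, n]")
    alt <- if (alternative == "greater") "greater" else "two.sided"
    p <- stats::binom.test(k, n, p = p0, alternative = alt)$p.value
    data.frame(k = k, n = n, p0 = p0, alternative = alternative, p_bin = p)
}

#' Expected-vs-observed p-value quantiles (QQ data)
#'
#' Sorted observed p-values against the uniform expectation `i/(m+1)`, on the
#' -log10 scale, for QQ inspection of the per-variant frequency-difference
#' p-values; also counts p < 0.05.
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return list with `points` (data.frame `expected`, `observed`,
#'   `neglog10_expected`, `neglog10_observed`) and `n_below_0.05`.
#' @export
qqPoints <- function(pvalues) {
    p <- as.numeric(pvalues)
    if (!length(p)) stop("need at least one p-value")
    if (any(!is.finite(p) | p <= 0 | p > 1))
        stop("p-values must lie in (0, 1]")
    m <- length(p)
    obs <- sort(p)
    expd <- seq_len(m) / (m + 1)
    list(points = data.frame(expected = expd, observed = obs,
                             neglog10_expected = -log10(expd),
                             neglog10_observed = -log10(obs)),
         n_below_0.05 = sum(p < 0.05))
}

#' Per-variant dosage association with study membership and age
#'
#' On data pooling both cohorts, tests each variant's dosage for association
#' with (a) study membership (logistic regression, Wald p), (b) age (linear
#' regression), and (c) age adjusting for study membership — the screen used
#' to judge whether frequency differences reflect the cohorts' age contrast
#' or study-level artefacts.
#'
#' @param d pooled [DosageMatrix-class] or variants-x-samples matrix.
#' @param labels factor/vector of study membership (2 levels), one per sample.
#' @param age numeric age per sample.
#' @return data.frame per variant with `p_membership`, `p_age`,
#'   `p_age_adjusted` (NA and `flagged` for zero-variance dosages).
#' @export
dosageAssociationScreen <- function(d, labels, age) {
    m <- if (methods::is(d, "DosageMatrix")) dosages(d) else as.matrix(d)
    lab <- factor(labels)
    if (nlevels(lab) != 2L) stop("labels must have exactly two levels")
    y <- as.numeric(lab) - 1
    rows <- lapply(seq_len(nrow(m)), function(j) {
        x <- m[j, ]
        ok <- stats::complete.cases(x, y, age)
        if (sum(ok) < 4L || stats::var(x[ok]) == 0)
            return(data.frame(variant_id = rownames(m)[j] %||% j,
                              beta_membership = NA_real_,
                              p_membership = NA_real_, p_age = NA_real_,
                              p_age_adjusted = NA_real_, flagged = TRUE))
        gf <- suppressWarnings(
            stats::glm(y[ok] ~ x[ok], family = stats::binomial()))
        gs <- summary(gf)$coefficients
        l1 <- summary(stats::lm(age[ok] ~ x[ok]))$coefficients
        l2 <- summary(stats::lm(age[ok] ~ x[ok] + y[ok]))$coefficients
        data.frame(variant_id = rownames(m)[j] %||% j,
                   beta_membership = gs[2, 1], p_membership = gs[2, 4],
                   p_age = l1[2, 4], p_age_adjusted = l2[2, 4],
                   flagged = FALSE, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
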