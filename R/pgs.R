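#' Compute weighted and unweighted polygenic scores
#'
#' The unweighted score of individual i is the plain count of eGFR-lowering
#' alleles, `sum_j d_ij`. The weighted score is the weighted allele count
#' divided by the mean weight,
#' `sum_j d_ij * w_j / mean(w)`,
#' so that one unit corresponds to one allele of average effect on eGFR.
#' Dividing by the mean (rather than the sum) of the weights is what places
#' the score on the alleles-of-average-effect scale: for a panel of M
#' variants the score then ranges over `[0, ~2M]` like an allele count.
#'
#' Missing dosages are handled by per-individual renormalization: the mean
#' weight in the denominator is taken over that individual's non-missing
#' variants, and `nVariantsUsed` records how many entered each score. An
#' individual with no non-missing dosage gets `NA` scores and a warning.
#'
#' @param score a [ScoringFile-class] (typically after [harmonizeVariants()]).
#' @param geno a [DosageMatrix-class] containing at least the scoring
#'   variants, oriented to the effect allele.
#' @return a [PgsVector-class].
#' @examples
#' sf <- ScoringFile(data.frame(variant_id = c("v1", "v2", "v3"),
#'     chr = "1", pos = 1:3, effect_allele = "A", other_allele = "G",
#'     effect_weight = c(0.001, 0.002, 0.003)))
#' dm <- DosageMatrix(matrix(c(2, 1, 0), nrow = 1,
#'     dimnames = list("s1", c("v1", "v2", "v3"))))
#' as.data.frame(computePgs(sf, dm))   # weighted 2, unweighted 3
#' @export
computePgs <- function(score, geno) {
    ids <- variantIds(score)
    miss <- setdiff(ids, variantIds(geno))
    if (length(miss))
        stop("genotype data lacks scoring variants (run harmonizeVariants): ",
             paste(utils::head(miss, 5), collapse = ", "))
    d <- dosages(geno)[ids, , drop = FALSE]     # variants x samples
    w <- effectWeights(score)
    ok <- !is.na(d)
    nUsed <- as.integer(colSums(ok))
    unweighted <- colSums(d, na.rm = TRUE)
    wsum <- colSums(d * w, na.rm = TRUE)
    wbar <- colSums(ok * w) / nUsed             # per-individual mean weight
    weighted <- wsum / wbar
    none <- nUsed == 0L
    if (any(none)) {
        warning(sum(none), " individual(s) had no non-missing dosage; ",
                "scores set to NA")
        weighted[none] <- NA_real_
        unweighted[none] <- NA_real_
    }
    new("PgsVector", sample_id = colnames(d), weighted = unname(weighted),
        unweighted = unname(unweighted), nVariantsUsed = nUsed,
        trait = traitLabel(score))
}

#' Summarize a PGS distribution
#'
#' @param pgs a [PgsVector-class].
#' @return data.frame with one row per score type (`weighted`, `unweighted`)
#'   and columns `n`, `mean`, `sd` (n-1 denominator), `min`, `max`.
#' @export
summarizePgs <- function(pgs) {
    one <- function(x, type) {
        x <- x[!is.na(x)]
        if (length(x) < 2L)
            stop("need at least 2 non-missing scores to summarize")
        data.frame(score = type, n = length(x), mean = mean(x),
                   sd = stats::sd(x), min = min(x), max = max(x),
                   stringsAsFactors = FALSE)
    }
    rbind(one(pgs@weighted, "weighted"), one(pgs@unweighted, "unweighted"))
}

#' Remove variants from a scoring file
#'
#' Used for sensitivity reruns (e.g. recomputing the score without an
#' APOE-region variant). Downstream [computePgs()] renormalizes by the mean
#' weight of the remaining variants.
#'
#' @param score a [ScoringFile-class].
#' @param ids variant identifiers to drop; unknown ids raise a warning.
#' @return the reduced [ScoringFile-class].
#' @export
excludeVariants <- function(score, ids) {
    have <- variantIds(score)
    unknown <- setdiff(ids, have)
    if (length(unknown))
        warning("ids not in scoring file: ", paste(unknown, collapse = ", "))
    keep <- setdiff(have, ids)
    if (!length(keep))
        stop("excluding these variants would empty the scoring file")
    score[keep]
}
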