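#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

#' ScoringFile: per-variant effect weights defining a polygenic score
#'
#' A `ScoringFile` holds the variant records that define a PGS: one row per
#' variant with its chromosome, 1-based position, effect allele (oriented to
#' the eGFR-lowering allele), other allele, positive effect weight in
#' mL/min/1.73m2 per allele, and optionally the effect-allele frequency and
#' imputation quality of the source panel.
#'
#' @slot trait character(1), one of `"eGFRcrea"` or `"eGFRcys"` (or a free
#'   label for custom panels).
#' @slot variants a [S4Vectors::DataFrame] with columns `variant_id`, `chr`,
#'   `pos`, `effect_allele`, `other_allele`, `effect_weight` and optionally
#'   `effect_allele_freq`, `imputation_r2`, `flipped`.
#' @export
setClass("ScoringFile",
    representation(trait = "character", variants = "DataFrame"))

.validScoringFile <- function(object) {
    v <- object@variants
    msg <- character()
    required <- c("variant_id", "chr", "pos", "effect_allele", "other_allele",
                  "effect_weight")
    miss <- setdiff(required, colnames(v))
    if (length(miss))
        msg <- c(msg, paste0("missing variant columns: ",
                             paste(miss, collapse = ", ")))
    if (!length(msg)) {
        if (nrow(v) < 1L)
            msg <- c(msg, "scoring file must contain at least one variant")
        dup <- unique(v$variant_id[duplicated(v$variant_id)])
        if (length(dup))
            msg <- c(msg, paste0("duplicated variant_id: ",
                                 paste(dup, collapse = ", ")))
        if (any(!is.finite(v$effect_weight) | v$effect_weight <= 0))
            msg <- c(msg, "all effect weights must be positive")
        if (any(v$effect_allele == v$other_allele))
            msg <- c(msg, "effect allele must differ from other allele")
        if (any(v$pos < 1L))
            msg <- c(msg, "positions must be >= 1")
        if (!is.null(v$imputation_r2)) {
            bad <- !is.na(v$imputation_r2) &
                (v$imputation_r2 < 0 | v$imputation_r2 > 1)
            if (any(bad))
                msg <- c(msg, "imputation_r2 must lie in [0, 1]")
        }
    }
    if (length(msg)) msg else TRUE
}
setValidity("ScoringFile", .validScoringFile)

#' Construct a ScoringFile
#'
#' @param variants a data.frame or DataFrame of variant records (see the class
#'   description for required columns). Rows with a negative `effect_weight`
#'   are re-oriented: alleles swapped, weight negated, frequency complemented,
#'   and the `flipped` column set.
#' @param trait trait label, e.g. `"eGFRcrea"`.
#' @return a [ScoringFile-class] object.
#' @export
ScoringFile <- function(variants, trait = "eGFRcrea") {
    v <- DataFrame(as.data.frame(variants))
    if (!is.null(v$effect_weight)) {
        neg <- !is.na(v$effect_weight) & v$effect_weight < 0
        if (is.null(v$flipped)) v$flipped <- FALSE
        if (any(neg)) {
            ea <- v$effect_allele[neg]
            v$effect_allele[neg] <- v$other_allele[neg]
            v$other_allele[neg] <- ea
            v$effect_weight[neg] <- -v$effect_weight[neg]
            if (!is.null(v$effect_allele_freq))
                v$effect_allele_freq[neg] <- 1 - v$effect_allele_freq[neg]
            v$flipped[neg] <- TRUE
        }
    }
    new("ScoringFile", trait = as.character(trait), variants = v)
}

#' DosageMatrix: effect-allele dosages for a cohort
#'
#' Thin wrapper around [SummarizedExperiment::SummarizedExperiment] with one
#' assay `"dosage"` holding variants (rows) by samples (columns) effect-allele
#' dosages in `[0, 2]` (NA = missing). `rowData` may carry `counted_allele`
#' and `other_allele` (e.g. from a VCF, where the counted allele is ALT) used
#' during harmonization.
#'
#' @export
setClass("DosageMatrix", contains = "SummarizedExperiment")

.validDosageMatrix <- function(object) {
    if (!"dosage" %in% SummarizedExperiment::assayNames(object))
        return("assay 'dosage' is required")
    d <- assay(object, "dosage")
    if (any(!is.na(d) & (d < -1e-6 | d > 2 + 1e-6)))
        return("dosages must lie in [0, 2]")
    TRUE
}
setValidity("DosageMatrix", .validDosageMatrix)

#' Construct a DosageMatrix
#'
#' @param dosages numeric matrix of dosages. By convention of the on-disk TSV
#'   format, samples are rows and variants are columns; the object stores the
#'   Bioconductor orientation (variants in rows).
#' @param samplesInRows logical; set to `FALSE` if `dosages` is already
#'   variants-by-samples.
#' @param counted_allele,other_allele optional per-variant allele annotations
#'   (the dosage counts copies of `counted_allele`).
#' @return a [DosageMatrix-class].
#' @export
DosageMatrix <- function(dosages, samplesInRows = TRUE,
                         counted_allele = NULL, other_allele = NULL) {
    m <- as.matrix(dosages)
    if (samplesInRows) m <- t(m)
    storage.mode(m) <- "double"
    bad <- which(!is.na(m) & (m < -1e-6 | m > 2 + 1e-6), arr.ind = TRUE)
    if (nrow(bad)) {
        stop(sprintf(
            "dosage out of [0, 2] at variant '%s', sample '%s' (value %g)",
            rownames(m)[bad[1, 1]] %||% bad[1, 1],
            colnames(m)[bad[1, 2]] %||% bad[1, 2],
            m[bad[1, , drop = FALSE]]))
    }
    m[!is.na(m) & m < 0] <- 0
    m[!is.na(m) & m > 2] <- 2
    rd <- DataFrame(row.names = rownames(m))
    if (!is.null(counted_allele)) rd$counted_allele <- counted_allele
    if (!is.null(other_allele)) rd$other_allele <- other_allele
    new("DosageMatrix",
        SummarizedExperiment(assays = list(dosage = m), rowData = rd))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' PgsVector: per-individual polygenic scores
#'
#' Holds the weighted score (units: alleles of average effect, i.e. the
#' weighted allele count divided by the mean weight) and the unweighted score
#' (plain count of eGFR-lowering alleles), with the number of non-missing
#' variants used per individual.
#'
#' @slot sample_id character vector of sample identifiers.
#' @slot weighted,unweighted numeric scores (NA when every dosage was missing).
#' @slot nVariantsUsed integer count of variants entering each score.
#' @slot trait trait label inherited from the scoring file.
#' @export
setClass("PgsVector",
    representation(sample_id = "character", weighted = "numeric",
                   unweighted = "numeric", nVariantsUsed = "integer",
                   trait = "character"))

setValidity("PgsVector", function(object) {
    n <- length(object@sample_id)
    if (length(object@weighted) != n || length(object@unweighted) != n ||
        length(object@nVariantsUsed) != n)
        return("all slots must have equal length")
    ok <- !is.na(object@unweighted)
    if (any(object@unweighted[ok] < 0 |
            object@unweighted[ok] > 2 * object@nVariantsUsed[ok] + 1e-9))
        return("unweighted score must lie in [0, 2 * variants used]")
    if (any(!is.na(object@weighted) & object@weighted < -1e-9))
        return("weighted score must be non-negative")
    TRUE
})

setMethod("show", "ScoringFile", function(object) {
    cat(sprintf("ScoringFile for %s with %d variants\n",
                object@trait, nrow(object@variants)))
    cat(sprintf("  weight range: [%g, %g], mean %g\n",
                min(object@variants$effect_weight),
                max(object@variants$effect_weight),
                mean(object@variants$effect_weight)))
    if (!is.null(object@variants$imputation_r2))
        cat(sprintf("  imputation r2 available (%d non-missing)\n",
                    sum(!is.na(object@variants$imputation_r2))))
})

setMethod("show", "PgsVector", function(object) {
    cat(sprintf("PgsVector (%s) for %d individuals\n",
                object@trait, length(object@sample_id)))
    cat(sprintf("  weighted:   mean %.1f, sd %.2f\n",
                mean(object@weighted, na.rm = TRUE),
                stats::sd(object@weighted, na.rm = TRUE)))
    cat(sprintf("  unweighted: mean %.1f, sd %.2f\n",
                mean(object@unweighted, na.rm = TRUE),
                stats::sd(object@unweighted, na.rm = TRUE)))
})
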