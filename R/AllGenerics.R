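#' Accessors for kidneyPGS classes
#'
#' `variantIds()` returns the variant identifiers, `effectWeights()` the
#' positive per-allele weights, `traitLabel()` the trait a score targets,
#' `nVariants()` the panel size, and `dosages()` the dosage matrix in the
#' requested orientation.
#'
#' @param x a [ScoringFile-class], [DosageMatrix-class] or [PgsVector-class].
#' @param ... further arguments for methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("variantIds", function(x, ...) standardGeneric("variantIds"))

#' @rdname accessors
#' @export
setGeneric("effectWeights", function(x, ...) standardGeneric("effectWeights"))

#' @rdname accessors
#' @export
setGeneric("traitLabel", function(x, ...) standardGeneric("traitLabel"))

#' @rdname accessors
#' @export
setGeneric("nVariants", function(x, ...) standardGeneric("nVariants"))

#' @rdname accessors
#' @param samplesInRows logical; return samples-by-variants (the TSV dialect)
#'   instead of the internal variants-by-samples orientation.
#' @export
setGeneric("dosages", function(x, ...) standardGeneric("dosages"))

#' @rdname accessors
#' @export
setMethod("variantIds", "ScoringFile", function(x) x@variants$variant_id)

#' @rdname accessors
#' @export
setMethod("variantIds", "DosageMatrix", function(x) rownames(x))

#' @rdname accessors
#' @export
setMethod("effectWeights", "ScoringFile", function(x) {
    stats::setNames(x@variants$effect_weight, x@variants$variant_id)
})

#' @rdname accessors
#' @export
setMethod("traitLabel", "ScoringFile", function(x) x@trait)

#' @rdname accessors
#' @export
setMethod("traitLabel", "PgsVector", function(x) x@trait)

#' @rdname accessors
#' @export
setMethod("nVariants", "ScoringFile", function(x) nrow(x@variants))

#' @rdname accessors
#' @export
setMethod("nVariants", "DosageMatrix", function(x) nrow(x))

#' @rdname accessors
#' @export
setMethod("dosages", "DosageMatrix", function(x, samplesInRows = FALSE) {
    d <- assay(x, "dosage")
    if (samplesInRows) t(d) else d
})

#' Variant records of a scoring file as a data.frame
#' @param x a ScoringFile.
#' @param ... ignored.
#' @export
setMethod("as.data.frame", "ScoringFile", function(x, ...) {
    as.data.frame(x@variants)
})

#' Per-individual scores as a data.frame
#' @param x a PgsVector.
#' @param ... ignored.
#' @export
setMethod("as.data.frame", "PgsVector", function(x, ...) {
    data.frame(sample_id = x@sample_id, weighted = x@weighted,
               unweighted = x@unweighted, n_variants_used = x@nVariantsUsed,
               stringsAsFactors = FALSE)
})

#' @rdname accessors
#' @export
setMethod("length", "PgsVector", function(x) length(x@sample_id))

#' Subset a scoring file by variant
#' @param x a ScoringFile.
#' @param i index or variant_id character vector.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "ScoringFile", function(x, i, j, ..., drop = FALSE) {
    v <- x@variants
    if (is.character(i)) i <- match(i, v$variant_id)
    ScoringFile(as.data.frame(v[i, , drop = FALSE]), trait = x@trait)
})
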