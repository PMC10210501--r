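#' Read a PGS scoring file
#'
#' Parses a tab-separated scoring file (PGS-Catalog-like dialect) into a
#' [ScoringFile-class]. Lines starting with `#` are comments. Mandatory
#' columns: `variant_id`, `chr`, `pos`, `effect_allele`, `other_allele`,
#' `effect_weight`; optional: `effect_allele_freq`, `imputation_r2`.
#'
#' Weights are stored as positive magnitudes oriented to the eGFR-lowering
#' allele: a row with a negative `effect_weight` has its allele pair swapped,
#' its frequency complemented, and the `flipped` flag set.
#'
#' @param path path to the scoring TSV.
#' @param trait trait label to attach (`"eGFRcrea"` or `"eGFRcys"`).
#' @return a [ScoringFile-class]; row order of the file is preserved.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("variant_id\tchr\tpos\teffect_allele\tother_allele\teffect_weight",
#'              "rs1\t1\t100\tA\tG\t0.002"), tf)
#' readScoringFile(tf)
#' @export
readScoringFile <- function(path, trait = "eGFRcrea") {
    if (!file.exists(path)) stop("scoring file not found: ", path)
    df <- utils::read.delim(path, comment.char = "#",
                            stringsAsFactors = FALSE, check.names = FALSE)
    required <- c("variant_id", "chr", "pos", "effect_allele", "other_allele",
                  "effect_weight")
    miss <- setdiff(required, colnames(df))
    if (length(miss))
        stop("scoring file is missing mandatory column(s): ",
             paste(miss, collapse = ", "))
    dup <- unique(df$variant_id[duplicated(df$variant_id)])
    if (length(dup))
        stop("duplicated variant_id in scoring file: ",
             paste(dup, collapse = ", "))
    if (any(!is.finite(df$effect_weight) | df$effect_weight == 0))
        stop("effect_weight must be non-zero and finite for every variant")
    df$chr <- as.character(df$chr)
    ScoringFile(df, trait = trait)
}

#' Write a scoring file to TSV
#'
#' Inverse of [readScoringFile()]; numeric columns are written with full
#' precision so that a read/write round trip is exact.
#'
#' @param score a [ScoringFile-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeScoringFile <- function(score, path) {
    df <- as.data.frame(score)
    .writeTsvFull(df, path)
    invisible(path)
}

# full-precision TSV writer (%.17g keeps doubles exact on round trip)
.writeTsvFull <- function(df, path) {
    fmt <- vapply(df, function(col) {
        if (is.double(col)) "g" else "s"
    }, character(1))
    out <- df
    for (j in seq_along(out)) {
        if (fmt[j] == "g") {
            x <- sprintf("%.17g", out[[j]])
            x[is.na(out[[j]])] <- "NA"
            out[[j]] <- x
        }
    }
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
}

#' Read an effect-allele dosage matrix
#'
#' Two dialects are supported. `format = "tsv"`: samples in rows, first
#' column `sample_id`, one column per variant, missing values as `NA`.
#' `format = "vcf"`: a VCF with a per-genotype `DS` FORMAT field; the counted
#' allele is ALT and REF/ALT are stored in `rowData` so that harmonization can
#' re-orient dosages to the scoring file's effect allele.
#'
#' @param path input file.
#' @param format `"tsv"` or `"vcf"`.
#' @return a [DosageMatrix-class].
#' @export
readDosageMatrix <- function(path, format = c("tsv", "vcf")) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("dosage file not found: ", path)
    if (format == "tsv") {
        df <- utils::read.delim(path, stringsAsFactors = FALSE,
                                check.names = FALSE)
        if (!"sample_id" %in% colnames(df))
            stop("dosage TSV must have a 'sample_id' first column")
        ids <- as.character(df$sample_id)
        m <- as.matrix(df[, setdiff(colnames(df), "sample_id"), drop = FALSE])
        storage.mode(m) <- "double"
        rownames(m) <- ids
        bad <- which(!is.na(m) & (m < -1e-6 | m > 2 + 1e-6), arr.ind = TRUE)
        if (nrow(bad))
            stop(sprintf("dosage out of [0, 2] at row %d ('%s'), column '%s'",
                         bad[1, 1], ids[bad[1, 1]], colnames(m)[bad[1, 2]]))
        DosageMatrix(m, samplesInRows = TRUE)
    } else {
        if (!requireNamespace("vcfR", quietly = TRUE))
            stop("reading VCF dosages requires the 'vcfR' package")
        vcf <- vcfR::read.vcfR(path, verbose = FALSE)
        fmt <- vcf@gt[, 1L]
        if (!any(grepl("(^|:)DS(:|$)", fmt)))
            stop("VCF has no per-genotype DS field")
        ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
        ids <- vcfR::getID(vcf)
        rownames(ds) <- ids
        DosageMatrix(ds, samplesInRows = FALSE,
                     counted_allele = vcfR::getALT(vcf),
                     other_allele = vcfR::getREF(vcf))
    }
}

#' Write a dosage matrix in the TSV dialect
#'
#' @param geno a [DosageMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeDosageMatrix <- function(geno, path) {
    m <- dosages(geno, samplesInRows = TRUE)
    df <- data.frame(sample_id = rownames(m), as.data.frame(m),
                     check.names = FALSE, stringsAsFactors = FALSE)
    .writeTsvFull(df, path)
    invisible(path)
}
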