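#' Harmonize a scoring file with a dosage matrix
#'
#' Intersects the scoring panel with the genotyped variants, re-orients
#' dosages stored on the opposite allele (`d <- 2 - d` when the counted/other
#' pair is swapped relative to the scoring file), optionally drops variants
#' below an imputation-quality threshold, and reports every action taken.
#'
#' Strand-ambiguous variants (A/T or C/G allele pairs) are matched by ID and
#' allele pair only — no frequency-based strand inference is attempted, which
#' is appropriate when both cohorts share one imputation panel — and are
#' flagged `ambiguous` in the report.
#'
#' @param score a [ScoringFile-class].
#' @param geno a [DosageMatrix-class]. If `rowData` carries `counted_allele` /
#'   `other_allele` annotations they are checked against the scoring file;
#'   otherwise dosages are assumed to already count the effect allele.
#' @param r2Threshold numeric or `NULL`; variants with scoring-file
#'   `imputation_r2` below this are dropped (the conventional filter is 0.8).
#' @return a list with elements `score` (subset [ScoringFile-class]), `geno`
#'   (re-oriented, subset [DosageMatrix-class], rows in scoring-file order)
#'   and `report` (data.frame `variant_id`, `action`, `reason`).
#' @export
harmonizeVariants <- function(score, geno, r2Threshold = NULL) {
    v <- as.data.frame(score)
    d <- dosages(geno)
    rd <- as.data.frame(rowData(geno))
    actions <- data.frame(variant_id = character(), action = character(),
                          reason = character(), stringsAsFactors = FALSE)
    note <- function(id, action, reason) {
        rbind(actions, data.frame(variant_id = id, action = action,
                                  reason = reason, stringsAsFactors = FALSE))
    }

    present <- v$variant_id %in% rownames(d)
    for (id in v$variant_id[!present])
        actions <- note(id, "dropped", "absent from genotype data")
    keep <- v[present, , drop = FALSE]
    if (nrow(keep)) {
        d <- d[keep$variant_id, , drop = FALSE]
        hasAlleles <- all(c("counted_allele", "other_allele") %in% colnames(rd))
        if (hasAlleles) {
            rd <- rd[keep$variant_id, , drop = FALSE]
            same <- rd$counted_allele == keep$effect_allele &
                rd$other_allele == keep$other_allele
            swap <- rd$counted_allele == keep$other_allele &
                rd$other_allele == keep$effect_allele
            mismatch <- !(same | swap)
            if (any(swap)) {
                d[swap, ] <- 2 - d[swap, , drop = FALSE]
                for (id in keep$variant_id[swap])
                    actions <- note(id, "flipped",
                                    "dosage counted the other allele")
            }
            if (any(mismatch)) {
                for (id in keep$variant_id[mismatch])
                    actions <- note(id, "dropped", "allele mismatch")
                keep <- keep[!mismatch, , drop = FALSE]
                d <- d[!mismatch, , drop = FALSE]
            }
        }
        ambiguous <- .isStrandAmbiguous(keep$effect_allele, keep$other_allele)
        for (id in keep$variant_id[ambiguous])
            actions <- note(id, "kept", "ambiguous")
        if (!is.null(r2Threshold) && !is.null(keep$imputation_r2)) {
            low <- !is.na(keep$imputation_r2) &
                keep$imputation_r2 < r2Threshold
            for (id in keep$variant_id[low])
                actions <- note(id, "dropped", "low imputation quality")
            keep <- keep[!low, , drop = FALSE]
            d <- d[keep$variant_id, , drop = FALSE]
        }
    }
    if (nrow(keep) == 0L)
        stop("no variants survive harmonization")
    list(score = ScoringFile(keep, trait = traitLabel(score)),
         geno = DosageMatrix(d, samplesInRows = FALSE),
         report = actions)
}

.isStrandAmbiguous <- function(a1, a2) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    nchar(a1) == 1L & nchar(a2) == 1L &
        !is.na(comp[a1]) & comp[a1] == a2
}

#' Write a harmonization report
#' @param report data.frame from [harmonizeVariants()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeHarmonizationReport <- function(report, path) {
    utils::write.table(report, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
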