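test_that("scoring files parse with order preserved and comments skipped", {
    df <- makeScoringDf(3)
    path <- tempfile(fileext = ".tsv")
    writeLines(c("# comment line",
                 paste(colnames(df), collapse = "\t"),
                 apply(df, 1, paste, collapse = "\t")), path)
    sf <- readScoringFile(path)
    expect_s4_class(sf, "ScoringFile")
    expect_equal(nVariants(sf), 3L)
    expect_equal(variantIds(sf), paste0("rs", 1:3))
    expect_equal(unname(effectWeights(sf)), c(0.001, 0.002, 0.003))
})

test_that("negative source weights are re-oriented to the eGFR-lowering allele", {
    df <- makeScoringDf(2, weights = c(0.001, -0.0019), freqs = c(0.4, 0.735))
    sf <- readScoringFile(writeScoringTsv(df))
    v <- as.data.frame(sf)
    expect_equal(v$effect_weight[2], 0.0019)
    expect_equal(v$effect_allele[2], "G")   # allele pair swapped
    expect_equal(v$other_allele[2], "A")
    expect_equal(v$effect_allele_freq[2], 1 - 0.735)
    expect_true(v$flipped[2])
    expect_false(v$flipped[1])
})

test_that("scoring file validation rejects malformed input", {
    df <- makeScoringDf(3)
    df$variant_id[2] <- "rs1"
    expect_error(readScoringFile(writeScoringTsv(df)), "rs1")
    df <- makeScoringDf(3)[, -6]
    expect_error(readScoringFile(writeScoringTsv(df)), "effect_weight")
    df <- makeScoringDf(3); df$effect_weight[1] <- 0
    expect_error(readScoringFile(writeScoringTsv(df)), "non-zero")
    expect_error(readScoringFile(tempfile()), "not found")
})

test_that("dosage TSV round-trips and rejects out-of-range cells", {
    m <- matrix(c(0, 1, 2, 1.5, 0.25, 2), nrow = 2,
                dimnames = list(c("s1", "s2"), c("rs1", "rs2", "rs3")))
    path <- tempfile(fileext = ".tsv")
    writeDosageMatrix(makeDosage(m), path)
    dm <- readDosageMatrix(path, "tsv")
    expect_equal(dosages(dm, samplesInRows = TRUE), m)
    writeLines(c("sample_id\trs1", "s1\t2.5"), path)
    expect_error(readDosageMatrix(path, "tsv"), "rs1")
})

test_that("VCF dosages are read from the DS field with allele annotations", {
    path <- tempfile(fileext = ".vcf")
    writeLines(c(
        "##fileformat=VCFv4.2",
        '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
        '##FORMAT=<ID=DS,Number=1,Type=Float,Description="Dosage">',
        "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
        "1\t100\trs1\tG\tA\t.\tPASS\t.\tGT:DS\t0/1:1.7\t0/0:0.1",
        "1\t200\trs2\tT\tC\t.\tPASS\t.\tGT:DS\t0/0:0.0\t1/1:2.0"), path)
    dm <- readDosageMatrix(path, "vcf")
    expect_equal(unname(dosages(dm)["rs1", ]), c(1.7, 0.1))
    rd <- as.data.frame(SummarizedExperiment::rowData(dm))
    expect_equal(rd$counted_allele, c("A", "C"))   # ALT is counted
    # VCF without DS errors
    writeLines(c(
        "##fileformat=VCFv4.2",
        '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
        "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
        "1\t100\trs1\tG\tA\t.\tPASS\t.\tGT\t0/1"), path)
    expect_error(readDosageMatrix(path, "vcf"), "DS")
})

test_that("harmonization intersects, flips swapped alleles and filters on r2", {
    df <- makeScoringDf(5, r2 = c(0.95, 0.79, 0.9, 0.99, 0.85))
    sf <- ScoringFile(df)
    # genotypes lack rs5; rs3 stored on the opposite allele
    m <- rbind(s1 = c(0, 1, 2, 0.4), s2 = c(2, 0, 1, 1.2))
    colnames(m) <- paste0("rs", 1:4)
    dm <- DosageMatrix(m, samplesInRows = TRUE,
                       counted_allele = c("A", "A", "G", "A"),
                       other_allele = c("G", "G", "A", "G"))
    h <- harmonizeVariants(sf, dm)
    expect_setequal(variantIds(h$score), paste0("rs", 1:4))
    expect_equal(unname(dosages(h$geno)["rs3", ]), 2 - c(2, 1))
    rep <- h$report
    expect_true(any(rep$variant_id == "rs5" &
                    rep$reason == "absent from genotype data"))
    expect_true(any(rep$variant_id == "rs3" & rep$action == "flipped"))
    # imputation-quality filter drops rs2 (0.79 < 0.8)
    h2 <- harmonizeVariants(sf, dm, r2Threshold = 0.8)
    expect_false("rs2" %in% variantIds(h2$score))
    expect_true(any(h2$report$variant_id == "rs2" &
                    h2$report$reason == "low imputation quality"))
    # zero survivors is an error
    empty <- makeDosage(matrix(1), variantIds = "zzz")
    expect_error(harmonizeVariants(sf, empty), "no variants survive")
})

test_that("strand-ambiguous pairs are kept but flagged", {
    df <- makeScoringDf(2)
    df$effect_allele <- c("A", "C")
    df$other_allele <- c("T", "G")
    sf <- ScoringFile(df)
    dm <- makeDosage(matrix(c(1, 1), 1), variantIds = c("rs1", "rs2"))
    h <- harmonizeVariants(sf, dm)
    expect_equal(sum(h$report$reason == "ambiguous"), 2L)
    expect_equal(nVariants(h$score), 2L)
})

test_that("weighted PGS is the weighted allele count per mean weight", {
    # hand-computed: d = (2,1,0), w = (1,2,3)/1000 -> sum(dw) = 0.004,
    # mean weight 0.002 -> weighted = 2; unweighted = 3
    sf <- ScoringFile(makeScoringDf(3))
    dm <- makeDosage(matrix(c(2, 1, 0), nrow = 1))
    pgs <- computePgs(sf, dm)
    expect_equal(pgs@weighted, 2)
    expect_equal(pgs@unweighted, 3)
    expect_equal(pgs@nVariantsUsed, 3L)
    # single variant: unit normalization makes weighted = dosage
    sf1 <- ScoringFile(makeScoringDf(1, weights = 0.01))
    dm1 <- makeDosage(matrix(c(0, 1, 2), ncol = 1))
    expect_equal(computePgs(sf1, dm1)@weighted, c(0, 1, 2))
})

test_that("PGS is invariant to weight rescaling and equals the count under equal weights", {
    set.seed(41)
    m <- 12; n <- 9
    w <- runif(m, 1e-4, 5e-3)
    d <- matrix(sample(0:2, n * m, replace = TRUE), n, m,
                dimnames = list(paste0("s", 1:n), paste0("rs", 1:m)))
    dm <- DosageMatrix(d)
    sf <- ScoringFile(makeScoringDf(m, weights = w))
    sfScaled <- ScoringFile(makeScoringDf(m, weights = w * 37.5))
    expect_equal(computePgs(sf, dm)@weighted,
                 computePgs(sfScaled, dm)@weighted, tolerance = 1e-12)
    sfEq <- ScoringFile(makeScoringDf(m, weights = 0.002))
    pgsEq <- computePgs(sfEq, dm)
    expect_equal(pgsEq@weighted, pgsEq@unweighted, tolerance = 1e-12)
    # bounds
    pgs <- computePgs(sf, dm)
    expect_true(all(pgs@unweighted >= 0 & pgs@unweighted <= 2 * m))
    expect_true(all(pgs@weighted >= 0))
})

test_that("flip harmonization and direct orientation give identical scores", {
    set.seed(13)
    df <- makeScoringDf(4, weights = runif(4, 1e-3, 4e-3))
    sf <- ScoringFile(df)
    d <- matrix(runif(4 * 6, 0, 2), 6, 4,
                dimnames = list(paste0("s", 1:6), df$variant_id))
    direct <- DosageMatrix(d, samplesInRows = TRUE,
                           counted_allele = df$effect_allele,
                           other_allele = df$other_allele)
    flipped <- DosageMatrix(2 - d, samplesInRows = TRUE,
                            counted_allele = df$other_allele,
                            other_allele = df$effect_allele)
    p1 <- computePgs(harmonizeVariants(sf, direct)$score,
                     harmonizeVariants(sf, direct)$geno)
    p2 <- computePgs(harmonizeVariants(sf, flipped)$score,
                     harmonizeVariants(sf, flipped)$geno)
    expect_equal(p1@weighted, p2@weighted, tolerance = 1e-12)
})

test_that("missing dosages renormalize per individual and all-missing flags NA", {
    sf <- ScoringFile(makeScoringDf(3))
    d <- matrix(c(2, 1, NA,    # s1: uses w = (1,2)/1000, mean 0.0015
                  NA, NA, NA), nrow = 2, byrow = TRUE,
                dimnames = list(c("s1", "s2"), paste0("rs", 1:3)))
    expect_warning(pgs <- computePgs(sf, DosageMatrix(d)), "no non-missing")
    expect_equal(pgs@weighted[1], (2 * 0.001 + 1 * 0.002) / 0.0015)
    expect_equal(pgs@nVariantsUsed, c(2L, 0L))
    expect_true(is.na(pgs@weighted[2]) && is.na(pgs@unweighted[2]))
})

test_that("summarizePgs reports n-1 moments and rejects tiny samples", {
    sf <- ScoringFile(makeScoringDf(1, weights = 0.01))
    dm <- makeDosage(matrix(c(1, 2, 0, 1), ncol = 1) * 0 + c(1, 2, 3, 1) / 2)
    pgs <- computePgs(sf, dm)
    pgs@weighted <- c(1, 2, 3, 2)
    pgs@unweighted <- c(1, 1, 1, 1)
    s <- summarizePgs(pgs)
    expect_equal(s$mean[s$score == "weighted"], 2)
    expect_equal(s$sd[s$score == "weighted"], sd(c(1, 2, 3, 2)))
    expect_equal(s$sd[s$score == "unweighted"], 0)
    pgs1 <- computePgs(sf, makeDosage(matrix(1)))
    expect_error(summarizePgs(pgs1), "at least 2")
})

test_that("excluding variants renormalizes the score and validates ids", {
    df <- makeScoringDf(4, weights = c(1, 2, 3, 4) / 1000)
    sf <- ScoringFile(df)
    sf3 <- excludeVariants(sf, "rs4")
    expect_equal(nVariants(sf3), 3L)
    d <- makeDosage(matrix(c(1, 1, 1, 1), 1))
    d3 <- makeDosage(matrix(c(1, 1, 1), 1))
    # renormalization: mean weight changes from 2.5 to 2 (per mille)
    expect_equal(computePgs(sf3, d3)@weighted, (1 + 2 + 3) / 2)
    expect_warning(out <- excludeVariants(sf, c("rs1", "nope")), "nope")
    expect_equal(nVariants(out), 3L)
    expect_error(excludeVariants(sf, paste0("rs", 1:4)), "empty")
    expect_equal(variantIds(excludeVariants(sf, character(0))),
                 variantIds(sf))
})

test_that("simulated cohorts match Hardy-Weinberg PGS moments", {
    p <- syntheticPreset("custom", n = 4000L, m_variants = 40L)
    panel <- simulatePanel(p, seed = 21)
    geno <- simulateGenotypes(panel, p$n, seed = 22)
    pgs <- computePgs(panel, geno)
    v <- as.data.frame(panel)
    w <- v$effect_weight / mean(v$effect_weight)
    f <- v$effect_allele_freq
    expectedMean <- sum(2 * f * w)
    # Monte-Carlo SE of the mean weighted score
    se <- sd(pgs@weighted) / sqrt(p$n)
    expect_lt(abs(mean(pgs@weighted) - expectedMean), 3 * se)
    # unweighted variance ~ sum of per-variant heterozygosity
    expectedVar <- sum(2 * f * (1 - f))
    expect_lt(abs(var(pgs@unweighted) - expectedVar) / expectedVar, 0.15)
})
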