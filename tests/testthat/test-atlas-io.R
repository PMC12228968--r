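test_that("expression TSVs round-trip through read and write", {
    atlas <- makeAtlas(matrix(c(5, 0, 1, 2, 8, 3), nrow = 3,
                              dimnames = list(paste0("g", 1:3),
                                              c("s1", "s2"))),
                       tissue = c("liver", "muscle"),
                       stage = c("prenatal", "adult"))
    d <- withr::local_tempdir()
    ep <- file.path(d, "expr.tsv"); mp <- file.path(d, "meta.tsv")
    writeExpressionAtlas(atlas, ep, mp)
    back <- readExpressionAtlas(ep, mp)
    expect_equal(dim(back), c(3L, 2L))
    expect_equal(tpm(back), tpm(atlas))
    expect_identical(sampleTissue(back), sampleTissue(atlas))
    # second round trip is byte-identical: formatting is stable
    ep2 <- file.path(d, "expr2.tsv"); mp2 <- file.path(d, "meta2.tsv")
    writeExpressionAtlas(back, ep2, mp2)
    expect_identical(readLines(ep), readLines(ep2))
})

test_that("metadata must cover every sample, naming the missing ones", {
    d <- withr::local_tempdir()
    ep <- file.path(d, "expr.tsv"); mp <- file.path(d, "meta.tsv")
    writeLines(c("gene_id\tsA\tsB", "g1\t1\t2"), ep)
    writeLines(c("sample_id\ttissue\tstage", "sA\tliver\tadult"), mp)
    expect_error(readExpressionAtlas(ep, mp), "sB")
})

test_that("atlas validity rejects negative TPM and duplicate ids", {
    expect_error(makeAtlas(matrix(c(-1, 2), 1)), "non-negative")
    d <- withr::local_tempdir()
    ep <- file.path(d, "expr.tsv"); mp <- file.path(d, "meta.tsv")
    writeLines(c("gene_id\tsA", "g1\t1", "g1\t2"), ep)
    writeLines(c("sample_id\ttissue\tstage", "sA\tliver\tadult"), mp)
    expect_error(readExpressionAtlas(ep, mp), "duplicate gene ids")
})

test_that("gene filter keeps genes reaching TPM 0.1 in any sample (inclusive)", {
    mat <- rbind(allzero = c(0, 0), boundary = c(0.1, 0),
                 below = c(0.05, 0.09), high = c(2, 3))
    atlas <- makeAtlas(mat)
    kept <- rownames(filterUnexpressedGenes(atlas))
    expect_setequal(kept, c("boundary", "high"))
    # fixture of 10 genes, 3 with max TPM 0.05 -> 7 retained
    mat10 <- matrix(1, 10, 2,
                    dimnames = list(paste0("g", 1:10), c("s1", "s2")))
    mat10[1:3, ] <- 0.05
    expect_equal(nrow(filterUnexpressedGenes(makeAtlas(mat10))), 7L)
})

test_that("breadth filter removes samples strictly below 40% expressed", {
    mat <- matrix(0, 10, 3, dimnames = list(paste0("g", 1:10),
                                            c("low", "edge", "high")))
    mat[1:3, "low"] <- 1    # 30% -> removed
    mat[1:4, "edge"] <- 1   # 40% -> retained (strictly-below rule)
    mat[1:9, "high"] <- 1
    atlas <- makeAtlas(mat)
    kept <- colnames(filterLowBreadthSamples(atlas))
    expect_setequal(kept, c("edge", "high"))
    # all above threshold: identity
    expect_identical(colnames(filterLowBreadthSamples(atlas[, kept])), kept)
})

test_that("tissues with fewer than 3 samples are dropped whole", {
    mat <- matrix(1, 2, 8)
    atlas <- makeAtlas(mat, tissue = rep(c("big", "mid", "tiny"),
                                         c(5, 2, 1)))
    out <- filterSmallTissues(atlas)
    expect_equal(ncol(out), 5L)
    expect_setequal(unique(sampleTissue(out)), "big")
    # boundary: exactly 3 samples retained
    atlas3 <- makeAtlas(matrix(1, 2, 3), tissue = rep("t3", 3))
    expect_equal(ncol(filterSmallTissues(atlas3)), 3L)
})

test_that("QC filters are idempotent and the chain applies genes, samples, tissues in order", {
    sim <- simulateAtlas(atlasSimConfig(nTissues = 3, nStages = 2,
                                        nGenes = 80, nSpecificPerTissue = 3,
                                        nSpecificPerStage = 3,
                                        nTrajectoryGenes = 6, seed = 21))
    a <- sim$atlas
    f1 <- filterUnexpressedGenes(a)
    expect_identical(tpm(filterUnexpressedGenes(f1)), tpm(f1))
    f2 <- filterLowBreadthSamples(a)
    expect_identical(tpm(filterLowBreadthSamples(f2)), tpm(f2))
    f3 <- filterSmallTissues(a)
    expect_identical(tpm(filterSmallTissues(f3)), tpm(f3))
    chained <- filterSmallTissues(filterLowBreadthSamples(
        filterUnexpressedGenes(a)))
    qc <- qcAtlas(a, quiet = TRUE)
    expect_identical(tpm(qc$atlas), tpm(chained))
})

test_that("log transform matches its closed forms and rejects negatives", {
    expect_equal(logTransform(matrix(0)), matrix(-2))
    expect_equal(logTransform(matrix(0.75)), matrix(0))
    expect_equal(logTransform(matrix(3.75)), matrix(2))
    expect_error(logTransform(matrix(-0.1)), "negative")
})

test_that("top-variance selection sorts by SD of TPM with lexicographic ties", {
    # SDs {3,1,2,0} planted via two-sample spreads around a shared mean
    mat <- rbind(a_sd3 = c(10 - 3 / sqrt(2), 10 + 3 / sqrt(2)),
                 b_sd1 = c(10 - 1 / sqrt(2), 10 + 1 / sqrt(2)),
                 c_sd2 = c(10 - 2 / sqrt(2), 10 + 2 / sqrt(2)),
                 d_sd0 = c(10, 10))
    atlas <- makeAtlas(mat)
    expect_identical(topVarianceGenes(atlas, 2), c("a_sd3", "c_sd2"))
    ranked <- topVarianceGenes(atlas, 4)
    expect_identical(ranked[4], "d_sd0")   # constant gene ranks last
    expect_identical(sort(ranked), sort(rownames(mat)))  # k = n: all genes
    expect_error(topVarianceGenes(atlas, 5), "exceeds")
})

test_that("sample distance is 1 - Pearson r with the expected extremes", {
    x <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
    d <- sampleDistance(x)
    # oracle: direct pairwise evaluation of the Pearson formula
    pearson <- function(u, v) {
        sum((u - mean(u)) * (v - mean(v))) /
            sqrt(sum((u - mean(u))^2) * sum((v - mean(v))^2))
    }
    for (i in 1:3) for (j in 1:3)
        expect_equal(d[i, j], if (i == j) 0 else 1 - pearson(x[, i], x[, j]))
    dup <- cbind(a = x[, 1], b = x[, 1], c = -x[, 1])
    ddup <- sampleDistance(dup)
    expect_equal(ddup["a", "b"], 0)
    expect_equal(ddup["a", "c"], 2)
    bad <- cbind(x, flat = rep(1, 10))
    expect_error(sampleDistance(bad), "flat")
})

test_that("annotation and GWAS tables survive their file formats", {
    ann <- makeAnnotation(c("chr1", "chr1"), c(100, 5000), c(900, 5800),
                          c("gA", "gB"))
    d <- withr::local_tempdir()
    gp <- file.path(d, "genes.gff3")
    writeGeneAnnotation(ann, gp)
    back <- readGeneAnnotation(gp)
    expect_identical(names(back), c("gA", "gB"))
    expect_equal(GenomicRanges::start(back), c(100, 5000))
    expect_equal(GenomicRanges::end(back), c(900, 5800))
    # BED input is 0-based half-open; conversion lands on the same gene body
    bp <- file.path(d, "genes.bed")
    writeLines(c("chr1\t99\t900\tgA\t0\t+", "chr1\t4999\t5800\tgB\t0\t-"), bp)
    bed <- readGeneAnnotation(bp)
    expect_equal(GenomicRanges::start(bed), c(100, 5000))
    expect_equal(GenomicRanges::end(bed), c(900, 5800))

    gwas <- makeGwas("chr1", c(50, 600), beta = c(0.2, -0.1))
    gwp <- file.path(d, "gwas.tsv")
    writeGwasSummary(gwas, gwp)
    expect_equal(readGwasSummary(gwp), gwas)
    writeLines(c("snp_id\tchrom\tpos", "s1\tchr1\t10"), gwp)
    expect_error(readGwasSummary(gwp), "beta")
})
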