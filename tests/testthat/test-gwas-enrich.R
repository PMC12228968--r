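test_that("cis-window mapping is inclusive at exactly 20 kb from the gene body", {
    ann <- makeAnnotation("chr1", 30000, 31000, "gA")
    gwas <- makeGwas("chr1", c(51000, 51001, 30500, 9999, 10000))
    map <- mapSnpsToGenes(ann, gwas)
    # 51000 = end + 20 kb in, 51001 out; 10000 = start - 20 kb in, 9999 out
    expect_setequal(map$gA, c("snp1", "snp3", "snp5"))
    # window clamps at position 1 and rejects negatives
    nearStart <- mapSnpsToGenes(makeAnnotation("chr1", 5, 10, "gB"),
                                makeGwas("chr1", 1))
    expect_identical(nearStart$gB, "snp1")
    expect_error(mapSnpsToGenes(ann, gwas, window = -1), "window")
    expect_error(mapSnpsToGenes(ann, makeGwas("chrX", 100)),
                 "no shared chromosome")
})

test_that("mapping equals the brute-force interval scan on a tiled genome", {
    gs <- simulateGenomeGwas(genomeSimConfig(nChromosomes = 2, nSnps = 5000,
                                             seed = 37),
                             sprintf("gene%04d", 1:50))
    map <- mapSnpsToGenes(gs$annotation, gs$gwas, window = 20000)
    ann <- gs$annotation
    for (g in names(ann)) {
        hit <- gs$gwas$chrom ==
            as.character(GenomicRanges::seqnames(ann[g])) &
            gs$gwas$pos >= max(1, GenomicRanges::start(ann[g]) - 20000) &
            gs$gwas$pos <= GenomicRanges::end(ann[g]) + 20000
        expect_identical(sort(map[[g]]), sort(gs$gwas$snp_id[hit]))
    }
})

test_that("gene-set SNPs are a union counted once, with untestable sets signalled", {
    ann <- makeAnnotation("chr1", c(1000, 30000, 500000),
                          c(2000, 31000, 501000), c("gA", "gB", "gC"))
    gwas <- makeGwas("chr1", c(25000, 100, 600000))
    map <- mapSnpsToGenes(ann, gwas)
    # snp1 at 25000 sits in both gA's and gB's windows: counted once
    expect_identical(genesetSnps(map, c("gA", "gB")),
                     unique(c(map$gA, map$gB)))
    expect_length(genesetSnps(map, c("gA", "gB")), 2)
    expect_length(genesetSnps(map, "gC"), 0)   # untestable set
    expect_message(genesetSnps(map, c("gA", "missing")), "not in the SNP map")
})

test_that("T_sum is the sum of squared effects, homogeneous of degree 2", {
    expect_equal(tSum(c(0.1, -0.2, 0.3)), 0.14)
    expect_equal(tSum(rep(0, 5)), 0)
    x <- c(0.3, -1.2, 0.05)
    expect_equal(tSum(3 * x), 9 * tSum(x))
    expect_error(tSum(numeric()), "non-empty")
})

test_that("the empirical p-value counts ties conservatively with a pseudocount", {
    expect_equal(empiricalP(2.5, c(1, 2, 3, 4)), 0.6)  # (1 + 2) / (1 + 4)
    expect_equal(empiricalP(5, c(1, 2, 3, 4)), 1 / 5)  # floor of estimator
    expect_equal(empiricalP(0, c(1, 2, 3, 4)), 1)
    expect_equal(empiricalP(4, c(1, 2, 3, 4)), 2 / 5)  # tie counts >=
})

test_that("permutation p-values are seeded, deterministic and scale-invariant", {
    set.seed(41)
    effects <- rnorm(200)
    tObs <- tSum(effects[1:10])
    p1 <- permutationP(tObs, 10, effects, nPerm = 500, seed = 5)
    expect_identical(p1, permutationP(tObs, 10, effects, nPerm = 500,
                                      seed = 5))
    # multiplying every effect by a constant rescales statistic and null alike
    p2 <- permutationP(tSum(7 * effects[1:10]), 10, 7 * effects,
                       nPerm = 500, seed = 5)
    expect_identical(p1, p2)
    expect_error(permutationP(1, 300, effects), "exceeds")
})

test_that("permutation p converges to the exhaustive-enumeration value", {
    set.seed(43)
    effects <- rnorm(12)
    subset3 <- utils::combn(12, 3)
    tObs <- tSum(effects[c(2, 5, 9)])
    exact <- mean(apply(subset3, 2, function(i) tSum(effects[i]) >= tObs))
    p <- permutationP(tObs, 3, effects, nPerm = 50000, seed = 7)
    expect_lt(abs(p - exact), 0.01)
})

test_that("enrichment over sets applies BH across testable sets only", {
    genes <- sprintf("gene%04d", 1:100)
    eset <- GeneSet("planted", genes[1:10])
    gs <- simulateGenomeGwas(
        genomeSimConfig(nSnps = 2000, enrichedEffectSd = 0.4,
                        enrichedGeneSet = eset, seed = 47), genes)
    sets <- list(eset, GeneSet("decoy", genes[51:60]))
    res <- enrichGeneSets(sets, gs$annotation, gs$gwas, nPerm = 300,
                          seed = 3)
    expect_identical(res$set, c("planted", "decoy"))
    expect_lt(res$p_emp[1], res$p_emp[2])
    expect_equal(res$fdr, p.adjust(res$p_emp, "BH"))
    # single testable set: fdr equals p_emp
    one <- enrichGeneSets(list(eset), gs$annotation, gs$gwas, nPerm = 100,
                          seed = 3)
    expect_equal(one$fdr, one$p_emp)
    # untestable sets carry NA and are excluded from the FDR
    far <- GeneSet("far", "gene0100")  # last gene; shrink its window reach
    emptyGwas <- gs$gwas[gs$gwas$chrom == "none", ]
    expect_error(enrichGeneSets(list(far), gs$annotation, emptyGwas),
                 "no testable|no shared")
})

test_that("the gene-matched null mode is a valid alternative calibration", {
    genes <- sprintf("gene%04d", 1:100)
    gs <- simulateGenomeGwas(genomeSimConfig(nSnps = 2000, seed = 53), genes)
    sets <- list(GeneSet("s1", genes[1:10]), GeneSet("s2", genes[41:50]))
    res <- enrichGeneSets(sets, gs$annotation, gs$gwas, nPerm = 200,
                          seed = 9, nullMode = "gene")
    expect_true(all(res$p_emp > 0 & res$p_emp <= 1))
})

test_that("stronger planted enrichment stochastically lowers the set's p-value", {
    genes <- sprintf("gene%04d", 1:200)
    eset <- GeneSet("planted", genes[1:20])
    pAt <- function(mult, seed) {
        gs <- simulateGenomeGwas(
            genomeSimConfig(nSnps = 4000, backgroundEffectSd = 0.1,
                            enrichedEffectSd = 0.1 * mult,
                            enrichedGeneSet = eset, seed = seed), genes)
        enrichGeneSets(list(eset), gs$annotation, gs$gwas, nPerm = 200,
                       seed = seed)$p_emp
    }
    seeds <- 1:8
    pNull <- vapply(seeds, function(s) pAt(1, s), numeric(1))
    pMid <- vapply(seeds, function(s) pAt(2, s), numeric(1))
    pHigh <- vapply(seeds, function(s) pAt(4, s), numeric(1))
    expect_lt(mean(pMid), mean(pNull))
    expect_lte(mean(pHigh), mean(pMid))
})
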