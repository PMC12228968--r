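# Small deterministic fixtures built in code.

# Atlas from an explicit TPM matrix; default metadata gives each sample its
# own tissue unless tissue/stage vectors are supplied.
makeAtlas <- function(mat, tissue = NULL, stage = NULL, timepoint = NULL,
                      stageLevels = NULL) {
    mat <- as.matrix(mat)
    if (is.null(rownames(mat)))
        rownames(mat) <- sprintf("g%d", seq_len(nrow(mat)))
    if (is.null(colnames(mat)))
        colnames(mat) <- sprintf("s%d", seq_len(ncol(mat)))
    n <- ncol(mat)
    meta <- data.frame(
        sample_id = colnames(mat),
        tissue = if (is.null(tissue)) colnames(mat) else tissue,
        stage = if (is.null(stage)) rep("stage1", n) else stage)
    if (!is.null(timepoint)) meta$timepoint <- timepoint
    ExpressionAtlas(mat, meta, stageLevels = stageLevels)
}

# Atlas whose log2(TPM + 0.25) values are given exactly: inverts the
# transform so DE fold changes can be planted in closed form.
makeAtlasFromLog2 <- function(logmat, ...) {
    makeAtlas(2^as.matrix(logmat) - 0.25, ...)
}

# Tiled annotation + GWAS table built directly (no simulator), for
# boundary tests of the window mapping.
makeAnnotation <- function(chrom, start, end, ids) {
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
    names(gr) <- ids
    gr
}

makeGwas <- function(chrom, pos, beta = NULL) {
    n <- length(pos)
    data.frame(snp_id = sprintf("snp%d", seq_len(n)), chrom = chrom,
               pos = pos, beta = if (is.null(beta)) rep(0.1, n) else beta)
}

# Adjusted Rand index between two labelings (mclust's reference
# implementation; tests compare partitions, never label identities).
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
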