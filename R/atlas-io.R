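#' Read an expression atlas from TSV files
#'
#' The expression file is a TSV with gene ids in the first column and one
#' column per sample; the metadata file is a TSV with columns
#' \code{sample_id}, \code{tissue}, \code{stage} and optionally
#' \code{timepoint}. Every sample column must have a metadata row.
#'
#' @param path expression TSV path.
#' @param metaPath sample-metadata TSV path.
#' @param stageLevels optional developmental order of stage labels (defaults
#'   to order of first appearance in the metadata).
#' @return An [ExpressionAtlas-class].
#' @export
readExpressionAtlas <- function(path, metaPath, stageLevels = NULL) {
    tab <- utils::read.delim(path, check.names = FALSE,
                             stringsAsFactors = FALSE)
    ids <- as.character(tab[[1]])
    if (anyDuplicated(ids))
        stop("duplicate gene ids in ", path, ": ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    mat <- as.matrix(tab[, -1, drop = FALSE])
    rownames(mat) <- ids
    if (any(mat < 0))
        stop("negative expression values in ", path)
    meta <- utils::read.delim(metaPath, stringsAsFactors = FALSE)
    if (!all(c("sample_id", "tissue", "stage") %in% names(meta)))
        stop("metadata must have columns sample_id, tissue, stage")
    missing <- setdiff(colnames(mat), meta$sample_id)
    if (length(missing))
        stop("samples missing from metadata: ",
             paste(missing, collapse = ", "))
    ExpressionAtlas(mat, meta, stageLevels = stageLevels)
}

#' Write an expression atlas to TSV files
#'
#' @param atlas an [ExpressionAtlas-class].
#' @param path expression TSV path (column \code{gene_id} then samples).
#' @param metaPath sample-metadata TSV path.
#' @return Invisibly, \code{c(path, metaPath)}.
#' @export
writeExpressionAtlas <- function(atlas, path, metaPath) {
    tab <- data.frame(gene_id = rownames(atlas), tpm(atlas),
                      check.names = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    cd <- as.data.frame(colData(atlas))
    cd$stage <- as.character(cd$stage)
    if (!"sample_id" %in% names(cd))
        cd <- cbind(sample_id = colnames(atlas), cd)
    utils::write.table(cd, metaPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(c(path, metaPath))
}

#' Read a gene annotation from GFF3 or BED
#'
#' GFF3 coordinates are used as-is (1-based, inclusive); BED input (0-based,
#' half-open) is converted on read by the importer. Only gene features are
#' kept from GFF3. Gene ids are taken from the \code{ID} (or \code{Name} /
#' \code{name}) attribute.
#'
#' @param path annotation file.
#' @param format \code{"auto"} (by extension), \code{"gff3"} or \code{"bed"}.
#' @return A named \link[GenomicRanges]{GRanges}, one range per gene.
#' @export
readGeneAnnotation <- function(path, format = c("auto", "gff3", "bed")) {
    format <- match.arg(format)
    if (format == "auto")
        format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed"
                  else "gff3"
    gr <- rtracklayer::import(path, format = format)
    mc <- S4Vectors::mcols(gr)
    if ("type" %in% names(mc))
        gr <- gr[as.character(mc$type) == "gene"]
    mc <- S4Vectors::mcols(gr)
    idCol <- intersect(c("ID", "Name", "name"), names(mc))[1]
    if (is.na(idCol))
        stop("no gene id attribute (ID/Name/name) found in ", path)
    names(gr) <- as.character(mc[[idCol]])
    if (anyDuplicated(names(gr)))
        stop("duplicate gene ids in annotation ", path)
    gr
}

#' Write a gene annotation as GFF3 (gene features only)
#'
#' @param ann named \link[GenomicRanges]{GRanges} of gene bodies.
#' @param path output GFF3 path.
#' @return Invisibly, \code{path}.
#' @export
writeGeneAnnotation <- function(ann, path) {
    gr <- GenomicRanges::granges(ann)
    S4Vectors::mcols(gr)$type <- "gene"
    S4Vectors::mcols(gr)$ID <- names(ann)
    rtracklayer::export(gr, path, format = "gff3")
    invisible(path)
}

#' Read GWAS summary statistics from TSV
#'
#' Requires columns \code{snp_id}, \code{chrom}, \code{pos} (1-based bp) and
#' \code{beta} (the per-SNP marginal effect b); extra columns are preserved
#' but ignored by the enrichment test.
#'
#' @param path GWAS summary TSV.
#' @return A data.frame with at least the four required columns.
#' @export
readGwasSummary <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("snp_id", "chrom", "pos", "beta")
    miss <- setdiff(need, names(tab))
    if (length(miss))
        stop("GWAS summary is missing columns: ", paste(miss, collapse = ", "))
    if (anyDuplicated(tab$snp_id)) stop("duplicate snp_id in ", path)
    if (nrow(tab) && any(tab$pos < 1)) stop("SNP positions must be >= 1")
    if (anyNA(tab$beta) || any(!is.finite(tab$beta)))
        stop("non-finite SNP effects in ", path)
    tab
}

#' @rdname readGwasSummary
#' @param gwas a GWAS summary data.frame.
#' @export
writeGwasSummary <- function(gwas, path) {
    utils::write.table(gwas, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Expression-level quality-control filters
#'
#' Three row/column filters applied to a TPM atlas, each idempotent:
#' \describe{
#'   \item{\code{filterUnexpressedGenes}}{keeps genes expressed (TPM >=
#'     \code{minTpm}) in at least one sample.}
#'   \item{\code{filterLowBreadthSamples}}{drops samples in which fewer than
#'     \code{minFraction} of the atlas's current genes are expressed
#'     (removal only when strictly below the threshold).}
#'   \item{\code{filterSmallTissues}}{drops every sample of a tissue with
#'     fewer than \code{minN} samples.}
#' }
#' The pipeline applies them in that fixed order (genes, then samples, then
#' tissues); see [qcAtlas()].
#'
#' @param atlas an [ExpressionAtlas-class].
#' @param minTpm expression threshold defining "expressed" (default 0.1,
#'   inclusive).
#' @return A filtered [ExpressionAtlas-class].
#' @export
filterUnexpressedGenes <- function(atlas, minTpm = 0.1) {
    keep <- rowSums(tpm(atlas) >= minTpm) > 0
    atlas[keep, ]
}

#' @rdname filterUnexpressedGenes
#' @param minFraction minimum fraction of genes expressed per sample
#'   (default 0.40).
#' @export
filterLowBreadthSamples <- function(atlas, minFraction = 0.40,
                                    minTpm = 0.1) {
    frac <- colMeans(tpm(atlas) >= minTpm)
    atlas[, frac >= minFraction]
}

#' @rdname filterUnexpressedGenes
#' @param minN minimum number of samples a tissue must retain (default 3).
#' @export
filterSmallTissues <- function(atlas, minN = 3) {
    counts <- table(sampleTissue(atlas))
    keep <- sampleTissue(atlas) %in% names(counts)[counts >= minN]
    atlas[, keep]
}

#' Drop a manual exclude-list of samples
#'
#' Cohort-level outlier removal (e.g. from inspecting the sample clustering)
#' has no closed-form rule; it is exposed as an explicit exclude-list only.
#'
#' @param atlas an [ExpressionAtlas-class].
#' @param sampleIds character vector of sample ids to drop; ids not present
#'   are ignored with a warning.
#' @return The atlas without those samples.
#' @export
excludeSamples <- function(atlas, sampleIds) {
    unknown <- setdiff(sampleIds, colnames(atlas))
    if (length(unknown))
        warning("exclude-list samples not in atlas: ",
                paste(unknown, collapse = ", "))
    atlas[, !colnames(atlas) %in% sampleIds]
}

#' Apply the full QC filter chain with a report
#'
#' Runs [filterUnexpressedGenes()], [filterLowBreadthSamples()] and
#' [filterSmallTissues()] in that order, after dropping any manual
#' exclude-list, and reports the count removed by each rule.
#'
#' @inheritParams filterUnexpressedGenes
#' @inheritParams filterLowBreadthSamples
#' @param minTissueN minimum tissue sample count.
#' @param exclude optional character vector of sample ids to drop first.
#' @param quiet suppress the per-rule messages.
#' @return A list with \code{atlas} (filtered) and \code{report} (named
#'   integer vector of removal counts).
#' @export
qcAtlas <- function(atlas, minTpm = 0.1, minFraction = 0.40, minTissueN = 3,
                    exclude = NULL, quiet = FALSE) {
    report <- c(excluded = 0L, genes = 0L, samples = 0L, tissues = 0L)
    if (length(exclude)) {
        a2 <- excludeSamples(atlas, exclude)
        report["excluded"] <- ncol(atlas) - ncol(a2)
        atlas <- a2
    }
    a2 <- filterUnexpressedGenes(atlas, minTpm)
    report["genes"] <- nrow(atlas) - nrow(a2)
    a3 <- filterLowBreadthSamples(a2, minFraction, minTpm)
    report["samples"] <- ncol(a2) - ncol(a3)
    a4 <- filterSmallTissues(a3, minTissueN)
    report["tissues"] <- ncol(a3) - ncol(a4)
    if (!quiet)
        message("QC: removed ", report["excluded"], " excluded samples, ",
                report["genes"], " unexpressed genes, ",
                report["samples"], " low-breadth samples, ",
                report["tissues"], " samples from small tissues; ",
                nrow(a4), " genes x ", ncol(a4), " samples retained")
    list(atlas = a4, report = report)
}

#' Log-transform TPM values
#'
#' Elementwise \code{log2(TPM + pseudocount)}; the 0.25 pseudocount keeps
#' zeros at a finite floor of -2 log2 units.
#'
#' @param x an [ExpressionAtlas-class] or a non-negative numeric matrix.
#' @param pseudocount added before taking log2 (default 0.25).
#' @return A matrix in log2 units with the input's dimnames.
#' @export
logTransform <- function(x, pseudocount = 0.25) {
    mat <- if (is(x, "ExpressionAtlas")) tpm(x) else as.matrix(x)
    if (any(mat < 0)) stop("negative expression values cannot be logged")
    log2(mat + pseudocount)
}

#' Select the most variable genes
#'
#' Ranks genes by descending standard deviation of TPM across samples (ties
#' broken by gene id, lexicographically) and returns the top \code{k} ids —
#' the gene selection used for sample clustering and ordination.
#'
#' @param atlas an [ExpressionAtlas-class].
#' @param k number of genes to keep (default 6000).
#' @return Character vector of \code{k} gene ids.
#' @export
topVarianceGenes <- function(atlas, k = 6000) {
    if (k > nrow(atlas))
        stop("k (", k, ") exceeds the number of genes (", nrow(atlas), ")")
    x <- tpm(atlas)
    sds <- apply(x, 1, stats::sd)
    ids <- rownames(x)[order(-sds, rownames(x))]
    ids[seq_len(k)]
}

#' Correlation-based sample distance matrix
#'
#' D = 1 - r between sample columns, with r the Pearson correlation — the
#' distance used for hierarchical clustering of atlas samples.
#'
#' @param logmat samples-in-columns matrix (typically [logTransform()]
#'   output).
#' @return Symmetric samples x samples matrix with zero diagonal.
#' @export
sampleDistance <- function(logmat) {
    if (ncol(logmat) < 2) stop("need at least 2 samples")
    sds <- apply(logmat, 2, stats::sd)
    if (any(sds == 0))
        stop("zero-variance sample column(s): ",
             paste(colnames(logmat)[sds == 0], collapse = ", "))
    d <- 1 - stats::cor(logmat)
    diag(d) <- 0
    d
}
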