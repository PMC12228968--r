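#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData rowData
NULL

#' ExpressionAtlas: a multi-tissue, multi-stage TPM expression matrix
#'
#' An \code{ExpressionAtlas} holds a genes x samples matrix of TPM values
#' (assay \code{"tpm"}) together with per-sample metadata: a \code{tissue}
#' label, an ordered \code{stage} label, and optionally a \code{timepoint}
#' within stage. It extends \linkS4class{SummarizedExperiment}, so all the
#' usual subsetting, \code{assay()} and \code{colData()} machinery applies.
#'
#' Invariants enforced by the validity method: TPM values are finite and
#' non-negative (missing values are not permitted; upstream quantifiers emit
#' zeros, not NA), gene and sample identifiers are unique and non-empty, every
#' sample carries a tissue and a stage label, and the stage column is an
#' ordered factor so that developmental time has a total order.
#'
#' @slot .. see \linkS4class{SummarizedExperiment}.
#'
#' @seealso [ExpressionAtlas()] for construction from a matrix and a
#'   metadata data frame, [tpm()], [sampleTissue()], [sampleStage()].
#' @export
setClass("ExpressionAtlas", contains = "SummarizedExperiment")

.validExpressionAtlas <- function(object) {
    msg <- character()
    if (!"tpm" %in% names(assays(object)))
        msg <- c(msg, "assay 'tpm' is required")
    else {
        x <- assay(object, "tpm")
        if (anyNA(x) || any(!is.finite(x)))
            msg <- c(msg, "TPM matrix contains missing or non-finite values")
        else if (any(x < 0))
            msg <- c(msg, "TPM values must be non-negative")
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "gene ids must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids must be present and unique")
    cd <- colData(object)
    for (col in c("tissue", "stage")) {
        if (!col %in% names(cd))
            msg <- c(msg, sprintf("colData column '%s' is required", col))
        else if (anyNA(cd[[col]]))
            msg <- c(msg, sprintf("colData column '%s' has missing values", col))
    }
    if ("stage" %in% names(cd) && !is.ordered(cd$stage))
        msg <- c(msg, "'stage' must be an ordered factor")
    if (length(msg)) msg else TRUE
}

setValidity("ExpressionAtlas", .validExpressionAtlas)

#' Construct an ExpressionAtlas
#'
#' @param tpm numeric matrix of TPM values, genes in rows (rownames = gene
#'   ids), samples in columns (colnames = sample ids).
#' @param sampleInfo data frame with one row per sample. Must contain
#'   \code{sample_id} (or have row names matching the matrix columns),
#'   \code{tissue} and \code{stage}; \code{timepoint} is kept when present.
#'   Rows are reordered to match the column order of \code{tpm}.
#' @param stageLevels optional character vector giving the developmental
#'   order of stage labels; defaults to the order of first appearance in
#'   \code{sampleInfo}.
#'
#' @return An [ExpressionAtlas-class] object.
#' @examples
#' tpm <- matrix(c(5, 0, 1, 2, 8, 3), nrow = 3,
#'               dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' meta <- data.frame(sample_id = c("s1", "s2"),
#'                    tissue = c("liver", "muscle"),
#'                    stage = c("prenatal", "adult"))
#' ExpressionAtlas(tpm, meta)
#' @export
ExpressionAtlas <- function(tpm, sampleInfo, stageLevels = NULL) {
    tpm <- as.matrix(tpm)
    sampleInfo <- as.data.frame(sampleInfo)
    if ("sample_id" %in% names(sampleInfo))
        rownames(sampleInfo) <- as.character(sampleInfo$sample_id)
    if (is.null(colnames(tpm)))
        stop("expression matrix must have sample ids as column names")
    missing <- setdiff(colnames(tpm), rownames(sampleInfo))
    if (length(missing))
        stop("samples missing from metadata: ", paste(missing, collapse = ", "))
    sampleInfo <- sampleInfo[colnames(tpm), , drop = FALSE]
    if (is.null(stageLevels))
        stageLevels <- unique(as.character(sampleInfo$stage))
    sampleInfo$stage <- factor(as.character(sampleInfo$stage),
                               levels = stageLevels, ordered = TRUE)
    if (anyNA(sampleInfo$stage))
        stop("stage labels outside 'stageLevels' found in metadata")
    se <- SummarizedExperiment(assays = list(tpm = tpm),
                               colData = DataFrame(sampleInfo))
    new("ExpressionAtlas", se)
}

#' @describeIn ExpressionAtlas-class TPM matrix accessor.
#' @param x an \code{ExpressionAtlas}.
#' @export
tpm <- function(x) assay(x, "tpm")

#' @describeIn ExpressionAtlas-class per-sample tissue labels.
#' @export
sampleTissue <- function(x) as.character(colData(x)$tissue)

#' @describeIn ExpressionAtlas-class per-sample stage labels (ordered factor).
#' @export
sampleStage <- function(x) colData(x)$stage

#' @describeIn ExpressionAtlas-class per-sample timepoint labels, or NULL.
#' @export
sampleTimepoint <- function(x) colData(x)$timepoint

setMethod("show", "ExpressionAtlas", function(object) {
    cat("ExpressionAtlas:", nrow(object), "genes x", ncol(object), "samples\n")
    cat("  tissues:", paste(unique(sampleTissue(object)), collapse = ", "), "\n")
    cat("  stages: ", paste(levels(sampleStage(object)), collapse = " < "), "\n")
    invisible(object)
})

#' GeneSet: a named collection of gene ids with provenance
#'
#' Gene sets are the unit handed from the specificity and clustering stages
#' to the GWAS enrichment test. The \code{provenance} string records how the
#' set was derived, e.g. \code{"tissue-specific:liver"},
#' \code{"stage-specific:muscle/adult"}, \code{"cluster:3"} or \code{"user"}.
#'
#' @slot name single character label.
#' @slot genes character vector of gene ids (unique, non-empty).
#' @slot provenance single character string.
#' @export
setClass("GeneSet",
    representation(name = "character", genes = "character",
                   provenance = "character"))

setValidity("GeneSet", function(object) {
    msg <- character()
    if (length(object@name) != 1L) msg <- c(msg, "'name' must be length 1")
    if (anyDuplicated(object@genes)) msg <- c(msg, "'genes' must be unique")
    if (length(object@provenance) != 1L)
        msg <- c(msg, "'provenance' must be length 1")
    if (length(msg)) msg else TRUE
})

#' Construct a GeneSet
#'
#' @param name label for the set.
#' @param genes character vector of gene ids; duplicates are removed.
#' @param provenance free-text origin tag (default \code{"user"}).
#' @return A [GeneSet-class] object.
#' @export
GeneSet <- function(name, genes, provenance = "user") {
    new("GeneSet", name = as.character(name),
        genes = unique(as.character(genes)),
        provenance = as.character(provenance))
}

#' @describeIn GeneSet-class gene ids in the set.
#' @param x a \code{GeneSet}.
#' @export
geneIds <- function(x) x@genes

#' @describeIn GeneSet-class set name.
#' @export
setName <- function(x) x@name

setMethod("show", "GeneSet", function(object) {
    cat("GeneSet '", object@name, "' (", length(object@genes), " genes; ",
        object@provenance, ")\n", sep = "")
    invisible(object)
})

#' FuzzyClustering: result of fuzzy c-means on trajectory profiles
#'
#' @slot centroids K x stages matrix of cluster centres (z-units).
#' @slot membership genes x K matrix of graded memberships; each row sums
#'   to 1.
#' @slot m fuzzification exponent used (> 1).
#' @slot objective final value of the weighted within-cluster sum of squared
#'   distances.
#' @slot trace objective value after every sweep (non-increasing).
#' @export
setClass("FuzzyClustering",
    representation(centroids = "matrix", membership = "matrix",
                   m = "numeric", objective = "numeric", trace = "numeric"))

setValidity("FuzzyClustering", function(object) {
    msg <- character()
    if (nrow(object@centroids) < 2L) msg <- c(msg, "need K >= 2 centroids")
    if (ncol(object@membership) != nrow(object@centroids))
        msg <- c(msg, "membership columns must match centroid count")
    u <- object@membership
    if (any(u < -1e-9) || any(u > 1 + 1e-9))
        msg <- c(msg, "memberships must lie in [0,1]")
    if (any(abs(rowSums(u) - 1) > 1e-9))
        msg <- c(msg, "membership rows must sum to 1")
    if (object@m <= 1) msg <- c(msg, "fuzzifier m must exceed 1")
    if (length(msg)) msg else TRUE
})

#' @describeIn FuzzyClustering-class hard labels by largest membership.
#' @param x a \code{FuzzyClustering}.
#' @export
clusterLabels <- function(x) max.col(x@membership, ties.method = "first")

#' @describeIn FuzzyClustering-class membership matrix accessor.
#' @export
membership <- function(x) x@membership

#' @describeIn FuzzyClustering-class centroid matrix accessor.
#' @export
centroids <- function(x) x@centroids

setMethod("show", "FuzzyClustering", function(object) {
    cat("FuzzyClustering: K =", nrow(object@centroids),
        "clusters,", nrow(object@membership), "genes, m =", object@m, "\n")
    cat("  objective:", format(object@objective), "after",
        length(object@trace), "sweeps\n")
    invisible(object)
})
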