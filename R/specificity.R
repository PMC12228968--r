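#' Tau tissue-specificity index
#'
#' For a per-group expression profile x of length N,
#' tau = sum_i (1 - x_i / max(x)) / (N - 1). Tau is 0 for perfectly uniform
#' expression, 1 for expression confined to a single group, and invariant to
#' positive rescaling of the profile.
#'
#' \code{tau()} evaluates the index on a profile as given;
#' \code{tissueTau()} computes the package's standard per-gene profile first
#' — the per-tissue median TPM transformed as \code{log2(x + 1)} — and then
#' applies the index to every gene.
#'
#' @param x non-negative numeric profile (one value per group), not all
#'   zero, length >= 2.
#' @return \code{tau()}: a single value in [0, 1].
#' @examples
#' tau(c(10, 0, 0, 0))  # 1: single-group expression
#' tau(c(5, 5, 5, 5))   # 0: uniform
#' @export
tau <- function(x) {
    if (length(x) < 2) stop("tau needs at least 2 groups")
    if (any(x < 0)) stop("tau is defined for non-negative profiles")
    mx <- max(x)
    if (mx == 0) stop("tau is undefined for an all-zero profile")
    sum(1 - x / mx) / (length(x) - 1)
}

#' @rdname tau
#' @param atlas an [ExpressionAtlas-class].
#' @return \code{tissueTau()}: named per-gene vector of tau values (NA for
#'   genes with an all-zero profile).
#' @export
tissueTau <- function(atlas) {
    tissues <- unique(sampleTissue(atlas))
    if (length(tissues) < 2) stop("tau needs at least 2 tissues")
    x <- tpm(atlas)
    med <- vapply(tissues, function(t) {
        cols <- sampleTissue(atlas) == t
        apply(x[, cols, drop = FALSE], 1, stats::median)
    }, numeric(nrow(x)))
    prof <- log2(med + 1)
    mx <- apply(prof, 1, max)
    out <- rowSums(1 - prof / mx) / (ncol(prof) - 1)
    out[mx == 0] <- NA_real_
    names(out) <- rownames(x)
    out
}

#' One-vs-rest differential expression
#'
#' Compares one group of samples against all remaining samples, gene by
#' gene, on \code{log2(TPM + 0.25)} values: the log2 fold change is the
#' difference of group means, the p-value comes from a two-sided Welch
#' t-test on the same transformed values, and FDR is Benjamini-Hochberg
#' across all genes in the comparison.
#'
#' @param atlas an [ExpressionAtlas-class].
#' @param group target group label.
#' @param grouping which metadata column defines groups: \code{"tissue"}
#'   (default) or \code{"stage"} (one stage vs the rest, typically on a
#'   within-tissue sub-atlas).
#' @param minSamples minimum samples required on each side (default 2).
#' @return data.frame with columns \code{gene_id}, \code{log2FC}, \code{p},
#'   \code{fdr}, \code{direction} (\code{"up"} when log2FC > 0), ordered as
#'   the atlas genes.
#' @export
oneVsRestDE <- function(atlas, group, grouping = c("tissue", "stage"),
                        minSamples = 2) {
    grouping <- match.arg(grouping)
    labels <- if (grouping == "tissue") sampleTissue(atlas)
              else as.character(sampleStage(atlas))
    inGroup <- which(labels == group)
    outGroup <- which(labels != group)
    if (length(inGroup) < minSamples || length(outGroup) < minSamples)
        stop("group '", group, "' needs >= ", minSamples,
             " samples on each side (has ", length(inGroup), " vs ",
             length(outGroup), ")")
    lmat <- logTransform(atlas)
    w <- rowWelch(lmat, inGroup, outGroup)
    data.frame(gene_id = rownames(atlas), log2FC = w$diff, p = w$p,
               fdr = stats::p.adjust(w$p, method = "BH"),
               direction = ifelse(w$diff > 0, "up", "down"),
               stringsAsFactors = FALSE)
}

## Deterministic ranking used by the top-fraction rule: ascending FDR, then
## ascending p, then descending log2FC, then gene id.
.rankDE <- function(de) {
    order(de$fdr, de$p, -de$log2FC, de$gene_id)
}

#' Call tissue-specific genes by the top-5\% rule
#'
#' Runs (or reuses) a one-vs-rest comparison of the target tissue against
#' all others, restricts to upregulated genes (log2FC > 0), ranks by
#' ascending FDR (ties: ascending p, then descending log2FC, then gene id),
#' and returns the first \code{ceiling(fraction * genes tested)}. If fewer
#' genes are upregulated than the quota, all of them are returned with a
#' warning.
#'
#' @param atlas an [ExpressionAtlas-class].
#' @param tissue target tissue label.
#' @param fraction top fraction of tested genes to call specific
#'   (default 0.05).
#' @param de optional precomputed [oneVsRestDE()] table for this tissue.
#' @return A [GeneSet-class] with provenance
#'   \code{"tissue-specific:<tissue>"}.
#' @export
tissueSpecificGenes <- function(atlas, tissue, fraction = 0.05, de = NULL) {
    if (is.null(de)) de <- oneVsRestDE(atlas, tissue, "tissue")
    quota <- ceiling(fraction * nrow(de))
    up <- de[de$log2FC > 0, , drop = FALSE]
    up <- up[.rankDE(up), , drop = FALSE]
    if (nrow(up) < quota) {
        warning("tissue '", tissue, "': only ", nrow(up),
                " upregulated genes for a quota of ", quota)
        quota <- nrow(up)
    }
    GeneSet(paste0(tissue, "_specific"), up$gene_id[seq_len(quota)],
            provenance = paste0("tissue-specific:", tissue))
}

#' Call developmental-stage-specific genes
#'
#' Within one tissue, compares one stage against the remaining stages and
#' returns genes with log2 fold change > \code{log2fcMin} (strict) and
#' FDR < \code{fdrMax} (strict).
#'
#' @param atlas an [ExpressionAtlas-class] (the full atlas; it is subset to
#'   the tissue internally).
#' @param tissue tissue whose developmental axis is tested.
#' @param stage target stage label.
#' @param log2fcMin fold-change threshold in log2 units (default 2).
#' @param fdrMax FDR threshold (default 0.05).
#' @param minSamples minimum samples required in the stage and in its
#'   complement (default 3).
#' @return A [GeneSet-class] with provenance
#'   \code{"stage-specific:<tissue>/<stage>"}; may be empty.
#' @export
stageSpecificGenes <- function(atlas, tissue, stage, log2fcMin = 2,
                               fdrMax = 0.05, minSamples = 3) {
    sub <- atlas[, sampleTissue(atlas) == tissue]
    nIn <- sum(as.character(sampleStage(sub)) == stage)
    nOut <- ncol(sub) - nIn
    if (nIn < minSamples || nOut < minSamples)
        stop("tissue '", tissue, "', stage '", stage, "': need >= ",
             minSamples, " samples in the stage and its complement (has ",
             nIn, " vs ", nOut, ")")
    de <- oneVsRestDE(sub, stage, "stage", minSamples = minSamples)
    hits <- de$gene_id[de$log2FC > log2fcMin & de$fdr < fdrMax]
    GeneSet(paste0(tissue, "_", stage, "_specific"), hits,
            provenance = paste0("stage-specific:", tissue, "/", stage))
}
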