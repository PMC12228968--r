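#' Read co-expression module assignments
#'
#' Module detection (WGCNA-style clustering or matrix-factorization methods)
#' is performed upstream; assignments arrive as a TSV with columns
#' \code{gene_id} and \code{module_id} (optional \code{method},
#' \code{tissue}). A gene may belong to several modules — factorization
#' methods produce overlapping modules by design.
#'
#' @param path assignment TSV.
#' @return Named list mapping module id to a character vector of gene ids,
#'   with attributes \code{method} and \code{tissue} when those columns are
#'   present and single-valued.
#' @export
readModuleAssignments <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!all(c("gene_id", "module_id") %in% names(tab)))
        stop("module assignment TSV needs columns gene_id, module_id")
    mods <- split(as.character(tab$gene_id), as.character(tab$module_id))
    mods <- lapply(mods, unique)
    for (col in c("method", "tissue"))
        if (col %in% names(tab) && length(unique(tab[[col]])) == 1L)
            attr(mods, col) <- tab[[col]][1]
    mods
}

#' Module sharing index (Jaccard) between two sets of modules
#'
#' For every module pair (a in A, b in B) computes the Jaccard similarity
#' J = |a intersect b| / |a union b|, the module sharing index used to
#' compare co-expression modules found by different methods. Two empty
#' modules give 0 with a warning.
#'
#' @param a,b named lists of gene-id vectors (see
#'   [readModuleAssignments()]).
#' @return |A| x |B| matrix of values in [0, 1].
#' @examples
#' moduleSharingIndex(list(m1 = c("g1", "g2", "g3")),
#'                    list(w1 = c("g2", "g3", "g4")))  # 0.5
#' @export
moduleSharingIndex <- function(a, b) {
    if (!length(a) || !length(b)) stop("module lists must be non-empty")
    out <- matrix(0, length(a), length(b),
                  dimnames = list(names(a), names(b)))
    for (i in seq_along(a)) for (j in seq_along(b)) {
        uni <- length(union(a[[i]], b[[j]]))
        if (uni == 0) {
            warning("modules '", names(a)[i], "' and '", names(b)[j],
                    "' are both empty; Jaccard set to 0")
            next
        }
        out[i, j] <- length(intersect(a[[i]], b[[j]])) / uni
    }
    out
}

#' Module eigengene
#'
#' Summarizes a module as one per-sample score: the first principal
#' component of the gene-standardized \code{log2(TPM + 0.25)} submatrix of
#' the module's genes. The sign is fixed so the eigengene correlates
#' non-negatively with the module's mean standardized expression profile.
#'
#' @param atlas an [ExpressionAtlas-class].
#' @param genes gene ids of the module (>= 2 present in the atlas); missing
#'   ids are dropped with a warning.
#' @return Named numeric vector, one score per sample.
#' @export
moduleEigengene <- function(atlas, genes) {
    if (ncol(atlas) < 3) stop("need at least 3 samples")
    present <- intersect(genes, rownames(atlas))
    if (!length(present)) stop("no module genes found in the atlas")
    if (length(present) < length(genes))
        warning(length(genes) - length(present),
                " module gene(s) absent from the atlas")
    if (length(present) < 2) stop("need >= 2 module genes in the atlas")
    sub <- logTransform(atlas[present, ])
    z <- t(scale(t(sub)))
    keep <- rowSums(is.na(z)) == 0  # constant genes carry no signal
    z <- z[keep, , drop = FALSE]
    if (nrow(z) < 2) stop("fewer than 2 non-constant module genes")
    sv <- svd(z, nu = 0, nv = 1)
    eig <- drop(sv$v[, 1])
    ref <- colMeans(z)
    if (sum(eig * ref) < 0) eig <- -eig
    names(eig) <- colnames(atlas)
    eig
}

#' Module-stage association
#'
#' Correlates a module eigengene with each developmental stage's one-hot
#' sample indicator (point-biserial Pearson correlation), with a two-sided
#' p-value from the t-distribution transform of r. FDR is
#' Benjamini-Hochberg; when associating many modules, compute the table per
#' module with \code{adjust = FALSE} and correct jointly across all
#' (module, stage) pairs with [stats::p.adjust()], or use
#' [moduleStageAssociationTable()].
#'
#' @param eigengene per-sample score vector ([moduleEigengene()] output).
#' @param stages per-sample stage labels (ordered factor or character), in
#'   the same sample order.
#' @param adjust apply BH across this table's stages (default TRUE).
#' @return data.frame with columns \code{stage}, \code{r}, \code{p} and
#'   (when adjusted) \code{fdr}.
#' @export
moduleStageAssociation <- function(eigengene, stages, adjust = TRUE) {
    stages <- if (is.factor(stages)) droplevels(stages) else factor(stages)
    if (nlevels(stages) < 2) stop("need >= 2 stages")
    if (any(table(stages) < 2)) stop("every stage needs >= 2 samples")
    if (stats::sd(eigengene) == 0) stop("eigengene is constant")
    n <- length(eigengene)
    res <- do.call(rbind, lapply(levels(stages), function(s) {
        ind <- as.numeric(stages == s)
        r <- stats::cor(eigengene, ind)
        if (abs(r) >= 1) p <- 0
        else {
            t <- r * sqrt((n - 2) / (1 - r^2))
            p <- 2 * stats::pt(abs(t), n - 2, lower.tail = FALSE)
        }
        data.frame(stage = s, r = r, p = p, stringsAsFactors = FALSE)
    }))
    if (adjust) res$fdr <- stats::p.adjust(res$p, method = "BH")
    res
}

#' @rdname moduleStageAssociation
#' @param atlas an [ExpressionAtlas-class].
#' @param modules named list of module gene-id vectors.
#' @return \code{moduleStageAssociationTable()}: data.frame over all
#'   (module, stage) pairs with BH FDR applied jointly across the whole
#'   table.
#' @export
moduleStageAssociationTable <- function(atlas, modules) {
    res <- do.call(rbind, lapply(names(modules), function(mod) {
        eig <- moduleEigengene(atlas, modules[[mod]])
        tab <- moduleStageAssociation(eig, sampleStage(atlas),
                                      adjust = FALSE)
        cbind(module = mod, tab, stringsAsFactors = FALSE)
    }))
    res$fdr <- stats::p.adjust(res$p, method = "BH")
    res
}
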