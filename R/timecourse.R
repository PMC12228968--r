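#' Per-stage mean expression profiles
#'
#' Averages \code{log2(TPM + 0.25)} over the samples of each developmental
#' stage (within one tissue, or across the whole atlas), yielding the genes
#' x stages trajectory matrix that feeds the fuzzy clustering. Stages appear
#' in their metadata order; stages with no samples are omitted with a
#' warning.
#'
#' @param atlas an [ExpressionAtlas-class].
#' @param tissue optional tissue label to subset to first.
#' @param stages optional subset of stage labels to use (in atlas order).
#' @return genes x stages numeric matrix in log2 units.
#' @export
stageProfiles <- function(atlas, tissue = NULL, stages = NULL) {
    if (!is.null(tissue))
        atlas <- atlas[, sampleTissue(atlas) == tissue]
    lmat <- logTransform(atlas)
    lev <- levels(sampleStage(atlas))
    if (!is.null(stages)) lev <- lev[lev %in% stages]
    have <- lev[lev %in% as.character(sampleStage(atlas))]
    if (length(have) < 2) stop("need at least 2 stages with samples")
    if (length(have) < length(lev))
        warning("stages with no samples omitted: ",
                paste(setdiff(lev, have), collapse = ", "))
    prof <- vapply(have, function(s) {
        cols <- as.character(sampleStage(atlas)) == s
        rowMeans(lmat[, cols, drop = FALSE])
    }, numeric(nrow(lmat)))
    rownames(prof) <- rownames(atlas)
    prof
}

#' Row-standardize trajectory profiles
#'
#' Z-scores every gene's trajectory (mean 0 across stages, unit population
#' SD, so a row's z-values depend only on its shape, not on the number of
#' stages). Constant rows carry no trajectory shape; they are dropped and
#' reported via a warning and the \code{"dropped"} attribute.
#'
#' @param profiles genes x stages matrix (e.g. from [stageProfiles()]).
#' @return Standardized matrix, with attribute \code{dropped} listing the
#'   removed constant rows.
#' @export
standardizeRows <- function(profiles) {
    if (ncol(profiles) < 2) stop("need at least 2 stages")
    m <- rowMeans(profiles)
    s <- sqrt(rowMeans((profiles - m)^2))  # population SD
    drop <- s == 0
    if (any(drop))
        warning(sum(drop), " constant row(s) dropped: ",
                paste(utils::head(rownames(profiles)[drop], 5),
                      collapse = ", "))
    out <- (profiles[!drop, , drop = FALSE] - m[!drop]) / s[!drop]
    attr(out, "dropped") <- rownames(profiles)[drop]
    out
}

## Squared Euclidean distances between every row of x and every centroid.
.sqDist <- function(x, cent) {
    d2 <- matrix(rowSums(x^2), nrow(x), nrow(cent)) +
        matrix(rowSums(cent^2), nrow(x), nrow(cent), byrow = TRUE) -
        2 * x %*% t(cent)
    pmax(d2, 0)
}

## Fuzzy membership update: u_ik = 1 / sum_j (d_ik / d_ij)^(2/(m-1)).
## Points coinciding with a centroid get membership 1 there (degenerate
## rule), split evenly over tied centroids.
.fuzzyMembership <- function(d2, m) {
    w <- d2^(-1 / (m - 1))
    zero <- d2 < .Machine$double.eps
    hasZero <- rowSums(zero) > 0
    u <- w / rowSums(w)
    if (any(hasZero))
        u[hasZero, ] <- zero[hasZero, , drop = FALSE] /
            rowSums(zero[hasZero, , drop = FALSE])
    u
}

#' Fuzzy c-means clustering of trajectories
#'
#' Soft clustering by alternating optimization of the fuzzy c-means
#' objective sum_ik u_ik^m d(x_i, c_k)^2: memberships are updated as
#' u_ik = 1 / sum_j (d_ik/d_ij)^(2/(m-1)) and centroids as the u^m-weighted
#' means, iterated until the objective changes by less than \code{tol}.
#' Initialization picks K distinct data rows at random under \code{seed};
#' with \code{nstart > 1} the best of several seeded starts (lowest
#' objective) is returned. Identical seeds give identical results.
#'
#' @param x genes x stages matrix, typically [standardizeRows()] output.
#' @param k number of clusters (2 <= k <= rows).
#' @param m fuzzification exponent (> 1; default 2, the canonical choice).
#' @param tol convergence tolerance on the objective (default 1e-6).
#' @param maxIter sweep cap (default 1000).
#' @param seed RNG seed for initialization.
#' @param nstart number of random starts (default 1).
#' @return A [FuzzyClustering-class].
#' @export
fuzzyCMeans <- function(x, k, m = 2, tol = 1e-6, maxIter = 1000, seed = 1,
                        nstart = 1) {
    x <- as.matrix(x)
    if (k < 2) stop("k must be >= 2")
    if (k > nrow(x)) stop("k exceeds the number of rows")
    if (m <= 1) stop("fuzzifier m must exceed 1")
    one <- function(s) {
        cent <- withSeed(s, x[sample.int(nrow(x), k), , drop = FALSE])
        trace <- numeric()
        obj <- Inf
        for (it in seq_len(maxIter)) {
            d2 <- .sqDist(x, cent)
            u <- .fuzzyMembership(d2, m)
            newObj <- sum(u^m * d2)
            if (newObj > obj + 1e-8)
                warning("fuzzy c-means objective increased at sweep ", it)
            trace <- c(trace, newObj)
            done <- is.finite(obj) && abs(obj - newObj) < tol
            obj <- newObj
            if (done) break
            um <- u^m
            cent <- (t(um) %*% x) / colSums(um)
        }
        new("FuzzyClustering", centroids = cent, membership = u, m = m,
            objective = obj, trace = trace)
    }
    fits <- lapply(seq_len(nstart) - 1L + seed, one)
    fits[[which.min(vapply(fits, function(f) f@objective, numeric(1)))]]
}

#' Minimum centroid distance over a range of K
#'
#' Runs [fuzzyCMeans()] for each candidate K and reports the minimum
#' pairwise Euclidean distance between centroids — the model-selection curve
#' for choosing the number of trajectory clusters. The usual reading is to
#' pick the largest K before the curve's first steep drop (once K exceeds
#' the number of real trajectory shapes, two centroids land in the same
#' cluster and the minimum distance collapses); the drop location is
#' reported, not enforced.
#'
#' @inheritParams fuzzyCMeans
#' @param kRange integer vector of K values to scan.
#' @param nstart random starts per K (default 3).
#' @return data.frame with columns \code{k} and \code{minCentroidDist};
#'   attribute \code{"suggestedK"} holds the K preceding the largest drop.
#' @export
minCentroidDistance <- function(x, kRange = 2:8, m = 2, seed = 1,
                                nstart = 3) {
    dists <- vapply(kRange, function(k) {
        fit <- fuzzyCMeans(x, k, m = m, seed = seed, nstart = nstart)
        min(stats::dist(fit@centroids))
    }, numeric(1))
    out <- data.frame(k = kRange, minCentroidDist = dists)
    if (length(kRange) > 1) {
        drop <- -diff(dists)
        attr(out, "suggestedK") <- kRange[which.max(drop)]
    }
    out
}
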