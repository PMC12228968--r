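## Internal helpers shared across modules.

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
## All stochastic entry points funnel through this so a seed argument never
## disturbs the global stream.
withSeed <- function(seed, expr) {
    if (is.null(seed)) return(expr)
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

## Row-wise Welch two-sample t-test on a matrix: columns idx1 vs idx2.
## Returns mean difference, t, df and two-sided p per row. Degenerate rows
## (both groups constant) get p = 1 when the means agree and p = 0 otherwise.
rowWelch <- function(mat, idx1, idx2) {
    n1 <- length(idx1); n2 <- length(idx2)
    stopifnot(n1 >= 2L, n2 >= 2L)
    x1 <- mat[, idx1, drop = FALSE]
    x2 <- mat[, idx2, drop = FALSE]
    m1 <- rowMeans(x1); m2 <- rowMeans(x2)
    v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
    v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
    se2 <- v1 / n1 + v2 / n2
    diff <- m1 - m2
    t <- diff / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
    zero <- se2 == 0
    if (any(zero)) p[zero] <- ifelse(diff[zero] == 0, 1, 0)
    data.frame(diff = diff, t = t, df = df, p = p, row.names = rownames(mat))
}

## Checksum files for reproducibility manifests.
fileChecksums <- function(paths) {
    sums <- tools::md5sum(paths)
    names(sums) <- basename(paths)
    as.list(sums)
}
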