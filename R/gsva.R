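#' Gaussian-kernel CDF statistics per gene and sample
#'
#' For each gene, the expression value of each sample is scored by the
#' estimated cumulative density under a Gaussian kernel density fitted to
#' that gene's values across samples, with bandwidth `sd/4`:
#' `z_ij = mean_k Phi((x_ij - x_ik) / h_i)`. Constant genes get `z = 0.5`
#' everywhere.
#'
#' @param expr numeric matrix of log2 expression (genes x samples) or a
#'   `SummarizedExperiment`.
#' @return matrix of the same dimensions as the expression values.
#' @export
kernelCdfScores <- function(expr) {
    if (methods::is(expr, "SummarizedExperiment"))
        expr <- SummarizedExperiment::assay(expr)
    x <- as.matrix(expr)
    if (ncol(x) < 3L) stop("kernel CDF scoring needs at least 3 samples")
    if (!all(is.finite(x))) stop("expression values must be finite")
    z <- x
    for (i in seq_len(nrow(x))) z[i, ] <- .kcdfRow(x[i, ])
    z
}

.kcdfRow <- function(xi) {
    h <- stats::sd(xi) / 4
    if (!is.finite(h) || h == 0) return(rep(0.5, length(xi)))
    # column means of Phi((x_j - x_k)/h) over kernel centres k
    colMeans(stats::pnorm(outer(-xi, xi, "+") / h))
}

#' Enrichment scores by a weighted Kolmogorov-style random walk
#'
#' Per sample, genes are ranked by their kernel CDF statistic (largest
#' first) and the rank positions are symmetrized about the middle of the
#' list: gene weight `|N/2 - rank|^tau`. The walk steps up by the
#' normalized weight at member genes and down by `1/(N - m)` at
#' non-members; the enrichment score is the maximum positive deviation
#' minus the magnitude of the maximum negative deviation.
#'
#' @param z kernel CDF matrix from [kernelCdfScores()].
#' @param collection named list of gene sets.
#' @param tau weight exponent (default 1).
#' @param minSize sets with fewer surviving members after intersection
#'   with the matrix genes are dropped with a warning (default 2).
#' @return matrix of enrichment scores, sets x samples.
#' @export
esScores <- function(z, collection, tau = 1, minSize = 2) {
    z <- as.matrix(z)
    if (!length(collection)) stop("empty gene-set collection")
    genes <- rownames(z)
    if (is.null(genes)) stop("z must carry gene rownames")
    sets <- lapply(collection, intersect, y = genes)
    small <- vapply(sets, length, 0L) < minSize
    if (any(small)) {
        warning(sprintf("dropping %d set(s) with fewer than %d members after intersection",
                        sum(small), minSize))
        sets <- sets[!small]
    }
    if (!length(sets)) stop("no gene sets survive the size filter")
    N <- nrow(z)
    es <- matrix(NA_real_, length(sets), ncol(z),
                 dimnames = list(names(sets), colnames(z)))
    for (j in seq_len(ncol(z))) {
        ord <- order(z[, j], decreasing = TRUE)
        rnk <- integer(N); rnk[ord] <- seq_len(N)
        w <- abs(N / 2 - rnk)^tau
        for (s in seq_along(sets)) {
            idx <- match(sets[[s]], genes)
            es[s, j] <- .walkES(ord, idx, w, N)
        }
    }
    es
}

# Random-walk enrichment score over a fixed ranking.
# ord: gene indices from best to worst rank; idx: member gene indices;
# w: per-gene weights (indexed like genes); N: number of genes.
.walkES <- function(ord, idx, w, N) {
    m <- length(idx)
    inSet <- logical(N); inSet[idx] <- TRUE
    stepUp <- w[ord] * inSet[ord]
    denomUp <- sum(stepUp)
    up <- if (denomUp > 0) cumsum(stepUp) / denomUp else cumsum(inSet[ord]) / m
    down <- cumsum(!inSet[ord]) / max(N - m, 1L)
    v <- up - down
    max(c(0, v)) - max(c(0, -v))
}

#' Differential pathway activity between groups
#'
#' Applies the moderated two-group machinery ([fitGeneModels()] +
#' [moderateStatistics()]) to an enrichment-score matrix, sets playing the
#' role of genes, and retains sets with BH-adjusted `q < alpha`.
#'
#' @param es enrichment-score matrix (sets x samples) from [esScores()].
#' @param groups `"case"`/`"control"` labels, one per column of `es`.
#' @param alpha adjusted-p cut-off (strict; default 0.05).
#' @return data.frame with columns set, scoreDiff (case minus control),
#'   t, p, q, sorted by q then p.
#' @export
differentialPathways <- function(es, groups, alpha = 0.05) {
    fit <- fitGeneModels(as.matrix(es), groups)
    ms <- moderateStatistics(fit)
    tab <- ms@table
    out <- tab[tab$q < alpha, c("gene", "log2FC", "t", "p", "q"), drop = FALSE]
    names(out) <- c("set", "scoreDiff", "t", "p", "q")
    out <- out[order(out$q, out$p), , drop = FALSE]
    rownames(out) <- NULL
    out
}
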