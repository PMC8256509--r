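#' Collapse probe-level rows to one row per gene symbol
#'
#' Microarray platforms map several probes to the same gene symbol. Rows
#' sharing a symbol are replaced by their per-sample arithmetic mean; rows
#' with a missing or empty symbol are dropped.
#'
#' @param probeTable data.frame whose first (or named) column holds gene
#'   symbols and whose remaining columns are numeric per-sample values.
#' @param geneCol name of the symbol column. Default `"gene"`.
#' @return numeric matrix, one row per gene symbol (rownames), columns as
#'   in the input.
#' @examples
#' pt <- data.frame(gene = c("A", "A", "B"), s1 = c(1, 3, 5), s2 = c(3, 5, 7))
#' collapseProbes(pt)
#' @export
collapseProbes <- function(probeTable, geneCol = "gene") {
    if (!is.data.frame(probeTable) || nrow(probeTable) == 0L)
        stop("probeTable must be a non-empty data.frame")
    if (!geneCol %in% names(probeTable))
        stop("column '", geneCol, "' not found in probeTable")
    sym <- as.character(probeTable[[geneCol]])
    keep <- !is.na(sym) & nzchar(trimws(sym))
    probeTable <- probeTable[keep, , drop = FALSE]
    sym <- sym[keep]
    if (!nrow(probeTable)) stop("no probes with a gene symbol remain")
    vals <- as.matrix(probeTable[, setdiff(names(probeTable), geneCol), drop = FALSE])
    storage.mode(vals) <- "double"
    sums <- rowsum(vals, group = sym)
    cnt <- as.vector(table(sym)[rownames(sums)])
    sums / cnt
}

.exprAndGroups <- function(expr, groups) {
    if (methods::is(expr, "SummarizedExperiment")) {
        if (is.null(groups)) groups <- SummarizedExperiment::colData(expr)$group
        expr <- SummarizedExperiment::assay(expr)
    }
    if (is.null(groups)) stop("groups must be supplied (or held in colData(expr)$group)")
    groups <- as.character(groups)
    if (length(groups) != ncol(expr))
        stop("length(groups) must equal ncol(expr)")
    if (!all(groups %in% c("case", "control")))
        stop("groups must be 'case' or 'control'")
    list(x = as.matrix(expr), groups = groups)
}

#' Fit per-gene two-group linear models
#'
#' Ordinary least squares on the case/control design, gene by gene: the
#' log2 fold change is the difference of group means (case minus control)
#' and the residual variance is pooled across groups with
#' `nCase + nControl - 2` degrees of freedom.
#'
#' @param expr numeric matrix of log2 expression (genes x samples) or a
#'   `SummarizedExperiment` whose `colData` has a `group` column.
#' @param groups character vector of `"case"`/`"control"` labels, one per
#'   sample; taken from `colData(expr)$group` when `expr` is a
#'   SummarizedExperiment.
#' @return A [GeneFit-class] object.
#' @seealso [moderateStatistics()]
#' @export
fitGeneModels <- function(expr, groups = NULL) {
    eg <- .exprAndGroups(expr, groups)
    x <- eg$x; groups <- eg$groups
    if (!all(is.finite(x))) stop("expression values must be finite")
    i1 <- groups == "case"; i0 <- groups == "control"
    n1 <- sum(i1); n0 <- sum(i0)
    if (n1 < 2L || n0 < 2L)
        stop("each group needs at least 2 samples for a residual variance")
    m1 <- rowMeans(x[, i1, drop = FALSE])
    m0 <- rowMeans(x[, i0, drop = FALSE])
    ss1 <- rowSums((x[, i1, drop = FALSE] - m1)^2)
    ss0 <- rowSums((x[, i0, drop = FALSE] - m0)^2)
    df <- n1 + n0 - 2
    genes <- rownames(x) %||% paste0("g", seq_len(nrow(x)))
    methods::new("GeneFit",
        genes = genes, log2FC = unname(m1 - m0),
        s2 = unname((ss1 + ss0) / df), df = rep(df, nrow(x)),
        stdevUnscaled = sqrt(1 / n1 + 1 / n0),
        nCase = as.integer(n1), nControl = as.integer(n0))
}

#' Empirical-Bayes moderation of per-gene variances
#'
#' Estimates a prior `(d0, s20)` for the residual variances by moment
#' matching on the log variances (digamma/trigamma inversion), forms the
#' posterior variance `(d0*s20 + df*s2) / (d0 + df)`, and recomputes
#' t-statistics against it with `d0 + df` degrees of freedom. An infinite
#' `d0` (log-variances less dispersed than chi-square sampling noise alone
#' predicts) collapses every posterior variance to `s20` and the reference
#' distribution to normal.
#'
#' Zero residual variances are floored at `varFloor` so the moment
#' equations stay finite; noiseless simulated genes therefore still
#' participate.
#'
#' @param fit A [GeneFit-class] object.
#' @param varFloor lower bound applied to residual variances.
#' @return A [ModeratedStats-class] object.
#' @export
moderateStatistics <- function(fit, varFloor = .Machine$double.eps) {
    stopifnot(methods::is(fit, "GeneFit"))
    if (length(fit@genes) < 2L) stop("need at least 2 genes to moderate")
    if (all(fit@s2 == 0))
        stop("all residual variances are zero: moderation is degenerate")
    s2 <- pmax(fit@s2, varFloor)
    df <- fit@df
    e <- log(s2) - digamma(df / 2) + log(df / 2)
    ebar <- mean(e)
    evar <- stats::var(e) - mean(trigamma(df / 2))
    if (is.finite(evar) && evar > 0) {
        d0 <- 2 * trigammaInverse(evar)
        s20 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
    } else {
        # log-variances no more dispersed than sampling noise alone: the
        # prior absorbs everything and the pooled mean variance is the limit
        d0 <- Inf
        s20 <- mean(s2)
    }
    s2Post <- if (is.finite(d0)) (d0 * s20 + df * s2) / (d0 + df) else rep(s20, length(s2))
    tstat <- fit@log2FC / (fit@stdevUnscaled * sqrt(s2Post))
    dfTotal <- d0 + df
    p <- 2 * stats::pt(-abs(tstat), df = dfTotal)
    tab <- data.frame(
        gene = fit@genes, log2FC = fit@log2FC, s2 = fit@s2,
        s2Post = s2Post, t = tstat, p = p, q = adjustBH(p),
        stringsAsFactors = FALSE)
    methods::new("ModeratedStats", table = tab, d0 = unname(d0),
                 s20 = unname(s20), dfResidual = df[1])
}

#' Benjamini-Hochberg adjustment
#'
#' Thin validated front end to `stats::p.adjust(method = "BH")`: step-up
#' adjusted p-values, clipped to 1, monotone in the rank order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of adjusted p-values, same order as `p`.
#' @export
adjustBH <- function(p) {
    if (!is.numeric(p)) stop("p must be numeric")
    if (any(!is.finite(p)) || any(p < 0 | p > 1))
        stop("all p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

#' Call differentially expressed genes
#'
#' Retains genes with BH-adjusted `q < alpha` and `|log2FC| > lfcThreshold`
#' (both strict) and labels the direction by the sign of the fold change.
#'
#' @param stats A [ModeratedStats-class] object.
#' @param lfcThreshold absolute log2 fold-change cut-off (default 2).
#' @param alpha adjusted-p cut-off (default 0.05).
#' @return data.frame with columns gene, log2FC, t, p, q, direction
#'   (`"up"`/`"down"`), sorted by q then p.
#' @export
callDEGs <- function(stats, lfcThreshold = 2, alpha = 0.05) {
    stopifnot(methods::is(stats, "ModeratedStats"))
    tab <- stats@table
    keep <- tab$q < alpha & abs(tab$log2FC) > lfcThreshold
    out <- tab[keep, c("gene", "log2FC", "t", "p", "q"), drop = FALSE]
    out$direction <- ifelse(out$log2FC > 0, "up", "down")
    out <- out[order(out$q, out$p), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Relative expression by the 2^-ddCt method
#'
#' Quantifies a target transcript relative to a reference gene and a
#' calibrator sample from qPCR cycle thresholds:
#' `ddCt = (ctTargetSample - ctRefSample) - (ctTargetCalibrator -
#' ctRefCalibrator)` and the fold change is `2^-ddCt`.
#'
#' @param ctTargetSample,ctRefSample Ct of target and reference gene in
#'   the sample of interest.
#' @param ctTargetCalibrator,ctRefCalibrator Ct of target and reference
#'   gene in the calibrator sample.
#' @return fold change(s), `2^-ddCt`.
#' @examples
#' ddctRelativeExpression(25, 20, 24, 20) # one extra cycle -> 0.5
#' @export
ddctRelativeExpression <- function(ctTargetSample, ctRefSample,
                                   ctTargetCalibrator, ctRefCalibrator) {
    ct <- c(ctTargetSample, ctRefSample, ctTargetCalibrator, ctRefCalibrator)
    if (any(!is.finite(ct))) stop("Ct values must be finite")
    ddct <- (ctTargetSample - ctRefSample) - (ctTargetCalibrator - ctRefCalibrator)
    2^(-ddct)
}
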