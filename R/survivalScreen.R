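#' Median split of expression values
#'
#' Labels samples `"high"` when strictly above the median and `"low"`
#' otherwise (ties go to the low group, so the split is deterministic).
#'
#' @param values numeric per-sample expression vector (named or not).
#' @return character vector of `"high"`/`"low"` labels parallel to
#'   `values`.
#' @export
medianSplit <- function(values) {
    if (length(values) < 4L) stop("median split needs at least 4 samples")
    if (any(!is.finite(values))) stop("values must be finite")
    med <- stats::median(values)
    lab <- ifelse(values > med, "high", "low")
    if (length(unique(lab)) < 2L)
        stop("degenerate split: all values on one side of the median")
    lab
}

#' Kaplan-Meier product-limit curve
#'
#' Survival estimate `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over the
#' distinct event times; times with only censorings leave the curve
#' unchanged (they only shrink the risk set).
#'
#' @param time positive follow-up times.
#' @param event 1 = death observed, 0 = right-censored.
#' @return data.frame with one row per distinct event time: time, nRisk,
#'   nEvent, survival.
#' @export
kmCurve <- function(time, event) {
    if (!length(time)) stop("empty survival table")
    if (any(!is.finite(time) | time <= 0)) stop("times must be positive")
    if (!all(event %in% c(0, 1))) stop("event must be 0/1")
    ut <- sort(unique(time[event == 1]))
    if (!length(ut))
        return(data.frame(time = numeric(), nRisk = integer(),
                          nEvent = integer(), survival = numeric()))
    nRisk <- vapply(ut, function(t) sum(time >= t), 0L)
    nEvent <- vapply(ut, function(t) sum(time == t & event == 1), 0L)
    data.frame(time = ut, nRisk = nRisk, nEvent = nEvent,
               survival = cumprod(1 - nEvent / nRisk))
}

#' Two-group log-rank test
#'
#' At each distinct event time the expected events in group 1 follow the
#' at-risk proportion and the variance is hypergeometric; the statistic
#' `(O1 - E1)^2 / V` is referred to chi-square on 1 df.
#'
#' @param time positive follow-up times.
#' @param event 1 = death, 0 = censored.
#' @param labels two-level group labels parallel to `time`.
#' @return list with elements statistic, p, observed (per-group event
#'   totals), expected (per-group expected totals).
#' @export
logrankTest <- function(time, event, labels) {
    labels <- as.character(labels)
    lev <- sort(unique(labels))
    if (length(lev) != 2L) stop("labels must have exactly two non-empty groups")
    if (any(!is.finite(time) | time <= 0)) stop("times must be positive")
    if (!all(event %in% c(0, 1))) stop("event must be 0/1")
    g1 <- labels == lev[1]
    ut <- sort(unique(time[event == 1]))
    O1 <- E1 <- V <- 0
    for (t in ut) {
        atRisk <- time >= t
        n <- sum(atRisk); n1 <- sum(atRisk & g1)
        d <- sum(time == t & event == 1)
        d1 <- sum(time == t & event == 1 & g1)
        O1 <- O1 + d1
        E1 <- E1 + d * n1 / n
        if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
    stat <- if (V > 0) (O1 - E1)^2 / V else 0
    totE <- sum(event == 1)
    list(statistic = stat,
         p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
         observed = stats::setNames(c(O1, totE - O1), lev),
         expected = stats::setNames(c(E1, totE - E1), lev))
}

# Restricted mean survival: area under the KM step function up to tmax.
.restrictedMean <- function(time, event, tmax) {
    km <- kmCurve(time, event)
    grid <- c(0, km$time[km$time <= tmax], tmax)
    surv <- c(1, km$survival[km$time <= tmax])
    sum(surv * diff(grid))
}

#' Median-split prognostic screening of candidate genes
#'
#' For each candidate gene the cohort is split at the median expression,
#' the two groups are compared by the log-rank test, and genes with
#' `p < alpha` are called prognostic. The direction is `"positive"` when
#' the high-expression group has the larger restricted mean survival over
#' the observed follow-up window (high expression associated with longer
#' survival), `"negative"` otherwise.
#'
#' @param clinical data.frame with columns sample, time, event.
#' @param exprMat genes x samples matrix of (log-scale) expression whose
#'   columns match `clinical$sample`.
#' @param genes character vector of genes to screen; genes absent from
#'   the matrix are skipped with a warning.
#' @param alpha log-rank p cut-off (strict; default 0.05).
#' @return data.frame with columns gene, p, direction for the retained
#'   genes, sorted by p. The full screen (all tested genes) is attached as
#'   attribute `"screen"`.
#' @export
screenPrognostic <- function(clinical, exprMat, genes, alpha = 0.05) {
    need <- c("sample", "time", "event")
    if (!all(need %in% names(clinical)))
        stop("clinical needs columns sample, time, event")
    exprMat <- as.matrix(exprMat)
    idx <- match(clinical$sample, colnames(exprMat))
    if (any(is.na(idx))) stop("clinical samples missing from the expression matrix")
    exprMat <- exprMat[, idx, drop = FALSE]
    missing <- setdiff(genes, rownames(exprMat))
    if (length(missing))
        warning("gene(s) absent from the expression matrix, skipped: ",
                paste(missing, collapse = ", "))
    genes <- intersect(genes, rownames(exprMat))
    rows <- lapply(genes, function(g) {
        lab <- tryCatch(medianSplit(exprMat[g, ]), error = function(e) NULL)
        if (is.null(lab)) {
            warning("degenerate median split for gene ", g, ", skipped")
            return(NULL)
        }
        lr <- logrankTest(clinical$time, clinical$event, lab)
        tmax <- max(clinical$time)
        rmHigh <- .restrictedMean(clinical$time[lab == "high"],
                                  clinical$event[lab == "high"], tmax)
        rmLow <- .restrictedMean(clinical$time[lab == "low"],
                                 clinical$event[lab == "low"], tmax)
        data.frame(gene = g, p = lr$p,
                   direction = if (rmHigh > rmLow) "positive" else "negative",
                   stringsAsFactors = FALSE)
    })
    screen <- do.call(rbind, rows)
    if (is.null(screen))
        screen <- data.frame(gene = character(), p = numeric(),
                             direction = character())
    out <- screen[screen$p < alpha, , drop = FALSE]
    out <- out[order(out$p), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "screen") <- screen
    out
}
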