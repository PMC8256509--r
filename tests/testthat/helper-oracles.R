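# Independent brute-force oracles used to freeze expected values.
# Each oracle is deliberately written along a different route than the
# package implementation it checks.

# Per-gene OLS via lm() on the group factor.
olsOracle <- function(x, groups) {
    f <- factor(groups, levels = c("control", "case"))
    out <- t(apply(x, 1, function(row) {
        m <- stats::lm(row ~ f)
        c(lfc = unname(stats::coef(m)[2]),
          s2 = sum(stats::residuals(m)^2) / m$df.residual)
    }))
    as.data.frame(out)
}

# Numeric root-finder solve of the log-variance moment equations.
momentSolveOracle <- function(s2, df, floor = .Machine$double.eps) {
    s2 <- pmax(s2, floor)
    e <- log(s2) - digamma(df / 2) + log(df / 2)
    target <- stats::var(e) - mean(trigamma(df / 2))
    if (!is.finite(target) || target <= 0)
        return(list(d0 = Inf, s20 = mean(s2)))
    root <- stats::uniroot(function(y) trigamma(y) - target,
                           lower = 1e-8, upper = 1e8, tol = 1e-12)$root
    d0 <- 2 * root
    list(d0 = d0, s20 = exp(mean(e) + digamma(d0 / 2) - log(d0 / 2)))
}

# Step-up BH by the direct min-over-larger-ranks definition.
bhOracle <- function(p) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    adj <- vapply(seq_len(m), function(i) min(1, min(m * ps[i:m] / (i:m))), 0)
    out <- numeric(m)
    out[o] <- adj
    out
}

# Hypergeometric upper tail by direct summation of the pmf.
hyperOracle <- function(k, K, n, N) {
    js <- k:min(K, n)
    sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Gaussian-kernel CDF by numeric quadrature of the kernel density.
kcdfQuadOracle <- function(xi) {
    h <- stats::sd(xi) / 4
    dens <- function(t) mean(stats::dnorm(t, mean = xi, sd = h))
    vapply(xi, function(v)
        stats::integrate(Vectorize(dens), -Inf, v,
                         rel.tol = 1e-10, abs.tol = 1e-12)$value, 0)
}

# Step-by-step random-walk ES for one sample: explicit loop over the
# ranked gene list, no cumsum shortcuts.
walkOracle <- function(zcol, genes, set, tau = 1) {
    N <- length(zcol)
    ord <- order(zcol, decreasing = TRUE)
    rnk <- integer(N); rnk[ord] <- seq_len(N)
    w <- abs(N / 2 - rnk)^tau
    inSet <- genes %in% set
    m <- sum(inSet)
    denom <- sum(w[inSet])
    if (denom == 0) { w <- rep(1, N); denom <- m }  # all-middle degenerate set
    v <- numeric(N); acc <- 0
    for (l in seq_len(N)) {
        gi <- ord[l]
        acc <- acc + if (inSet[gi]) w[gi] / denom else -1 / (N - m)
        v[l] <- acc
    }
    max(c(0, v)) - max(c(0, -v))
}

# Log-rank by building the full risk table as a data.frame first.
logrankOracle <- function(time, event, labels) {
    lev <- sort(unique(labels))
    tab <- do.call(rbind, lapply(sort(unique(time[event == 1])), function(t) {
        data.frame(t = t,
                   n = sum(time >= t),
                   n1 = sum(time >= t & labels == lev[1]),
                   d = sum(time == t & event == 1),
                   d1 = sum(time == t & event == 1 & labels == lev[1]))
    }))
    tab$e1 <- tab$d * tab$n1 / tab$n
    tab$v <- ifelse(tab$n > 1,
                    tab$d * (tab$n1 / tab$n) * (1 - tab$n1 / tab$n) *
                        (tab$n - tab$d) / (tab$n - 1), 0)
    stat <- (sum(tab$d1) - sum(tab$e1))^2 / sum(tab$v)
    list(statistic = stat,
         p = stats::pchisq(stat, 1, lower.tail = FALSE))
}

# Small deterministic survival fixture shared across tests.
survivalFixture8 <- function() {
    data.frame(
        time = c(2, 4, 4, 6, 8, 9, 12, 15),
        event = c(1, 1, 0, 1, 1, 0, 1, 1),
        group = c("a", "b", "a", "b", "a", "b", "a", "b"),
        stringsAsFactors = FALSE)
}

# A two-cluster barbell-style metabolic graph: two star clusters of
# compounds around separate reaction/pathway cores, joined by one bridge.
barbellGraph <- function(nPerSide = 8) {
    cIds <- sprintf("C%03d", seq_len(2 * nPerSide))
    nodes <- data.frame(
        id = c(cIds, "R001", "R002", "P01", "P02", "M01"),
        type = c(rep("compound", 2 * nPerSide), "reaction", "reaction",
                 "pathway", "pathway", "module"))
    left <- cIds[seq_len(nPerSide)]
    right <- cIds[-seq_len(nPerSide)]
    edges <- rbind(
        data.frame(source = left, target = "R001"),
        data.frame(source = right, target = "R002"),
        data.frame(source = c("R001", "R002", "P01", "P02"),
                   target = c("P01", "P02", "M01", "M01")))
    list(nodes = nodes, edges = edges, left = left, right = right)
}
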