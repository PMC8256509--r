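test_that("probe collapsing averages multi-probe genes and drops blanks", {
    pt <- data.frame(gene = c("A", "A", "B", "", NA),
                     s1 = c(1, 3, 7, 9, 9), s2 = c(3, 5, 8, 9, 9))
    out <- collapseProbes(pt)
    expect_equal(out["A", ], c(s1 = 2, s2 = 4))
    expect_equal(out["B", ], c(s1 = 7, s2 = 8))   # single probe unchanged
    expect_equal(rownames(out), c("A", "B"))      # blank symbols excluded
    expect_error(collapseProbes(pt[0, ]), "non-empty")
})

test_that("noiseless two-group fit recovers exact effect and zero variance", {
    x <- rbind(gA = c(rep(3.5, 19), rep(1, 4)))
    groups <- rep(c("case", "control"), c(19, 4))
    fit <- fitGeneModels(x, groups)
    expect_equal(fit@log2FC, 2.5)
    expect_equal(fit@s2, 0)
    expect_equal(fit@df, 21)
})

test_that("per-gene OLS matches the lm() oracle on random matrices", {
    set.seed(42)
    x <- matrix(rnorm(50 * 10), 50, 10,
                dimnames = list(sprintf("g%02d", 1:50), NULL))
    groups <- rep(c("case", "control"), each = 5)
    fit <- fitGeneModels(x, groups)
    orc <- olsOracle(x, groups)
    expect_equal(fit@log2FC, orc$lfc, tolerance = 1e-10)
    expect_equal(fit@s2, orc$s2, tolerance = 1e-10)
})

test_that("swapping group labels negates log2FC and keeps variances and p", {
    set.seed(7)
    x <- matrix(rnorm(30 * 8), 30, 8)
    g1 <- rep(c("case", "control"), each = 4)
    g2 <- rep(c("control", "case"), each = 4)
    f1 <- fitGeneModels(x, g1); f2 <- fitGeneModels(x, g2)
    expect_equal(f1@log2FC, -f2@log2FC)
    expect_equal(f1@s2, f2@s2)
    expect_equal(moderateStatistics(f1)@table$p, moderateStatistics(f2)@table$p)
})

test_that("moderation prior matches an independent numeric moment solve", {
    set.seed(99)
    x <- matrix(rnorm(80 * 10, sd = rep(runif(80, 0.5, 2), 10)), 80, 10)
    fit <- fitGeneModels(x, rep(c("case", "control"), each = 5))
    ms <- moderateStatistics(fit)
    orc <- momentSolveOracle(fit@s2, fit@df)
    expect_equal(priorDf(ms), orc$d0, tolerance = 1e-6)
    expect_equal(priorVar(ms), orc$s20, tolerance = 1e-6)
    # shrinkage: posterior variance lies between observed and prior variance
    tab <- statsTable(ms)
    expect_true(all(tab$s2Post >= pmin(tab$s2, priorVar(ms)) - 1e-12))
    expect_true(all(tab$s2Post <= pmax(tab$s2, priorVar(ms)) + 1e-12))
})

test_that("moderation agrees with the limma cross-check", {
    skip_if_not_installed("limma")
    set.seed(3)
    x <- matrix(rnorm(60 * 9), 60, 9)
    groups <- rep(c("case", "control"), c(5, 4))
    fit <- fitGeneModels(x, groups)
    ms <- moderateStatistics(fit)
    design <- cbind(1, as.numeric(groups == "case"))
    lf <- limma::eBayes(limma::lmFit(x, design))
    expect_equal(statsTable(ms)$log2FC, unname(lf$coefficients[, 2]),
                 tolerance = 1e-10)
    expect_equal(priorDf(ms), lf$df.prior, tolerance = 1e-6)
    expect_equal(priorVar(ms), lf$s2.prior, tolerance = 1e-6)
    expect_equal(statsTable(ms)$t, unname(lf$t[, 2]), tolerance = 1e-8)
    expect_equal(statsTable(ms)$p, unname(lf$p.value[, 2]), tolerance = 1e-8)
})

test_that("identical per-gene variances collapse the prior onto them", {
    fit <- methods::new("GeneFit", genes = paste0("g", 1:5),
                        log2FC = rnorm(5), s2 = rep(0.8, 5), df = rep(8, 5),
                        stdevUnscaled = sqrt(0.4), nCase = 5L, nControl = 5L)
    ms <- moderateStatistics(fit)
    expect_equal(priorVar(ms), 0.8, tolerance = 1e-6)
    expect_equal(statsTable(ms)$s2Post, rep(0.8, 5), tolerance = 1e-6)
})

test_that("all-zero variances raise the degenerate-moderation error", {
    fit <- methods::new("GeneFit", genes = c("a", "b"), log2FC = c(1, 2),
                        s2 = c(0, 0), df = c(4, 4), stdevUnscaled = 1,
                        nCase = 3L, nControl = 3L)
    expect_error(moderateStatistics(fit), "degenerate")
})

test_that("BH adjustment matches the step-up oracle and is permutation-stable", {
    expect_equal(adjustBH(0.03), 0.03)
    expect_equal(adjustBH(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    set.seed(10)
    p <- runif(200)
    expect_equal(adjustBH(p), bhOracle(p))
    perm <- sample(200)
    expect_equal(adjustBH(p[perm]), adjustBH(p)[perm])
    expect_error(adjustBH(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("DEG calling applies both thresholds strictly", {
    tab <- data.frame(
        gene = c("up", "atLfc", "atAlpha", "down"),
        log2FC = c(2.5, 2.0, 3.0, -2.6), s2 = 1, s2Post = 1,
        t = c(5, 4, 5, -5), p = c(1e-4, 1e-5, 1e-3, 1e-4),
        q = c(0.01, 0.001, 0.05, 0.01))
    ms <- methods::new("ModeratedStats", table = tab, d0 = 4, s20 = 1,
                       dfResidual = 8)
    degs <- callDEGs(ms)
    expect_setequal(degs$gene, c("up", "down"))
    expect_equal(degs$direction[degs$gene == "up"], "up")
    expect_equal(degs$direction[degs$gene == "down"], "down")
})

test_that("planted DE genes are recovered exactly in the noiseless case", {
    cfg <- simConfig(seed = 8L, nGenes = 300L, nDE = 40L, lfcEffect = 3,
                     noiseSd = 0)
    se <- simulateExpression(cfg)
    x <- SummarizedExperiment::assay(se)
    # tiny jitter so variances are positive but effects dwarf them
    set.seed(1); x <- x + matrix(rnorm(length(x), sd = 1e-4), nrow(x))
    ms <- moderateStatistics(fitGeneModels(x, SummarizedExperiment::colData(se)$group))
    degs <- callDEGs(ms)
    expect_setequal(degs$gene, names(S4Vectors::metadata(se)$deGenes))
})

test_that("pure-null simulations keep the DEG rate at or below nominal", {
    frac <- vapply(1:50, function(s) {
        cfg <- simConfig(seed = s, nGenes = 200L, nCase = 5L, nControl = 5L,
                         nDE = 0L, noiseSd = 1)
        se <- simulateExpression(cfg)
        ms <- moderateStatistics(
            fitGeneModels(SummarizedExperiment::assay(se),
                          SummarizedExperiment::colData(se)$group))
        nrow(callDEGs(ms)) / 200
    }, 0)
    expect_lte(mean(frac), 0.05)
})

test_that("the ddCt fold change follows its closed form", {
    expect_equal(ddctRelativeExpression(20, 18, 22, 20), 1.0)
    expect_equal(ddctRelativeExpression(25, 20, 24, 20), 0.5)
    expect_equal(ddctRelativeExpression(23, 20, 25, 20), 4.0)
    expect_error(ddctRelativeExpression(Inf, 20, 24, 20), "finite")
})
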