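test_that("simulated expression has the requested shape and planted effects", {
    cfg <- simConfig(seed = 1L, nGenes = 1000L, nDE = 40L, lfcEffect = 3)
    se <- simulateExpression(cfg)
    expect_equal(dim(se), c(1000L, 23L))
    expect_equal(as.vector(table(SummarizedExperiment::colData(se)$group)),
                 c(19L, 4L))
    de <- S4Vectors::metadata(se)$deGenes
    expect_length(de, 40L)
    expect_setequal(abs(de), 3)
})

test_that("noiseless generation plants group-mean differences exactly", {
    cfg <- simConfig(seed = 3L, nGenes = 50L, nDE = 6L, lfcEffect = 2.5,
                     noiseSd = 0)
    se <- simulateExpression(cfg)
    x <- SummarizedExperiment::assay(se)
    grp <- SummarizedExperiment::colData(se)$group
    diff <- rowMeans(x[, grp == "case"]) - rowMeans(x[, grp == "control"])
    de <- S4Vectors::metadata(se)$deGenes
    expect_equal(unname(diff[names(de)]), unname(de))
    expect_equal(unname(diff[setdiff(rownames(se), names(de))]),
                 rep(0, 44))
})

test_that("generators are deterministic in the configuration seed", {
    cfg <- simConfig(seed = 11L, nGenes = 60L, nDE = 4L,
                     nSamplesSurvival = 20L,
                     prognosticGenes = c(G0001 = 2))
    a <- simulateStudy(cfg)
    b <- simulateStudy(cfg)
    expect_identical(SummarizedExperiment::assay(a$expression),
                     SummarizedExperiment::assay(b$expression))
    expect_identical(SummarizedExperiment::colData(a$clinical),
                     SummarizedExperiment::colData(b$clinical))
    expect_identical(a$graph@edges, b$graph@edges)
    expect_identical(a$ppiEdges, b$ppiEdges)
    expect_identical(a$geneSets, b$geneSets)
})

test_that("zero censor rate yields all-event cohorts", {
    cfg <- simConfig(seed = 5L, nGenes = 20L, nDE = 2L, censorRate = 0,
                     prognosticGenes = c(G0001 = 2))
    clin <- simulateClinical(cfg, simulateExpression(cfg))
    expect_true(all(SummarizedExperiment::colData(clin)$event == 1L))
    expect_true(all(SummarizedExperiment::colData(clin)$time > 0))
})

test_that("a planted hazard ratio of 3 at n = 80 is detected with high power", {
    hits <- 0L
    for (s in 1:100) {
        cfg <- simConfig(seed = s, nGenes = 10L, nDE = 2L,
                         nSamplesSurvival = 80L,
                         prognosticGenes = c(G0001 = 3), censorRate = 0.3)
        clin <- simulateClinical(cfg, simulateExpression(cfg))
        cd <- SummarizedExperiment::colData(clin)
        lab <- medianSplit(SummarizedExperiment::assay(clin)["G0001", ])
        lr <- logrankTest(cd$time, cd$event, lab)
        if (lr$p < 0.05) hits <- hits + 1L
    }
    expect_gte(hits, 80L)
})

test_that("a unit hazard ratio gives null log-rank behaviour", {
    pv <- vapply(1:60, function(s) {
        cfg <- simConfig(seed = s, nGenes = 10L, nDE = 2L,
                         nSamplesSurvival = 60L,
                         prognosticGenes = c(G0001 = 1), censorRate = 0.2)
        clin <- simulateClinical(cfg, simulateExpression(cfg))
        cd <- SummarizedExperiment::colData(clin)
        lab <- medianSplit(SummarizedExperiment::assay(clin)["G0001", ])
        logrankTest(cd$time, cd$event, lab)$p
    }, 0)
    # roughly uniform: rejection at 5% should stay near its nominal rate
    expect_lte(mean(pv < 0.05), 0.15)
    expect_gt(mean(pv), 0.3)
})

test_that("the metabolic graph generator yields one connected typed graph", {
    cfg <- simConfig(seed = 2L,
                     graphSizes = c(compounds = 5L, reactions = 3L,
                                    enzymes = 2L, pathways = 1L, modules = 1L),
                     nAffectedCompounds = 2L)
    mg <- simulateMetabolicGraph(cfg)
    expect_equal(nrow(graphNodes(mg$graph)), 12L)
    expect_length(scoredNodes(mg$graph), 12L)  # single pathway-anchored component
    expect_length(excludedComponents(mg$graph), 0L)
    expect_setequal(unique(graphNodes(mg$graph)$type),
                    c("compound", "reaction", "enzyme", "pathway", "module"))
    g <- igraph::graph_from_data_frame(graphEdges(mg$graph), directed = FALSE)
    expect_equal(igraph::components(g)$no, 1L)
})

test_that("invalid configurations are rejected", {
    expect_error(simConfig(nGenes = 0L), "positive")
    expect_error(simConfig(nDE = 50L, nGenes = 10L), "nDE")
    expect_error(simConfig(censorRate = 1.5), "censorRate")
    expect_error(simConfig(graphSizes = c(compounds = 5L, reactions = 3L,
                                          enzymes = 1L, pathways = 0L,
                                          modules = 1L)))
})

test_that("association tables honour the overlap fraction at the extremes", {
    cfg1 <- simConfig(seed = 4L, nGenes = 80L, nDE = 10L, overlapFraction = 1)
    st1 <- simulateStudy(cfg1)
    degs <- data.frame(gene = names(st1$truth@deGenes),
                       direction = ifelse(st1$truth@deGenes > 0, "up", "down"))
    net <- buildPPI(st1$ppiEdges, degs, minScore = 0.7)
    fg <- featureGenes(net, st1$diseaseTableA, st1$diseaseTableB)
    # full overlap: the three-way intersection is the whole PPI node set
    expect_setequal(fg$gene[fg$feature], graphNodes(net)$gene)
    expect_gt(sum(fg$feature), 0)

    cfg0 <- simConfig(seed = 4L, nGenes = 80L, nDE = 10L, overlapFraction = 0)
    st0 <- simulateStudy(cfg0)
    fg0 <- featureGenes(buildPPI(st0$ppiEdges, degs, minScore = 0.7),
                        st0$diseaseTableA, st0$diseaseTableB)
    expect_equal(sum(fg0$feature), 0L)
})

test_that("written study bundles describe the generated objects exactly", {
    cfg <- simConfig(seed = 6L, nGenes = 40L, nDE = 4L,
                     nSamplesSurvival = 15L,
                     prognosticGenes = c(G0001 = 2),
                     graphSizes = c(compounds = 10L, reactions = 6L,
                                    enzymes = 3L, pathways = 2L, modules = 1L),
                     nAffectedCompounds = 2L)
    st <- simulateStudy(cfg)
    d <- withr::local_tempdir()
    files <- writeStudy(st, d)
    expect_true(all(file.exists(files)))
    x <- readTableChecked(files[["expression.tsv"]])
    expect_equal(x$gene, rownames(st$expression))
    expect_equal(as.matrix(x[, -1]),
                 SummarizedExperiment::assay(st$expression),
                 ignore_attr = TRUE)
    truth <- jsonlite::read_json(files[["truth.json"]], simplifyVector = TRUE)
    expect_setequal(truth$affectedCompounds, st$truth@affectedCompounds)
    expect_equal(truth$keyCompound, st$truth@keyCompound)
    expect_equal(unlist(truth$deGenes), st$truth@deGenes)
})
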