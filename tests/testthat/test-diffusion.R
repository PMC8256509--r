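tinyGraph <- function() {
    nodes <- data.frame(id = c("C1", "R1", "P1"),
                        type = c("compound", "reaction", "pathway"))
    edges <- data.frame(source = c("C1", "R1"), target = c("R1", "P1"))
    buildMetabolicGraph(nodes, edges)
}

test_that("graph building validates typology and edge endpoints", {
    g <- tinyGraph()
    expect_length(scoredNodes(g), 3L)
    expect_error(buildMetabolicGraph(
        data.frame(id = "X", type = "mystery"),
        data.frame(source = character(), target = character())), "unknown node type")
    expect_error(buildMetabolicGraph(
        data.frame(id = c("C1", "R1"), type = c("compound", "reaction")),
        data.frame(source = "C1", target = "GHOST")), "GHOST")
    expect_error(buildMetabolicGraph(
        data.frame(id = c("C1", "R1"), type = c("compound", "reaction")),
        data.frame(source = "C1", target = "C1")), "self-loop")
})

test_that("pathway-free components are excluded from scoring with a warning", {
    nodes <- data.frame(id = c("C1", "R1", "P1", "C2", "R2"),
                        type = c("compound", "reaction", "pathway",
                                 "compound", "reaction"))
    edges <- data.frame(source = c("C1", "R1", "C2"),
                        target = c("R1", "P1", "R2"))
    expect_warning(g <- buildMetabolicGraph(nodes, edges), "without a pathway")
    expect_setequal(scoredNodes(g), c("C1", "R1", "P1"))
    expect_equal(excludedComponents(g), list(c("C2", "R2")))
})

test_that("the conductance system matches hand matrices and is positive definite", {
    # single pathway node, no edges
    g1 <- buildMetabolicGraph(data.frame(id = "P1", type = "pathway"),
                              data.frame(source = character(),
                                         target = character()))
    s1 <- conductanceSystem(g1)
    expect_equal(as.matrix(s1@KI), matrix(1, 1, 1), ignore_attr = TRUE)

    # path compound - reaction - pathway
    s <- conductanceSystem(tinyGraph())
    L <- matrix(c(1, -1, 0, -1, 2, -1, 0, -1, 1), 3, 3, byrow = TRUE)
    expect_equal(as.matrix(s@L), L, ignore_attr = TRUE)
    expect_equal(Matrix::diag(s@B), c(0, 0, 1))
    expect_equal(as.matrix(s@KI), L + diag(c(0, 0, 1)), ignore_attr = TRUE)
    expect_equal(unname(Matrix::rowSums(s@L)), rep(0, 3))

    cfg <- simConfig(seed = 41L)
    mg <- simulateMetabolicGraph(cfg)
    KI <- as.matrix(conductanceSystem(mg$graph)@KI)
    expect_gt(min(eigen(KI, symmetric = TRUE, only.values = TRUE)$values), 0)
})

test_that("diffusion solves the conductance system to tight residuals", {
    s <- conductanceSystem(tinyGraph())
    expect_equal(unname(diffusionScores(s, c(0, 0, 0))), rep(0, 3))
    g1 <- conductanceSystem(buildMetabolicGraph(
        data.frame(id = "P1", type = "pathway"),
        data.frame(source = character(), target = character())))
    expect_equal(unname(diffusionScores(g1, 1)), 1)

    cfg <- simConfig(seed = 43L,
                     graphSizes = c(compounds = 20L, reactions = 12L,
                                    enzymes = 5L, pathways = 3L, modules = 2L),
                     nAffectedCompounds = 2L)
    mg <- simulateMetabolicGraph(cfg)
    sys <- conductanceSystem(mg$graph)
    gvec <- as.numeric(sys@ids %in% mg$affectedCompounds)
    tv <- diffusionScores(sys, gvec)
    dense <- solve(as.matrix(sys@KI)) %*% gvec     # dense-inverse oracle
    expect_equal(unname(tv), as.vector(dense), tolerance = 1e-8)
    resid <- sqrt(sum((as.matrix(sys@KI) %*% unname(tv) - gvec)^2)) /
        sqrt(sum(gvec^2))
    expect_lt(resid, 1e-10)
})

test_that("heat stays local: the affected cluster runs hotter", {
    bb <- barbellGraph()
    g <- buildMetabolicGraph(bb$nodes, bb$edges)
    sys <- conductanceSystem(g)
    tv <- diffusionScores(sys, bb$left[1:4])
    expect_gt(mean(tv[bb$left]), mean(tv[bb$right]))
})

test_that("permutation p-values respect the add-one floor and determinism", {
    bb <- barbellGraph()
    g <- buildMetabolicGraph(bb$nodes, bb$edges)
    sc1 <- permutationPvalues(g, bb$left[1:2], nPerm = 10, seed = 5)
    expect_gte(min(scoresTable(sc1)$p), 1 / 11)
    expect_lte(max(scoresTable(sc1)$p), 1)
    sc2 <- permutationPvalues(g, bb$left[1:2], nPerm = 10, seed = 5)
    expect_identical(scoresTable(sc1), scoresTable(sc2))
    expect_error(permutationPvalues(g, "P01", nPerm = 10, seed = 1),
                 "compound")
    expect_error(permutationPvalues(g, bb$left[1:2], nPerm = 10),
                 "seed")
})

test_that("p-values depend only on score ranks, not the solve convention", {
    # recompute p with the identical null draws under a flipped/scaled
    # convention T' = -3 T; the exceedance counts must be unchanged
    bb <- barbellGraph()
    g <- buildMetabolicGraph(bb$nodes, bb$edges)
    sys <- conductanceSystem(g)
    pool <- sys@ids[graphNodes(g)$type[match(sys@ids, graphNodes(g)$id)] == "compound"]
    tObs <- diffusionScores(sys, bb$left[1:2])
    W <- apply(diag(length(sys@ids))[, match(pool, sys@ids)], 2,
               function(e) as.numeric(Matrix::solve(sys@KI, e)))
    set.seed(77); ex1 <- 0
    for (b in 1:200) { idx <- sample.int(length(pool), 2)
        ex1 <- ex1 + (rowSums(W[, idx]) >= tObs) }
    set.seed(77); ex2 <- 0
    for (b in 1:200) { idx <- sample.int(length(pool), 2)
        ex2 <- ex2 + (-3 * rowSums(W[, idx]) <= -3 * tObs) }
    expect_identical(ex1, ex2)
})

test_that("significant subnetworks apply the strict threshold", {
    bb <- barbellGraph()
    g <- buildMetabolicGraph(bb$nodes, bb$edges)
    sc <- permutationPvalues(g, bb$left[1:2], nPerm = 19, seed = 3)
    tab <- scoresTable(sc)
    tab$p <- rep(1, nrow(tab))
    scAll1 <- methods::new("DiffusionScores", table = tab, nPerm = 19L,
                           seed = 3L)
    expect_equal(nrow(graphNodes(significantSubnetwork(g, scAll1))), 0L)
    tab$p <- rep(0.05, nrow(tab))
    scBound <- methods::new("DiffusionScores", table = tab, nPerm = 19L,
                            seed = 3L)
    expect_equal(nrow(graphNodes(significantSubnetwork(g, scBound))), 0L)
    sub <- significantSubnetwork(g, sc, alpha = 0.5)
    keep <- scoresTable(sc)$node[scoresTable(sc)$p < 0.5]
    expect_setequal(graphNodes(sub)$id, keep)
    e <- graphEdges(sub)
    expect_true(all(e$source %in% keep & e$target %in% keep))
})

test_that("the disease network overlays DEG-compound edges correctly", {
    nodes <- data.frame(id = c("C1", "C2", "R1", "P1"),
                        type = c("compound", "compound", "reaction", "pathway"))
    edges <- data.frame(source = c("C1", "C2", "R1"),
                        target = c("R1", "R1", "P1"))
    g <- buildMetabolicGraph(nodes, edges)
    tab <- data.frame(node = c("C1", "C2", "R1", "P1"),
                      type = nodes$type, score = 1:4,
                      p = c(0.01, 0.2, 0.01, 0.01))
    sc <- methods::new("DiffusionScores", table = tab, nPerm = 100L, seed = 1L)
    sub <- significantSubnetwork(g, sc)        # C2 not retained
    degs <- data.frame(gene = sprintf("G%d", 1:7),
                       direction = rep_len(c("up", "down"), 7))
    cg <- data.frame(compound = c(rep("C1", 6), "C2"),
                     gene = sprintf("G%d", 1:7))
    dmn <- assembleDiseaseNetwork(sub, cg, degs)
    cc <- compoundCounts(dmn)
    expect_equal(cc$nGenes[cc$compound == "C1"], 6L)
    expect_false("C2" %in% graphNodes(dmn)$id)
    expect_false("G7" %in% graphNodes(dmn)$id)  # only linked to non-retained C2
    ov <- graphEdges(dmn)[graphEdges(dmn)$kind == "overlay", ]
    expect_equal(nrow(ov), 6L)
    expect_true(all(ov$target == "C1"))
    # empty interaction table: subnet unchanged, zero counts
    dmn0 <- assembleDiseaseNetwork(sub, cg[0, ], degs)
    expect_equal(sum(compoundCounts(dmn0)$nGenes), 0L)
    expect_equal(nrow(graphNodes(dmn0)), 3L)
})

test_that("key metabolites rank by count, then p, then id", {
    dmn <- methods::new("DiseaseMetabolicNetwork",
        nodes = data.frame(id = character(), type = character(),
                           direction = character(), p = numeric()),
        edges = data.frame(source = character(), target = character(),
                           kind = character()),
        compoundCounts = data.frame(
            compound = c("Cb", "Ca", "Cc", "Cd"),
            nGenes = c(1L, 6L, 1L, 1L),
            p = c(0.02, 0.001, 0.001, 0.02)))
    rk <- rankKeyMetabolites(dmn)
    expect_equal(rk$compound, c("Ca", "Cc", "Cb", "Cd"))
    empty <- methods::new("DiseaseMetabolicNetwork",
        nodes = data.frame(id = character(), type = character(),
                           direction = character(), p = numeric()),
        edges = data.frame(source = character(), target = character(),
                           kind = character()),
        compoundCounts = data.frame(compound = character(),
                                    nGenes = integer(), p = numeric()))
    expect_equal(nrow(rankKeyMetabolites(empty)), 0L)
})

test_that("compound-id mapping is case-insensitive and reports misses", {
    map <- data.frame(name = c("Bisphenol A", "Cyclophosphamide"),
                      compoundId = c("C13624", "C07888"))
    got <- mapCompoundIds(c("bisphenol a", "BISPHENOL A", "unknownium"), map)
    expect_equal(got$ids, "C13624")             # duplicates deduplicated
    expect_equal(got$unmapped, "unknownium")
    empty <- mapCompoundIds(character(), map)
    expect_length(empty$ids, 0L)
    expect_length(empty$unmapped, 0L)
})
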