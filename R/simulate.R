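#' Construct a simulation configuration
#'
#' Defaults emulate the study conditions the package targets: a 19 case
#' vs 4 control expression contrast (the cell-line vs normal-bone design),
#' 40 planted DE genes at |log2FC| = 3 with unit Gaussian noise, an
#' 80-sample survival cohort with two planted prognostic genes (hazard
#' ratios 3 and 1/3 for the high-expression group), 30% censoring, and a
#' connected typed metabolic graph with 3 planted affected compounds.
#'
#' Gene identifiers are `G0001 ... G<nGenes>`; the planted DE genes are
#' the first `nDE`, alternating up/down. Every generator is a pure
#' function of the configuration: the same configuration reproduces the
#' same data byte for byte. The generators draw from seed offsets
#' (`seed`, `seed+1`, ...) so each stage has an independent stream.
#'
#' @param seed master RNG seed.
#' @param nGenes,nCase,nControl,nDE design counts.
#' @param lfcEffect planted absolute log2 fold change.
#' @param noiseSd Gaussian noise s.d. (log2 units).
#' @param nSamplesSurvival survival-cohort size.
#' @param prognosticGenes named numeric vector of hazard ratios; names
#'   must be gene ids (default hazard ratio 3 on G0001, 1/3 on G0002).
#' @param censorRate expected censored fraction in `[0, 1]`.
#' @param graphSizes named integer vector (compounds, reactions, enzymes,
#'   pathways, modules).
#' @param nAffectedCompounds planted hot compounds.
#' @param overlapFraction fraction of DE genes included in each
#'   disease-association table.
#' @return A validated [SimConfig-class] object.
#' @export
simConfig <- function(seed = 1L, nGenes = 1000L, nCase = 19L, nControl = 4L,
                      nDE = 40L, lfcEffect = 3, noiseSd = 1,
                      nSamplesSurvival = 80L,
                      prognosticGenes = c(G0001 = 3, G0002 = 1 / 3),
                      censorRate = 0.3,
                      graphSizes = c(compounds = 80L, reactions = 50L,
                                     enzymes = 15L, pathways = 5L,
                                     modules = 2L),
                      nAffectedCompounds = 3L, overlapFraction = 0.8) {
    methods::new("SimConfig",
        seed = as.integer(seed), nGenes = as.integer(nGenes),
        nCase = as.integer(nCase), nControl = as.integer(nControl),
        nDE = as.integer(nDE), lfcEffect = as.numeric(lfcEffect),
        noiseSd = as.numeric(noiseSd),
        nSamplesSurvival = as.integer(nSamplesSurvival),
        prognosticGenes = prognosticGenes,
        censorRate = as.numeric(censorRate),
        graphSizes = stats::setNames(as.integer(graphSizes), names(graphSizes)),
        nAffectedCompounds = as.integer(nAffectedCompounds),
        overlapFraction = as.numeric(overlapFraction))
}

.geneIds <- function(n) sprintf("G%04d", seq_len(n))

#' Simulate a two-group log2 expression matrix with planted DE genes
#'
#' Per-gene base means are uniform on `[4, 10]` log2 units; the planted DE
#' genes (the first `nDE`, alternating signs) have their case-group mean
#' shifted by `+/- lfcEffect`; i.i.d. Gaussian noise with s.d. `noiseSd`
#' is added everywhere. With `noiseSd = 0` the group-mean differences are
#' exactly `+/- lfcEffect` at planted genes and 0 elsewhere.
#'
#' @param config A [SimConfig-class] object.
#' @return A `SummarizedExperiment` (assay `"log2expr"`, `colData$group`
#'   in case/control); the planted signed effects are stored in
#'   `metadata(.)$deGenes` as a named numeric vector.
#' @export
simulateExpression <- function(config) {
    methods::validObject(config)
    genes <- .geneIds(config@nGenes)
    nS <- config@nCase + config@nControl
    samples <- c(sprintf("case_%02d", seq_len(config@nCase)),
                 sprintf("ctrl_%02d", seq_len(config@nControl)))
    groups <- rep(c("case", "control"), c(config@nCase, config@nControl))
    de <- if (config@nDE > 0)
        stats::setNames(config@lfcEffect *
                        rep_len(c(1, -1), config@nDE), genes[seq_len(config@nDE)])
    else stats::setNames(numeric(), character())
    x <- withSeed(config@seed, {
        base <- stats::runif(config@nGenes, 4, 10)
        m <- matrix(base, config@nGenes, nS) +
            matrix(stats::rnorm(config@nGenes * nS, sd = config@noiseSd),
                   config@nGenes, nS)
        m[match(names(de), genes), groups == "case"] <-
            m[match(names(de), genes), groups == "case"] + de
        m
    })
    dimnames(x) <- list(genes, samples)
    SummarizedExperiment::SummarizedExperiment(
        assays = list(log2expr = x),
        colData = S4Vectors::DataFrame(group = groups, row.names = samples),
        metadata = list(deGenes = de))
}

#' Simulate a right-censored survival cohort with planted prognostic genes
#'
#' A separate cohort (TARGET-like `log2(fpkm+1)` scale) is generated over
#' the same gene universe as `expr`. Event times are exponential with a
#' multiplicative hazard: the baseline rate gives a 36-month median
#' survival, multiplied by each planted gene's hazard ratio when the
#' sample sits above that gene's median expression. Each subject is
#' independently censored with probability `censorRate`, at a uniform
#' time before its event.
#'
#' @param config A [SimConfig-class] object.
#' @param expr SummarizedExperiment from [simulateExpression()] (supplies
#'   the gene universe).
#' @return A `SummarizedExperiment` with assay `"log2fpkm"` and
#'   `colData` columns `time` (months) and `event` (1 = death,
#'   0 = censored).
#' @export
simulateClinical <- function(config, expr) {
    if (config@nSamplesSurvival < 10L)
        stop("the survival cohort needs at least 10 samples")
    genes <- rownames(expr)
    bad <- setdiff(names(config@prognosticGenes), genes)
    if (length(bad))
        stop("prognostic gene(s) not in the expression universe: ",
             paste(bad, collapse = ", "))
    nS <- config@nSamplesSurvival
    samples <- sprintf("surv_%03d", seq_len(nS))
    out <- withSeed(config@seed + 1L, {
        base <- stats::runif(length(genes), 1, 8)
        x <- matrix(base, length(genes), nS) +
            matrix(stats::rnorm(length(genes) * nS), length(genes), nS)
        dimnames(x) <- list(genes, samples)
        lambda0 <- log(2) / 36  # 36-month baseline median survival
        logHr <- rep(0, nS)
        for (g in names(config@prognosticGenes)) {
            high <- x[g, ] > stats::median(x[g, ])
            logHr <- logHr + high * log(config@prognosticGenes[[g]])
        }
        tEvent <- stats::rexp(nS, rate = lambda0 * exp(logHr))
        cens <- stats::rbinom(nS, 1L, config@censorRate) == 1L
        time <- ifelse(cens, stats::runif(nS) * tEvent, tEvent)
        list(x = x, time = time, event = as.integer(!cens))
    })
    SummarizedExperiment::SummarizedExperiment(
        assays = list(log2fpkm = out$x),
        colData = S4Vectors::DataFrame(time = out$time, event = out$event,
                                       row.names = samples))
}

#' Simulate a connected typed metabolic graph with planted hot compounds
#'
#' KEGG-style typology: compounds attach to reactions, reactions to
#' pathways and enzymes, pathways to modules. Every reaction carries a
#' pathway edge and every module links back to the first pathway, so the
#' graph is one connected component anchored by pathway nodes (keeping
#' the conductance matrix non-singular). The planted affected compounds
#' (the first `nAffectedCompounds`) all attach to reactions of the first
#' pathway, forming a "hot" cluster around it.
#'
#' @param config A [SimConfig-class] object.
#' @return list with elements `graph` (a [MetabolicGraph-class]),
#'   `affectedCompounds` (character ids), `keyCompound` (character(1)).
#' @export
simulateMetabolicGraph <- function(config) {
    gs <- config@graphSizes
    nC <- gs[["compounds"]]; nR <- gs[["reactions"]]; nE <- gs[["enzymes"]]
    nP <- gs[["pathways"]]; nM <- gs[["modules"]]
    cIds <- sprintf("C%03d", seq_len(nC)); rIds <- sprintf("R%03d", seq_len(nR))
    eIds <- sprintf("E%03d", seq_len(nE)); pIds <- sprintf("P%02d", seq_len(nP))
    mIds <- sprintf("M%02d", seq_len(nM))
    nAff <- config@nAffectedCompounds
    edges <- withSeed(config@seed + 3L, {
        # reaction -> pathway; the first few reactions anchor the hot pathway
        pw <- sample.int(nP, nR, replace = TRUE)
        pw[seq_len(min(3L, nR))] <- 1L
        hot <- which(pw == 1L)
        src <- rIds; tgt <- pIds[pw]
        # compounds -> reactions; affected compounds cluster on hot reactions
        for (i in seq_len(nC)) {
            rs <- if (i <= nAff) unique(c(hot[1], sample(hot, 1)))
                  else unique(sample.int(nR, sample(1:2, 1)))
            src <- c(src, rep(cIds[i], length(rs))); tgt <- c(tgt, rIds[rs])
        }
        for (i in seq_len(nE)) {
            rs <- unique(sample.int(nR, sample(1:2, 1)))
            src <- c(src, rep(eIds[i], length(rs))); tgt <- c(tgt, rIds[rs])
        }
        src <- c(src, pIds, mIds)
        tgt <- c(tgt, mIds[((seq_len(nP) - 1L) %% nM) + 1L], rep(pIds[1], nM))
        data.frame(source = src, target = tgt, stringsAsFactors = FALSE)
    })
    edges <- edges[!duplicated(edgeKey(edges$source, edges$target)), , drop = FALSE]
    rownames(edges) <- NULL
    nodes <- data.frame(
        id = c(cIds, rIds, eIds, pIds, mIds),
        type = rep(c("compound", "reaction", "enzyme", "pathway", "module"),
                   c(nC, nR, nE, nP, nM)),
        stringsAsFactors = FALSE)
    graph <- buildMetabolicGraph(nodes, edges)
    if (length(graph@excluded))
        stop("graph generation produced a pathway-free component; enlarge graphSizes")
    list(graph = graph, affectedCompounds = cIds[seq_len(nAff)],
         keyCompound = cIds[1])
}

#' Simulate PPI, disease-association, compound-gene and id-mapping tables
#'
#' Emulates the downloaded resources of the integrated analysis: a scored
#' STRING-like PPI edge list (dense among DE genes, sparse elsewhere), two
#' disease-gene tables (CTD/GeneCards-like) overlapping the planted DE set
#' by `overlapFraction` and always containing the planted prognostic
#' genes when the overlap is positive, a CTD-like compound-gene table in
#' chemical names whose first chemical (the planted key metabolite) links
#' to six DEGs, and a name-to-compound-id mapping in which only some
#' chemicals resolve — and of those, only the planted affected compounds
#' exist in the metabolic graph.
#'
#' @param config A [SimConfig-class] object.
#' @param truth A [GroundTruth-class] object (from [simulateStudy()]'s
#'   earlier stages) holding DE genes, prognostic genes and affected
#'   compounds.
#' @return list with elements `ppiEdges`, `diseaseTableA`,
#'   `diseaseTableB`, `compoundGeneTable`, `mappingTable`.
#' @export
simulateAssociationTables <- function(config, truth) {
    deGenes <- names(truth@deGenes)
    allGenes <- .geneIds(config@nGenes)
    nonDE <- setdiff(allGenes, deGenes)
    prog <- names(truth@prognosticGenes)
    withSeed(config@seed + 2L, {
        # PPI: dense high-confidence edges among DE genes, noisy background
        pairs <- if (length(deGenes) >= 2) t(utils::combn(deGenes, 2)) else
            matrix(character(), 0, 2)
        keep <- stats::runif(nrow(pairs)) < 0.25
        ppi <- data.frame(geneA = pairs[keep, 1], geneB = pairs[keep, 2],
                          score = round(stats::runif(sum(keep), 0.5, 1), 3),
                          stringsAsFactors = FALSE)
        for (g in prog) {  # planted prognostic genes always well connected
            partners <- utils::head(setdiff(deGenes, g), 2)
            ppi <- rbind(ppi, data.frame(geneA = g, geneB = partners,
                                         score = 0.9))
        }
        bg <- data.frame(geneA = sample(nonDE, 60, replace = TRUE),
                         geneB = sample(allGenes, 60, replace = TRUE),
                         score = round(stats::runif(60), 3),
                         stringsAsFactors = FALSE)
        ppi <- rbind(ppi, bg[bg$geneA != bg$geneB, ])
        rownames(ppi) <- NULL

        nOv <- round(config@overlapFraction * length(deGenes))
        mkTable <- function() {
            core <- if (nOv > 0) unique(c(prog, sample(deGenes, nOv))) else character()
            sort(unique(c(core, sample(nonDE, 20))))
        }
        tabA <- mkTable(); tabB <- mkTable()

        # chemicals: the first is the key metabolite, wired to 6 DEGs; every
        # chemical that resolves to a planted affected compound must carry a
        # prognostic-gene link so the discovery chain can seed the diffusion
        chems <- sprintf("chem%02d", 1:10)
        nAff <- length(truth@affectedCompounds)
        keyGenes <- utils::head(unique(c(prog, deGenes)), 6)
        cg <- data.frame(compound = "chem01", gene = keyGenes,
                         stringsAsFactors = FALSE)
        for (i in seq_along(chems)[-1]) {
            g <- if (i <= nAff && length(prog)) sample(prog, 1)
                 else sample(unique(c(prog, deGenes)), sample(1:2, 1))
            cg <- rbind(cg, data.frame(compound = chems[i], gene = g,
                                       stringsAsFactors = FALSE))
        }
        rownames(cg) <- NULL
        # mapping: affected compounds first, then ids absent from the graph
        nAff <- length(truth@affectedCompounds)
        mapped <- chems[seq_len(min(5L, length(chems)))]
        ids <- c(truth@affectedCompounds,
                 sprintf("CX%02d", seq_len(max(0L, length(mapped) - nAff))))
        mapping <- data.frame(name = mapped, compoundId = ids[seq_along(mapped)],
                              stringsAsFactors = FALSE)
        list(ppiEdges = ppi, diseaseTableA = tabA, diseaseTableB = tabB,
             compoundGeneTable = cg, mappingTable = mapping)
    })
}

#' Simulate a gene-set collection with planted enriched sets
#'
#' Two planted sets collect the up- and down-regulated DE genes (plus a
#' few bystanders); the remaining sets are size-15 random draws from the
#' gene universe. Written/read as standard GMT.
#'
#' @param config A [SimConfig-class] object.
#' @param nNullSets number of random background sets (default 20).
#' @return named list of character vectors.
#' @export
simulateGeneSets <- function(config, nNullSets = 20L) {
    genes <- .geneIds(config@nGenes)
    de <- genes[seq_len(config@nDE)]
    up <- de[rep_len(c(TRUE, FALSE), length(de))]
    down <- setdiff(de, up)
    withSeed(config@seed + 4L, {
        sets <- list(
            KEGG_PLANTED_UP = unique(c(up, sample(setdiff(genes, de), 5))),
            KEGG_PLANTED_DOWN = unique(c(down, sample(setdiff(genes, de), 5))))
        for (i in seq_len(nNullSets))
            sets[[sprintf("KEGG_SYNTH_SET_%02d", i)]] <- sample(genes, 15)
        sets
    })
}

#' Simulate a complete synthetic study
#'
#' Runs every generator in order (expression, clinical cohort, metabolic
#' graph, association tables, gene sets) and assembles the planted ground
#' truth. This is the bundle [runPipeline()] consumes after
#' [writeStudy()].
#'
#' @param config A [SimConfig-class] object.
#' @return list with elements `expression`, `clinical` (both
#'   SummarizedExperiment), `graph`, `ppiEdges`, `diseaseTableA`,
#'   `diseaseTableB`, `compoundGeneTable`, `mappingTable`, `geneSets`,
#'   and `truth` (a [GroundTruth-class]).
#' @export
simulateStudy <- function(config) {
    expr <- simulateExpression(config)
    clinical <- simulateClinical(config, expr)
    mg <- simulateMetabolicGraph(config)
    truth <- methods::new("GroundTruth",
        deGenes = S4Vectors::metadata(expr)$deGenes,
        prognosticGenes = config@prognosticGenes,
        affectedCompounds = mg$affectedCompounds,
        keyCompound = mg$keyCompound)
    tabs <- simulateAssociationTables(config, truth)
    c(list(expression = expr, clinical = clinical, graph = mg$graph,
           geneSets = simulateGeneSets(config), truth = truth), tabs)
}

#' Write a simulated study bundle to disk
#'
#' Emits the plain-text inputs the pipeline reads: expression and groups
#' TSV, clinical and survival-expression TSV, PPI edges, disease gene
#' lists, compound-gene and mapping tables, graph node/edge TSV, a GMT
#' collection, and the planted truth as JSON.
#'
#' @param study list from [simulateStudy()].
#' @param dir output directory (created if absent).
#' @return invisibly, the named vector of written file paths.
#' @export
writeStudy <- function(study, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(dir, f)
    x <- SummarizedExperiment::assay(study$expression)
    writeTableChecked(data.frame(gene = rownames(x), x, check.names = FALSE),
                      p("expression.tsv"))
    writeTableChecked(data.frame(
        sample = colnames(study$expression),
        group = SummarizedExperiment::colData(study$expression)$group),
        p("groups.tsv"))
    cs <- SummarizedExperiment::assay(study$clinical)
    writeTableChecked(data.frame(gene = rownames(cs), cs, check.names = FALSE),
                      p("survival_expression.tsv"))
    cd <- SummarizedExperiment::colData(study$clinical)
    writeTableChecked(data.frame(sample = rownames(cd), time = cd$time,
                                 event = cd$event), p("clinical.tsv"))
    writeTableChecked(study$ppiEdges, p("ppi_edges.tsv"))
    writeTableChecked(data.frame(gene = study$diseaseTableA), p("disease_genes_a.tsv"))
    writeTableChecked(data.frame(gene = study$diseaseTableB), p("disease_genes_b.tsv"))
    writeTableChecked(study$compoundGeneTable, p("compound_gene.tsv"))
    writeTableChecked(study$mappingTable, p("mapping.tsv"))
    writeTableChecked(study$graph@nodes, p("graph_nodes.tsv"))
    writeTableChecked(study$graph@edges, p("graph_edges.tsv"))
    writeGMT(study$geneSets, p("gene_sets.gmt"))
    truth <- study$truth
    jsonlite::write_json(list(
        deGenes = as.list(truth@deGenes),
        prognosticGenes = as.list(truth@prognosticGenes),
        affectedCompounds = truth@affectedCompounds,
        keyCompound = truth@keyCompound), p("truth.json"), auto_unbox = TRUE,
        digits = NA)
    files <- c("expression.tsv", "groups.tsv", "survival_expression.tsv",
               "clinical.tsv", "ppi_edges.tsv", "disease_genes_a.tsv",
               "disease_genes_b.tsv", "compound_gene.tsv", "mapping.tsv",
               "graph_nodes.tsv", "graph_edges.tsv", "gene_sets.gmt",
               "truth.json")
    invisible(stats::setNames(file.path(dir, files), files))
}
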