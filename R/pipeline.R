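#' Assemble a pipeline configuration
#'
#' Collects the input file paths, analysis thresholds (defaults are the
#' study's stated cut-offs: |log2FC| > 2 and adjusted p < 0.05 for DEGs,
#' raw p < 0.05 with count >= 1 for ORA, adjusted p < 0.05 for pathway
#' scores, edge score >= 0.7 for the PPI network, log-rank p < 0.05 for
#' prognosis, permutation p < 0.05 for diffusion), the permutation count
#' and the RNG seed. `inputDir` may point at a [writeStudy()] bundle, in
#' which case all file paths default to the bundle's layout.
#'
#' @param inputDir directory holding the input files (a [writeStudy()]
#'   bundle layout).
#' @param outDir output directory.
#' @param seed integer RNG seed (mandatory: the diffusion stage is
#'   stochastic).
#' @param lfc,deAlpha,oraAlpha,gsvaAlpha,ppiMinScore,survivalAlpha,
#'   diffusionAlpha stage thresholds.
#' @param nPerm permutation count for diffusion p-values.
#' @param ... named overrides for individual file paths (`exprFile`,
#'   `groupsFile`, `gmtFile`, `ppiFile`, `diseaseAFile`, `diseaseBFile`,
#'   `clinicalFile`, `survivalExprFile`, `nodesFile`, `edgesFile`,
#'   `compoundGeneFile`, `mappingFile`).
#' @return named list of class `"pipelineConfig"`.
#' @export
pipelineConfig <- function(inputDir, outDir, seed, lfc = 2, deAlpha = 0.05,
                           oraAlpha = 0.05, gsvaAlpha = 0.05,
                           ppiMinScore = 0.7, survivalAlpha = 0.05,
                           diffusionAlpha = 0.05, nPerm = 1000L, ...) {
    if (missing(seed)) stop("a seed is required (the diffusion stage is stochastic)")
    p <- function(f) file.path(inputDir, f)
    cfg <- list(
        exprFile = p("expression.tsv"), groupsFile = p("groups.tsv"),
        gmtFile = p("gene_sets.gmt"), ppiFile = p("ppi_edges.tsv"),
        diseaseAFile = p("disease_genes_a.tsv"),
        diseaseBFile = p("disease_genes_b.tsv"),
        clinicalFile = p("clinical.tsv"),
        survivalExprFile = p("survival_expression.tsv"),
        nodesFile = p("graph_nodes.tsv"), edgesFile = p("graph_edges.tsv"),
        compoundGeneFile = p("compound_gene.tsv"),
        mappingFile = p("mapping.tsv"),
        outDir = outDir, seed = as.integer(seed), lfc = lfc,
        deAlpha = deAlpha, oraAlpha = oraAlpha, gsvaAlpha = gsvaAlpha,
        ppiMinScore = ppiMinScore, survivalAlpha = survivalAlpha,
        diffusionAlpha = diffusionAlpha, nPerm = as.integer(nPerm))
    over <- list(...)
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown configuration field(s): ",
                          paste(bad, collapse = ", "))
    cfg[names(over)] <- over
    structure(cfg, class = "pipelineConfig")
}

#' Read a pipeline configuration from a YAML file
#'
#' The YAML mirrors the arguments of [pipelineConfig()]; `inputDir`,
#' `outDir` and `seed` are required, everything else optional.
#'
#' @param path YAML file path.
#' @return named list of class `"pipelineConfig"`.
#' @export
readPipelineConfig <- function(path) {
    y <- yaml::read_yaml(path)
    need <- c("inputDir", "outDir", "seed")
    miss <- setdiff(need, names(y))
    if (length(miss)) stop("configuration is missing field(s): ",
                           paste(miss, collapse = ", "))
    do.call(pipelineConfig, y)
}

.stage <- function(name, expr) {
    wr <- character()
    val <- withCallingHandlers(
        tryCatch(expr, error = function(e)
            stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                 call. = FALSE)),
        warning = function(w) {
            wr <<- c(wr, conditionMessage(w))
            invokeRestart("muffleWarning")
        })
    list(value = val, warnings = wr)
}

#' Run the full integrated analysis
#'
#' Executes, in order: moderated differential expression; up/down
#' over-representation analysis; gene-set variation scoring with
#' differential pathway testing; PPI construction, degrees and feature
#' genes; median-split prognostic screening of the feature genes; and the
#' heat-diffusion metabolite prioritization with disease-network
#' assembly. Each stage's outputs are written as TSV before the next
#' stage starts, and a JSON run manifest records per-stage input hashes,
#' parameters, row counts and collected warnings. Identical configuration
#' and seed reproduce identical outputs.
#'
#' The affected-metabolite set is derived as in the source workflow:
#' compounds linked (in the compound-gene table) to the prognostic genes
#' are mapped to compound ids, and the ids present among the graph's
#' scored compounds become the diffusion input. If no prognostic gene
#' survives, the feature genes are used as a fallback, with a warning.
#'
#' @param config list from [pipelineConfig()] or [readPipelineConfig()].
#' @return invisibly, the manifest (named list) also written to
#'   `manifest.json` under `config$outDir`.
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "pipelineConfig") || is.list(config))
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    out <- function(f) file.path(config$outDir, f)
    manifest <- list(package = "osteoMetNet",
                     version = as.character(utils::packageVersion("osteoMetNet")),
                     seed = config$seed, stages = list())
    note <- function(name, inputs, outputs, rows, params, warnings) {
        manifest$stages[[name]] <<- list(
            inputs = as.list(tools::md5sum(inputs[file.exists(inputs)])),
            outputs = as.list(tools::md5sum(outputs)),
            rows = rows, params = params,
            warnings = if (length(warnings)) warnings else list())
    }

    ## 1. differential expression -------------------------------------
    st <- .stage("differential_expression", {
        x <- readExpressionTSV(config$exprFile)
        groups <- readTableChecked(config$groupsFile,
                                   c(sample = "character", group = "character"))
        x <- x[, groups$sample, drop = FALSE]
        ms <- moderateStatistics(fitGeneModels(x, groups$group))
        degs <- callDEGs(ms, lfcThreshold = config$lfc, alpha = config$deAlpha)
        writeTableChecked(ms@table, out("stats.tsv"))
        writeTableChecked(degs, out("degs.tsv"))
        list(x = x, groups = groups$group, ms = ms, degs = degs)
    })
    de <- st$value
    note("differential_expression", c(config$exprFile, config$groupsFile),
         c(out("stats.tsv"), out("degs.tsv")),
         list(genes = nrow(de$ms@table), degs = nrow(de$degs)),
         list(lfc = config$lfc, alpha = config$deAlpha), st$warnings)

    ## 2. over-representation analysis --------------------------------
    st <- .stage("ora", {
        sets <- readGMT(config$gmtFile)
        universe <- rownames(de$x)
        up <- de$degs$gene[de$degs$direction == "up"]
        down <- de$degs$gene[de$degs$direction == "down"]
        oraUp <- enrichORA(up, sets, universe, alpha = config$oraAlpha)
        oraDown <- enrichORA(down, sets, universe, alpha = config$oraAlpha)
        writeTableChecked(oraUp, out("ora_up.tsv"))
        writeTableChecked(oraDown, out("ora_down.tsv"))
        list(up = oraUp, down = oraDown, sets = sets)
    })
    note("ora", config$gmtFile, c(out("ora_up.tsv"), out("ora_down.tsv")),
         list(up = nrow(st$value$up), down = nrow(st$value$down)),
         list(alpha = config$oraAlpha, minCount = 1), st$warnings)
    sets <- st$value$sets

    ## 3. gene-set variation scoring ----------------------------------
    st <- .stage("gsva", {
        z <- kernelCdfScores(de$x)
        es <- esScores(z, sets)
        diff <- differentialPathways(es, de$groups, alpha = config$gsvaAlpha)
        writeTableChecked(data.frame(set = rownames(es), es,
                                     check.names = FALSE), out("gsva_es.tsv"))
        writeTableChecked(diff, out("gsva_diff.tsv"))
        diff
    })
    note("gsva", config$gmtFile, c(out("gsva_es.tsv"), out("gsva_diff.tsv")),
         list(differential = nrow(st$value)),
         list(alpha = config$gsvaAlpha, tau = 1), st$warnings)

    ## 4. PPI network and feature genes -------------------------------
    st <- .stage("feature_network", {
        edges <- readTableChecked(config$ppiFile,
            c(geneA = "character", geneB = "character", score = "numeric"))
        net <- buildPPI(edges, de$degs, minScore = config$ppiMinScore)
        degTab <- nodeDegrees(net)
        tabA <- readTableChecked(config$diseaseAFile, c(gene = "character"))$gene
        tabB <- readTableChecked(config$diseaseBFile, c(gene = "character"))$gene
        fg <- featureGenes(net, tabA, tabB)
        writeTableChecked(net@edges, out("ppi_edges.tsv"))
        writeTableChecked(degTab, out("ppi_degrees.tsv"))
        writeTableChecked(fg, out("feature_genes.tsv"))
        list(net = net, features = fg$gene[fg$feature])
    })
    fn <- st$value
    note("feature_network",
         c(config$ppiFile, config$diseaseAFile, config$diseaseBFile),
         c(out("ppi_edges.tsv"), out("ppi_degrees.tsv"), out("feature_genes.tsv")),
         list(nodes = nrow(fn$net@nodes), edges = nrow(fn$net@edges),
              features = length(fn$features)),
         list(minScore = config$ppiMinScore), st$warnings)

    ## 5. survival screening ------------------------------------------
    st <- .stage("survival", {
        clin <- readTableChecked(config$clinicalFile,
            c(sample = "character", time = "numeric", event = "integer"))
        sx <- readExpressionTSV(config$survivalExprFile)
        prog <- screenPrognostic(clin, sx, fn$features,
                                 alpha = config$survivalAlpha)
        writeTableChecked(attr(prog, "screen"), out("survival_screen.tsv"))
        writeTableChecked(prog, out("prognosis.tsv"))
        prog
    })
    prog <- st$value
    note("survival", c(config$clinicalFile, config$survivalExprFile),
         c(out("survival_screen.tsv"), out("prognosis.tsv")),
         list(screened = nrow(attr(prog, "screen")), prognostic = nrow(prog)),
         list(alpha = config$survivalAlpha), st$warnings)

    ## 6. diffusion and disease-metabolic network ---------------------
    st <- .stage("diffusion", {
        nodes <- readTableChecked(config$nodesFile,
                                  c(id = "character", type = "character"))
        edges <- readTableChecked(config$edgesFile,
                                  c(source = "character", target = "character"))
        graph <- buildMetabolicGraph(nodes, edges)
        cg <- readTableChecked(config$compoundGeneFile,
                               c(compound = "character", gene = "character"))
        mapping <- readTableChecked(config$mappingFile,
                                    c(name = "character", compoundId = "character"))
        scoredTypes <- graph@nodes$type[match(graph@scoredIds, graph@nodes$id)]
        pool <- graph@scoredIds[scoredTypes == "compound"]
        affectedFrom <- function(genes) {
            chems <- unique(cg$compound[toupper(cg$gene) %in% toupper(genes)])
            mapped <- mapCompoundIds(chems, mapping)
            list(affected = intersect(mapped$ids, pool), mapped = mapped)
        }
        # widen the seeding gene set until a mapped compound hits the graph:
        # prognostic genes, then feature genes, then the whole table
        got <- affectedFrom(prog$gene)
        if (!length(got$affected)) {
            warning("no prognostic-gene compound maps into the graph; widening to feature genes")
            got <- affectedFrom(fn$features)
        }
        if (!length(got$affected)) {
            warning("no feature-gene compound maps into the graph; using every listed chemical")
            got <- affectedFrom(cg$gene)
        }
        affected <- got$affected
        mapped <- got$mapped
        if (!length(affected))
            stop("no mapped compound survives in the scored metabolic graph")
        scores <- permutationPvalues(graph, affected, nPerm = config$nPerm,
                                     seed = config$seed)
        subnet <- significantSubnetwork(graph, scores,
                                        alpha = config$diffusionAlpha)
        cgIds <- data.frame(
            compound = mapping$compoundId[match(tolower(cg$compound),
                                                tolower(mapping$name))],
            gene = cg$gene, stringsAsFactors = FALSE)
        cgIds <- cgIds[!is.na(cgIds$compound), , drop = FALSE]
        dmn <- assembleDiseaseNetwork(subnet, cgIds, de$degs)
        keys <- rankKeyMetabolites(dmn)
        writeTableChecked(scores@table, out("diffusion_scores.tsv"))
        writeTableChecked(dmn@nodes, out("disease_network_nodes.tsv"))
        writeTableChecked(dmn@edges, out("disease_network_edges.tsv"))
        writeTableChecked(keys, out("key_metabolites.tsv"))
        jsonlite::write_json(list(
            seed = config$seed, nPerm = config$nPerm, affected = affected,
            unmapped = mapped$unmapped,
            excludedComponents = graph@excluded),
            out("diffusion_report.json"), auto_unbox = TRUE, digits = NA)
        list(scores = scores, network = dmn, keys = keys)
    })
    note("diffusion",
         c(config$nodesFile, config$edgesFile, config$compoundGeneFile,
           config$mappingFile),
         c(out("diffusion_scores.tsv"), out("disease_network_nodes.tsv"),
           out("disease_network_edges.tsv"), out("key_metabolites.tsv")),
         list(scored = nrow(st$value$scores@table),
              retained = nrow(st$value$network@nodes),
              keyMetabolite = if (nrow(st$value$keys))
                  st$value$keys$compound[1] else NA_character_),
         list(alpha = config$diffusionAlpha, nPerm = config$nPerm),
         st$warnings)

    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         digits = NA)
    invisible(manifest)
}
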