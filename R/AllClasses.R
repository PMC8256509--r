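#' @import methods
#' @importFrom stats pnorm pt pchisq phyper p.adjust rnorm rexp runif rbinom
#'   median var sd setNames quantile rbeta
#' @importFrom utils head read.delim write.table
NULL

#' Simulation configuration
#'
#' Holds every knob of the synthetic-data generators: the two-group
#' expression design (case/control sizes emulating a 19-cell-line vs
#' 4-normal-bone contrast), planted differential-expression effects, the
#' right-censored survival cohort with planted prognostic genes, and the
#' typed metabolic graph with planted affected compounds. Construct with
#' [simConfig()].
#'
#' @slot seed integer; master RNG seed, every generator is a pure function
#'   of the configuration including this seed.
#' @slot nGenes,nCase,nControl,nDE integer counts; `nDE <= nGenes`.
#' @slot lfcEffect numeric, planted absolute log2 fold change.
#' @slot noiseSd numeric, Gaussian noise s.d. on the log2 scale.
#' @slot nSamplesSurvival integer, size of the survival cohort.
#' @slot prognosticGenes named numeric vector of hazard ratios (per-gene
#'   multiplicative hazard for the high-expression group).
#' @slot censorRate numeric in `[0,1]`, expected fraction censored.
#' @slot graphSizes named integer vector with elements `compounds`,
#'   `reactions`, `enzymes`, `pathways`, `modules`.
#' @slot nAffectedCompounds integer, planted "hot" compounds.
#' @slot overlapFraction numeric in `[0,1]`, fraction of DE genes carried
#'   into each disease-association table.
#' @export
setClass("SimConfig", slots = c(
    seed = "integer",
    nGenes = "integer", nCase = "integer", nControl = "integer",
    nDE = "integer", lfcEffect = "numeric", noiseSd = "numeric",
    nSamplesSurvival = "integer", prognosticGenes = "numeric",
    censorRate = "numeric", graphSizes = "integer",
    nAffectedCompounds = "integer", overlapFraction = "numeric"
))

setValidity("SimConfig", function(object) {
    msg <- character()
    cnt <- c(nGenes = object@nGenes, nCase = object@nCase,
             nControl = object@nControl, nSamplesSurvival = object@nSamplesSurvival)
    if (any(cnt <= 0L)) msg <- c(msg, "all counts must be positive")
    if (object@nDE < 0L || object@nDE > object@nGenes)
        msg <- c(msg, "nDE must lie in [0, nGenes]")
    if (object@censorRate < 0 || object@censorRate > 1)
        msg <- c(msg, "censorRate must lie in [0, 1]")
    if (object@overlapFraction < 0 || object@overlapFraction > 1)
        msg <- c(msg, "overlapFraction must lie in [0, 1]")
    need <- c("compounds", "reactions", "enzymes", "pathways", "modules")
    if (!all(need %in% names(object@graphSizes)))
        msg <- c(msg, "graphSizes must name compounds, reactions, enzymes, pathways, modules")
    else {
        if (any(object@graphSizes[need] < 1L))
            msg <- c(msg, "all graphSizes must be >= 1")
        if (object@graphSizes[["pathways"]] < 1L)
            msg <- c(msg, "at least one pathway node is required")
        if (object@nAffectedCompounds < 1L ||
            object@nAffectedCompounds > object@graphSizes[["compounds"]])
            msg <- c(msg, "nAffectedCompounds must lie in [1, compounds]")
    }
    if (length(msg)) msg else TRUE
})

#' Planted ground truth of a synthetic study
#'
#' @slot deGenes named numeric; planted signed log2 fold changes.
#' @slot prognosticGenes named numeric; planted hazard ratios.
#' @slot affectedCompounds character; compound node ids planted as "hot".
#' @slot keyCompound character(1); the compound wired to the most DEGs.
#' @export
setClass("GroundTruth", slots = c(
    deGenes = "numeric", prognosticGenes = "numeric",
    affectedCompounds = "character", keyCompound = "character"
))

#' Per-gene two-group linear model fits
#'
#' One ordinary least-squares fit per gene on the case/control design:
#' log2 fold change (case minus control mean), pooled residual variance,
#' residual degrees of freedom and the unscaled standard error of the
#' contrast. Produced by [fitGeneModels()], consumed by
#' [moderateStatistics()].
#'
#' @slot genes character gene identifiers.
#' @slot log2FC,s2,df numeric vectors parallel to `genes`.
#' @slot stdevUnscaled numeric(1), `sqrt(1/n1 + 1/n2)`.
#' @slot nCase,nControl integer group sizes.
#' @export
setClass("GeneFit", slots = c(
    genes = "character", log2FC = "numeric", s2 = "numeric", df = "numeric",
    stdevUnscaled = "numeric", nCase = "integer", nControl = "integer"
))

setValidity("GeneFit", function(object) {
    n <- length(object@genes)
    if (length(object@log2FC) != n || length(object@s2) != n)
        return("log2FC and s2 must be parallel to genes")
    if (any(object@s2 < 0)) return("residual variances must be non-negative")
    TRUE
})

#' Empirical-Bayes moderated statistics
#'
#' Result of shrinking per-gene residual variances toward a prior
#' `(d0, s20)` estimated by moment matching on the log variances, with
#' moderated t, two-sided p on `d0 + df` degrees of freedom and BH-adjusted
#' q. See [moderateStatistics()].
#'
#' @slot table data.frame with columns gene, log2FC, s2, s2Post, t, p, q.
#' @slot d0 numeric(1) prior degrees of freedom (may be `Inf`).
#' @slot s20 numeric(1) prior variance.
#' @slot dfResidual numeric(1) residual df of the per-gene fits.
#' @export
setClass("ModeratedStats", slots = c(
    table = "data.frame", d0 = "numeric", s20 = "numeric",
    dfResidual = "numeric"
))

#' Score-filtered protein-protein interaction network
#'
#' Undirected network over differentially expressed genes whose edges carry
#' a confidence score at or above the retention threshold. Isolated genes
#' are not part of the node set. Built by [buildPPI()].
#'
#' @slot nodes data.frame with columns gene, direction.
#' @slot edges data.frame with columns geneA, geneB, score.
#' @slot minScore numeric(1) retention threshold.
#' @export
setClass("PPINetwork", slots = c(
    nodes = "data.frame", edges = "data.frame", minScore = "numeric"
))

setValidity("PPINetwork", function(object) {
    e <- object@edges
    if (nrow(e)) {
        if (any(e$geneA == e$geneB)) return("self-loops are not allowed")
        key <- paste(pmin(e$geneA, e$geneB), pmax(e$geneA, e$geneB))
        if (anyDuplicated(key)) return("duplicate undirected edges")
        if (any(e$score < object@minScore)) return("edge below score threshold")
    }
    TRUE
})

#' Heterogeneous KEGG-style metabolic graph
#'
#' Typed undirected graph over compound, reaction, enzyme, pathway, module
#' (and, after overlay, gene) nodes. The scored subgraph excludes gene
#' nodes; connected components of it that lack a pathway node are excluded
#' from diffusion scoring and recorded in `excluded`. Built by
#' [buildMetabolicGraph()].
#'
#' @slot nodes data.frame with columns id, type.
#' @slot edges data.frame with columns source, target.
#' @slot scoredIds character; node ids participating in diffusion scoring.
#' @slot excluded list of character vectors, one per excluded component.
#' @export
setClass("MetabolicGraph", slots = c(
    nodes = "data.frame", edges = "data.frame",
    scoredIds = "character", excluded = "list"
))

.nodeTypes <- c("compound", "reaction", "enzyme", "pathway", "module", "gene")

setValidity("MetabolicGraph", function(object) {
    msg <- character()
    if (!all(object@nodes$type %in% .nodeTypes))
        msg <- c(msg, sprintf("unknown node type(s): %s",
                 paste(setdiff(unique(object@nodes$type), .nodeTypes), collapse = ", ")))
    if (anyDuplicated(object@nodes$id)) msg <- c(msg, "duplicated node ids")
    e <- object@edges
    if (nrow(e)) {
        if (any(e$source == e$target)) msg <- c(msg, "self-loops are not allowed")
        bad <- !(e$source %in% object@nodes$id) | !(e$target %in% object@nodes$id)
        if (any(bad)) msg <- c(msg, "edge endpoints missing from node table")
    }
    if (length(msg)) msg else TRUE
})

#' Conductance system of the scored metabolic subgraph
#'
#' Holds the unnormalized graph Laplacian `L = D - A` of the scored
#' (non-gene) subgraph, the diagonal pathway indicator `B`, and the
#' conductance matrix `KI = L + B` that governs the heat-diffusion solve.
#' `KI` is symmetric positive definite whenever every scored component
#' contains a pathway node.
#'
#' @slot L,B,KI sparse symmetric matrices (package Matrix).
#' @slot ids character node ids indexing the rows/columns.
#' @export
setClass("ConductanceSystem", slots = c(
    L = "ANY", B = "ANY", KI = "ANY", ids = "character"
))

#' Diffusion scores with permutation p-values
#'
#' @slot table data.frame with columns node, type, score and (after
#'   [permutationPvalues()]) p.
#' @slot nPerm integer(1); 0 until permutation p-values are attached.
#' @slot seed integer(1) RNG seed of the permutation null.
#' @export
setClass("DiffusionScores", slots = c(
    table = "data.frame", nPerm = "integer", seed = "integer"
))

#' Disease-metabolic network
#'
#' Diffusion-significant metabolic subgraph augmented with DEG-compound
#' overlay edges; tracks per-compound DEG-interaction counts used to call
#' the key metabolite. Built by [assembleDiseaseNetwork()].
#'
#' @slot nodes data.frame with columns id, type, direction, p.
#' @slot edges data.frame with columns source, target, kind
#'   (`"metabolic"` or `"overlay"`).
#' @slot compoundCounts data.frame with columns compound, nGenes, p.
#' @export
setClass("DiseaseMetabolicNetwork", slots = c(
    nodes = "data.frame", edges = "data.frame", compoundCounts = "data.frame"
))
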