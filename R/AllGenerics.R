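#' @name accessors
#' @title Accessors for osteoMetNet result objects
#' @description Small accessor generics so downstream code never touches
#'   slots directly.
#' @param x an osteoMetNet S4 object.
#' @return `statsTable` the per-gene (or per-set) statistics data.frame;
#'   `priorDf`/`priorVar` the empirical-Bayes prior `(d0, s20)`;
#'   `graphNodes`/`graphEdges` the node/edge tables; `scoredNodes` the
#'   ids entering diffusion scoring; `excludedComponents` the
#'   pathway-free components; `scoresTable` the diffusion score/p table;
#'   `compoundCounts` the per-compound DEG-interaction counts.
NULL

#' @rdname accessors
#' @export
setGeneric("statsTable", function(x) standardGeneric("statsTable"))
#' @rdname accessors
#' @export
setGeneric("priorDf", function(x) standardGeneric("priorDf"))
#' @rdname accessors
#' @export
setGeneric("priorVar", function(x) standardGeneric("priorVar"))
#' @rdname accessors
#' @export
setGeneric("graphNodes", function(x) standardGeneric("graphNodes"))
#' @rdname accessors
#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))
#' @rdname accessors
#' @export
setGeneric("scoredNodes", function(x) standardGeneric("scoredNodes"))
#' @rdname accessors
#' @export
setGeneric("excludedComponents", function(x) standardGeneric("excludedComponents"))
#' @rdname accessors
#' @export
setGeneric("scoresTable", function(x) standardGeneric("scoresTable"))
#' @rdname accessors
#' @export
setGeneric("compoundCounts", function(x) standardGeneric("compoundCounts"))

#' @rdname accessors
setMethod("statsTable", "ModeratedStats", function(x) x@table)
#' @rdname accessors
setMethod("priorDf", "ModeratedStats", function(x) x@d0)
#' @rdname accessors
setMethod("priorVar", "ModeratedStats", function(x) x@s20)
#' @rdname accessors
setMethod("graphNodes", "MetabolicGraph", function(x) x@nodes)
#' @rdname accessors
setMethod("graphEdges", "MetabolicGraph", function(x) x@edges)
#' @rdname accessors
setMethod("graphNodes", "PPINetwork", function(x) x@nodes)
#' @rdname accessors
setMethod("graphEdges", "PPINetwork", function(x) x@edges)
#' @rdname accessors
setMethod("graphNodes", "DiseaseMetabolicNetwork", function(x) x@nodes)
#' @rdname accessors
setMethod("graphEdges", "DiseaseMetabolicNetwork", function(x) x@edges)
#' @rdname accessors
setMethod("scoredNodes", "MetabolicGraph", function(x) x@scoredIds)
#' @rdname accessors
setMethod("excludedComponents", "MetabolicGraph", function(x) x@excluded)
#' @rdname accessors
setMethod("scoresTable", "DiffusionScores", function(x) x@table)
#' @rdname accessors
setMethod("compoundCounts", "DiseaseMetabolicNetwork", function(x) x@compoundCounts)

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig: ", object@nGenes, " genes, ", object@nCase, " case / ",
        object@nControl, " control, ", object@nDE, " planted DE (|lfc| = ",
        object@lfcEffect, ", sd = ", object@noiseSd, ")\n",
        "  survival n = ", object@nSamplesSurvival, ", censor rate = ",
        object@censorRate, ", prognostic: ",
        paste(sprintf("%s (HR %.2g)", names(object@prognosticGenes),
                      object@prognosticGenes), collapse = ", "), "\n",
        "  graph: ", paste(sprintf("%d %s", object@graphSizes,
                                   names(object@graphSizes)), collapse = ", "),
        "; ", object@nAffectedCompounds, " affected compounds; seed ",
        object@seed, "\n", sep = "")
})

setMethod("show", "GeneFit", function(object) {
    cat("GeneFit: ", length(object@genes), " genes, ", object@nCase,
        " case vs ", object@nControl, " control (df = ", object@df[1],
        ")\n", sep = "")
})

setMethod("show", "ModeratedStats", function(object) {
    cat("ModeratedStats: ", nrow(object@table), " genes; prior d0 = ",
        format(object@d0, digits = 4), ", s20 = ",
        format(object@s20, digits = 4), "\n", sep = "")
})

setMethod("show", "PPINetwork", function(object) {
    cat("PPINetwork: ", nrow(object@nodes), " nodes, ", nrow(object@edges),
        " edges (score >= ", object@minScore, ")\n", sep = "")
})

setMethod("show", "MetabolicGraph", function(object) {
    tt <- table(object@nodes$type)
    cat("MetabolicGraph: ", nrow(object@nodes), " nodes (",
        paste(sprintf("%d %s", as.integer(tt), names(tt)), collapse = ", "),
        "), ", nrow(object@edges), " edges; ", length(object@scoredIds),
        " scored, ", length(object@excluded), " excluded component(s)\n",
        sep = "")
})

setMethod("show", "DiffusionScores", function(object) {
    cat("DiffusionScores: ", nrow(object@table), " nodes",
        if (object@nPerm > 0)
            paste0("; permutation null with ", object@nPerm,
                   " draws (seed ", object@seed, ")"), "\n", sep = "")
})

setMethod("show", "DiseaseMetabolicNetwork", function(object) {
    cat("DiseaseMetabolicNetwork: ", nrow(object@nodes), " nodes, ",
        nrow(object@edges), " edges (",
        sum(object@edges$kind == "overlay"), " DEG-compound overlay)\n",
        sep = "")
})
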