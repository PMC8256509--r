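#' Build the score-filtered PPI network over DEGs
#'
#' Retains edges whose confidence score is at or above `minScore`
#' (inclusive, matching the "medium confidence 0.7" convention of
#' STRING-style edge lists) and whose both endpoints are called DEGs.
#' Duplicate unordered pairs keep the maximum score; self-loops are
#' dropped. Gene symbols are upper-cased before matching, since
#' cross-database tables differ in case. DEGs with no retained edge are
#' not part of the node set.
#'
#' @param edgeTable data.frame with columns geneA, geneB, score (in
#'   `[0, 1]`).
#' @param degTable DEG table from [callDEGs()] (columns gene, direction).
#' @param minScore retention threshold (default 0.7, inclusive).
#' @return A [PPINetwork-class] object.
#' @export
buildPPI <- function(edgeTable, degTable, minScore = 0.7) {
    need <- c("geneA", "geneB", "score")
    if (!all(need %in% names(edgeTable)))
        stop("edgeTable needs columns geneA, geneB, score")
    bad <- which(!is.finite(edgeTable$score) |
                 edgeTable$score < 0 | edgeTable$score > 1)
    if (length(bad))
        stop("malformed edge score at row(s) ", paste(head(bad, 5), collapse = ", "))
    e <- data.frame(geneA = toupper(as.character(edgeTable$geneA)),
                    geneB = toupper(as.character(edgeTable$geneB)),
                    score = edgeTable$score, stringsAsFactors = FALSE)
    degGenes <- toupper(degTable$gene)
    e <- e[e$score >= minScore & e$geneA != e$geneB &
           e$geneA %in% degGenes & e$geneB %in% degGenes, , drop = FALSE]
    if (nrow(e)) {
        a <- pmin(e$geneA, e$geneB); b <- pmax(e$geneA, e$geneB)
        e <- data.frame(geneA = a, geneB = b, score = e$score,
                        stringsAsFactors = FALSE)
        e <- e[order(edgeKey(a, b), -e$score), , drop = FALSE]
        e <- e[!duplicated(edgeKey(e$geneA, e$geneB)), , drop = FALSE]
        rownames(e) <- NULL
    }
    nodeIds <- sort(unique(c(e$geneA, e$geneB)))
    nodes <- data.frame(
        gene = nodeIds,
        direction = degTable$direction[match(nodeIds, degGenes)],
        stringsAsFactors = FALSE)
    methods::new("PPINetwork", nodes = nodes, edges = e, minScore = minScore)
}

#' Node degrees of a PPI network
#'
#' Counts retained edges incident to each node; by the handshake identity
#' the degrees sum to twice the edge count.
#'
#' @param network A [PPINetwork-class] object.
#' @return data.frame with columns gene, degree, sorted by decreasing
#'   degree then gene.
#' @export
nodeDegrees <- function(network) {
    stopifnot(methods::is(network, "PPINetwork"))
    cnt <- table(factor(c(network@edges$geneA, network@edges$geneB),
                        levels = network@nodes$gene))
    out <- data.frame(gene = names(cnt), degree = as.integer(cnt),
                      stringsAsFactors = FALSE)
    out <- out[order(-out$degree, out$gene), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Feature genes by three-way intersection
#'
#' Intersects the PPI node set with two disease-association gene tables
#' (CTD-like and GeneCards-like lists). Symbols are upper-cased before
#' matching. The returned table covers the union of the three sources with
#' per-source membership flags; feature genes are the rows present in all
#' three.
#'
#' @param network A [PPINetwork-class] object.
#' @param tableA,tableB character vectors of disease-associated genes.
#' @return data.frame with columns gene, inNetwork, inTableA, inTableB,
#'   feature (logical); feature genes sorted first.
#' @export
featureGenes <- function(network, tableA, tableB) {
    stopifnot(methods::is(network, "PPINetwork"))
    net <- toupper(network@nodes$gene)
    a <- unique(toupper(as.character(tableA)))
    b <- unique(toupper(as.character(tableB)))
    all <- sort(unique(c(net, a, b)))
    out <- data.frame(
        gene = all,
        inNetwork = all %in% net, inTableA = all %in% a, inTableB = all %in% b,
        stringsAsFactors = FALSE)
    out$feature <- out$inNetwork & out$inTableA & out$inTableB
    out <- out[order(-out$feature, out$gene), , drop = FALSE]
    rownames(out) <- NULL
    out
}
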