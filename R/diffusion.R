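#' Build a typed metabolic graph from node and edge tables
#'
#' Validates the typology (compound, reaction, enzyme, pathway, module,
#' gene), rejects self-loops and edges to undeclared nodes (reporting the
#' offending row), deduplicates undirected edges, and determines which
#' nodes participate in diffusion scoring: gene nodes never do, and
#' connected components of the non-gene subgraph without a pathway node
#' are excluded with a warning (they would make the conductance matrix
#' singular).
#'
#' @param nodeTable data.frame with columns id, type.
#' @param edgeTable data.frame with columns source, target.
#' @return A [MetabolicGraph-class] object.
#' @export
buildMetabolicGraph <- function(nodeTable, edgeTable) {
    if (!all(c("id", "type") %in% names(nodeTable)))
        stop("nodeTable needs columns id, type")
    if (!all(c("source", "target") %in% names(edgeTable)))
        stop("edgeTable needs columns source, target")
    nodes <- data.frame(id = as.character(nodeTable$id),
                        type = as.character(nodeTable$type),
                        stringsAsFactors = FALSE)
    unknown <- setdiff(unique(nodes$type), .nodeTypes)
    if (length(unknown))
        stop("unknown node type(s): ", paste(unknown, collapse = ", "))
    e <- data.frame(source = as.character(edgeTable$source),
                    target = as.character(edgeTable$target),
                    stringsAsFactors = FALSE)
    dangling <- which(!(e$source %in% nodes$id) | !(e$target %in% nodes$id))
    if (length(dangling)) {
        miss <- setdiff(unique(c(e$source[dangling], e$target[dangling])), nodes$id)
        stop(sprintf("edge row(s) %s reference undeclared node(s): %s",
                     paste(head(dangling, 5), collapse = ", "),
                     paste(head(miss, 5), collapse = ", ")))
    }
    loops <- which(e$source == e$target)
    if (length(loops))
        stop("self-loop at edge row(s) ", paste(head(loops, 5), collapse = ", "))
    e <- e[!duplicated(edgeKey(e$source, e$target)), , drop = FALSE]
    rownames(e) <- NULL

    scored <- nodes$id[nodes$type != "gene"]
    eScored <- e[e$source %in% scored & e$target %in% scored, , drop = FALSE]
    g <- igraph::graph_from_data_frame(
        eScored, directed = FALSE,
        vertices = data.frame(name = scored))
    comp <- igraph::components(g)
    excluded <- list()
    keep <- character()
    for (k in seq_len(comp$no)) {
        ids <- names(comp$membership)[comp$membership == k]
        types <- nodes$type[match(ids, nodes$id)]
        if (any(types == "pathway")) keep <- c(keep, ids)
        else excluded <- c(excluded, list(sort(ids)))
    }
    if (length(excluded))
        warning(sprintf("%d component(s) without a pathway node excluded from scoring (%d node(s))",
                        length(excluded), sum(lengths(excluded))))
    methods::new("MetabolicGraph", nodes = nodes, edges = e,
                 scoredIds = keep, excluded = excluded)
}

#' Conductance system of the scored subgraph
#'
#' On the scored (non-gene, pathway-anchored) subgraph: `L = D - A` is the
#' unnormalized Laplacian, `B` the diagonal matrix with `B[i,i] = 1` if
#' node i is a pathway and 0 otherwise, and `KI = L + B`. With a pathway
#' node in every scored component, `KI` is symmetric positive definite, so
#' the heat-diffusion system has a unique solution.
#'
#' @param graph A [MetabolicGraph-class] object.
#' @return A [ConductanceSystem-class] object.
#' @export
conductanceSystem <- function(graph) {
    stopifnot(methods::is(graph, "MetabolicGraph"))
    ids <- graph@scoredIds
    if (!length(ids)) stop("no scored nodes: every component lacks a pathway")
    n <- length(ids)
    e <- graph@edges
    e <- e[e$source %in% ids & e$target %in% ids, , drop = FALSE]
    i <- match(e$source, ids); j <- match(e$target, ids)
    A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1,
                              dims = c(n, n), dimnames = list(ids, ids))
    L <- Matrix::Diagonal(n, x = Matrix::rowSums(A)) - A
    types <- graph@nodes$type[match(ids, graph@nodes$id)]
    B <- Matrix::Diagonal(n, x = as.numeric(types == "pathway"))
    KI <- methods::as(Matrix::forceSymmetric(L + B), "CsparseMatrix")
    methods::new("ConductanceSystem", L = L, B = B, KI = KI, ids = ids)
}

#' Heat-diffusion temperature scores
#'
#' Solves the conductance system `KI %*% T = G` for the temperature vector
#' `T`, where `G` is the binary indicator of the affected (input)
#' metabolites. Heat injected at the affected compounds spreads along the
#' graph and drains at pathway nodes; nodes close to the sources end up
#' hot. The relative residual of the solve is checked against 1e-10.
#'
#' @param system A [ConductanceSystem-class] object.
#' @param g numeric indicator vector over the scored nodes (or a character
#'   vector of affected compound ids).
#' @return named numeric vector of temperature scores over the scored
#'   nodes.
#' @export
diffusionScores <- function(system, g) {
    stopifnot(methods::is(system, "ConductanceSystem"))
    if (is.character(g)) {
        miss <- setdiff(g, system@ids)
        if (length(miss))
            stop("affected node(s) not in the scored subgraph: ",
                 paste(miss, collapse = ", "))
        g <- as.numeric(system@ids %in% g)
    }
    if (length(g) != length(system@ids)) stop("indicator length mismatch")
    tv <- as.numeric(Matrix::solve(system@KI, g))
    resid <- sqrt(sum((as.numeric(system@KI %*% tv) - g)^2))
    denom <- sqrt(sum(g^2))
    if (denom > 0 && resid / denom > 1e-10)
        stop("diffusion solve failed: relative residual ", resid / denom,
             " (is a scored component missing its pathway node?)")
    stats::setNames(tv, system@ids)
}

#' Permutation p-values for diffusion scores
#'
#' Monte-Carlo null: the affected set is redrawn uniformly among
#' compound-type scored nodes at the same cardinality, the diffusion is
#' re-solved, and each node's p-value is the add-one-corrected fraction of
#' permutations whose score reaches its observed score:
#' `p = (1 + #(T_perm >= T_obs)) / (nPerm + 1)`. Because only the rank of
#' the observed score among permuted scores matters, any global rescaling
#' or sign flip of the solve convention leaves the p-values unchanged.
#'
#' @param graph A [MetabolicGraph-class] object.
#' @param affected character vector of affected compound node ids.
#' @param nPerm number of permutations (default 10000).
#' @param seed integer RNG seed (mandatory for reproducibility).
#' @return A [DiffusionScores-class] object with columns node, type,
#'   score, p.
#' @export
permutationPvalues <- function(graph, affected, nPerm = 10000, seed) {
    stopifnot(methods::is(graph, "MetabolicGraph"))
    if (missing(seed)) stop("a seed is required for the permutation null")
    sys <- conductanceSystem(graph)
    types <- graph@nodes$type[match(sys@ids, graph@nodes$id)]
    pool <- sys@ids[types == "compound"]
    affected <- unique(as.character(affected))
    if (!length(affected)) stop("need at least one affected compound")
    bad <- setdiff(affected, pool)
    if (length(bad))
        stop("affected id(s) are not scored compound nodes: ",
             paste(bad, collapse = ", "))
    m <- length(affected)
    if (m > length(pool)) stop("affected set larger than the compound pool")
    tObs <- diffusionScores(sys, affected)

    # All permuted temperature vectors are sums of columns of KI^{-1}
    # restricted to compound nodes; precompute those columns once.
    n <- length(sys@ids)
    E <- matrix(0, n, length(pool))
    E[cbind(match(pool, sys@ids), seq_along(pool))] <- 1
    W <- as.matrix(Matrix::solve(sys@KI, E))
    exceed <- integer(n)
    withSeed(seed, {
        for (b in seq_len(nPerm)) {
            idx <- sample.int(length(pool), m)
            tPerm <- if (m == 1L) W[, idx] else rowSums(W[, idx, drop = FALSE])
            exceed <- exceed + (tPerm >= tObs)
        }
    })
    p <- (1 + exceed) / (nPerm + 1)
    tab <- data.frame(node = sys@ids, type = types, score = unname(tObs),
                      p = p, stringsAsFactors = FALSE)
    methods::new("DiffusionScores", table = tab, nPerm = as.integer(nPerm),
                 seed = as.integer(seed))
}

#' Diffusion-significant subnetwork
#'
#' Nodes with permutation `p < alpha` (strict) and the edges induced among
#' them.
#'
#' @param graph A [MetabolicGraph-class] object.
#' @param scores A [DiffusionScores-class] object.
#' @param alpha p cut-off (strict; default 0.05).
#' @return A [MetabolicGraph-class] restricted to the significant nodes;
#'   per-node p-values are attached as attribute `"p"` (named vector).
#' @export
significantSubnetwork <- function(graph, scores, alpha = 0.05) {
    stopifnot(methods::is(graph, "MetabolicGraph"),
              methods::is(scores, "DiffusionScores"))
    tab <- scores@table
    keepIds <- tab$node[tab$p < alpha]
    nodes <- graph@nodes[graph@nodes$id %in% keepIds, , drop = FALSE]
    e <- graph@edges
    e <- e[e$source %in% keepIds & e$target %in% keepIds, , drop = FALSE]
    rownames(nodes) <- rownames(e) <- NULL
    out <- methods::new("MetabolicGraph", nodes = nodes, edges = e,
                        scoredIds = character(), excluded = list())
    attr(out, "p") <- stats::setNames(tab$p, tab$node)[nodes$id]
    out
}

#' Assemble the disease-metabolic network
#'
#' Overlays DEG-compound interactions on the diffusion-significant
#' subnetwork: gene nodes (annotated up/down from the DEG table) and
#' gene-compound edges are added only for pairs whose compound survived
#' retention, and the DEG-interaction count per retained compound is
#' recorded — the criterion behind the key-metabolite call.
#'
#' @param subnet significant subnetwork from [significantSubnetwork()].
#' @param compoundGeneTable data.frame with columns compound, gene.
#' @param degTable DEG table from [callDEGs()].
#' @return A [DiseaseMetabolicNetwork-class] object.
#' @export
assembleDiseaseNetwork <- function(subnet, compoundGeneTable, degTable) {
    stopifnot(methods::is(subnet, "MetabolicGraph"))
    p <- attr(subnet, "p") %||% stats::setNames(rep(NA_real_, nrow(subnet@nodes)),
                                                subnet@nodes$id)
    nodes <- data.frame(id = subnet@nodes$id, type = subnet@nodes$type,
                        direction = NA_character_,
                        p = unname(p[subnet@nodes$id]),
                        stringsAsFactors = FALSE)
    edges <- if (nrow(subnet@edges))
        data.frame(subnet@edges, kind = "metabolic", stringsAsFactors = FALSE)
    else data.frame(source = character(), target = character(),
                    kind = character(), stringsAsFactors = FALSE)
    compounds <- nodes$id[nodes$type == "compound"]
    cg <- compoundGeneTable
    if (!is.null(cg) && nrow(cg)) {
        if (!all(c("compound", "gene") %in% names(cg)))
            stop("compoundGeneTable needs columns compound, gene")
        cg <- unique(data.frame(compound = as.character(cg$compound),
                                gene = toupper(as.character(cg$gene)),
                                stringsAsFactors = FALSE))
        cg <- cg[cg$compound %in% compounds &
                 cg$gene %in% toupper(degTable$gene), , drop = FALSE]
    } else {
        cg <- data.frame(compound = character(), gene = character())
    }
    if (nrow(cg)) {
        gn <- sort(unique(cg$gene))
        dir <- degTable$direction[match(gn, toupper(degTable$gene))]
        nodes <- rbind(nodes, data.frame(id = gn, type = "gene",
                                         direction = dir, p = NA_real_,
                                         stringsAsFactors = FALSE))
        edges <- rbind(edges, data.frame(source = cg$gene, target = cg$compound,
                                         kind = "overlay",
                                         stringsAsFactors = FALSE))
    }
    cnt <- vapply(compounds, function(cp) sum(cg$compound == cp), 0L)
    counts <- data.frame(compound = compounds, nGenes = unname(cnt),
                         p = unname(p[compounds]), stringsAsFactors = FALSE)
    rownames(nodes) <- rownames(edges) <- rownames(counts) <- NULL
    methods::new("DiseaseMetabolicNetwork", nodes = nodes, edges = edges,
                 compoundCounts = counts)
}

#' Rank candidate key metabolites
#'
#' Retained compounds ordered by descending DEG-interaction count, ties
#' broken by smaller diffusion p-value, then lexical id. The top compound
#' is the key-metabolite call.
#'
#' @param network A [DiseaseMetabolicNetwork-class] object.
#' @return data.frame with columns compound, nGenes, p in rank order.
#' @export
rankKeyMetabolites <- function(network) {
    stopifnot(methods::is(network, "DiseaseMetabolicNetwork"))
    cc <- network@compoundCounts
    if (!nrow(cc)) return(cc)
    cc <- cc[order(-cc$nGenes, cc$p, cc$compound), , drop = FALSE]
    rownames(cc) <- NULL
    cc
}

#' Map chemical names to compound identifiers
#'
#' Case-insensitive exact-name lookup in a name-to-id mapping table
#' (standing in for an online compound-ID conversion service). Unmapped
#' names are reported, never silently dropped; duplicate names map to a
#' deduplicated id set.
#'
#' @param chemicalNames character vector of chemical names.
#' @param mappingTable data.frame with columns name, compoundId.
#' @return list with elements `ids` (unique mapped compound ids) and
#'   `unmapped` (names without a mapping).
#' @export
mapCompoundIds <- function(chemicalNames, mappingTable) {
    if (!all(c("name", "compoundId") %in% names(mappingTable)))
        stop("mappingTable needs columns name, compoundId")
    nm <- unique(as.character(chemicalNames))
    if (!length(nm)) return(list(ids = character(), unmapped = character()))
    idx <- match(tolower(nm), tolower(as.character(mappingTable$name)))
    list(ids = unique(as.character(mappingTable$compoundId[idx[!is.na(idx)]])),
         unmapped = nm[is.na(idx)])
}
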