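#' Read a GMT gene-set file
#'
#' Standard tab-separated GMT: one set per line as
#' `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path file path.
#' @return named list of character vectors; each element carries a
#'   `description` attribute.
#' @export
readGMT <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) return(structure(list(), names = character()))
    sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
        if (length(f) < 3L) stop("malformed GMT line: need name, description, >=1 member")
        structure(unique(f[-(1:2)]), description = f[2])
    })
    names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, "", 1L)
    if (anyDuplicated(names(sets))) stop("duplicated set names in GMT")
    sets
}

#' Write a GMT gene-set file
#'
#' @param collection named list of character vectors (optionally with a
#'   `description` attribute per element).
#' @param path file path.
#' @export
writeGMT <- function(collection, path) {
    lines <- vapply(names(collection), function(nm) {
        desc <- attr(collection[[nm]], "description") %||% "na"
        paste(c(nm, desc, collection[[nm]]), collapse = "\t")
    }, "")
    writeLines(lines, path)
}

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` items from a
#' universe of `N` of which `K` are "in the set", the probability of
#' seeing at least `k` set members. Evaluated through the stable
#' distribution-function machinery of `stats::phyper`.
#'
#' @param k observed overlap count (vectorized).
#' @param K set size within the universe.
#' @param n query size within the universe.
#' @param N universe size.
#' @return upper-tail probability in `(0, 1]`.
#' @export
hypergeomUpperTail <- function(k, K, n, N) {
    v <- cbind(k, K, n, N)
    k <- v[, 1]; K <- v[, 2]; n <- v[, 3]; N <- v[, 4]
    if (any(k < 0 | K < 0 | n < 0 | N < 0)) stop("counts must be non-negative")
    if (any(K > N | n > N)) stop("K and n cannot exceed N")
    if (any(k > pmin(K, n))) stop("k cannot exceed min(K, n)")
    as.vector(ifelse(k == 0, 1,
                     stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)))
}

#' Over-representation analysis against a gene-set collection
#'
#' Hypergeometric upper-tail test of a query gene list against each set of
#' a collection, inside a stated gene universe. Query and sets are first
#' intersected with the universe; one row is returned per set passing the
#' overlap-count and raw-p filters. BH-adjusted q-values are computed over
#' all tested sets (before filtering) and reported but not filtered on.
#'
#' @param queryGenes character vector of query genes (e.g. up-regulated
#'   DEGs).
#' @param collection named list of character vectors (see [readGMT()]).
#' @param universe character vector; the assayed gene universe.
#' @param alpha raw-p cut-off (strict; default 0.05).
#' @param minCount minimum overlap count retained (default 1).
#' @return data.frame with columns set, k, K, n, N, p, q, overlap
#'   (comma-separated genes), sorted by p.
#' @export
enrichORA <- function(queryGenes, collection, universe, alpha = 0.05,
                      minCount = 1) {
    universe <- unique(as.character(universe))
    if (!length(universe)) stop("universe must be non-empty")
    query <- intersect(unique(as.character(queryGenes)), universe)
    if (!length(query))
        warning("query is empty after intersection with the universe")
    n <- length(query); N <- length(universe)
    rows <- lapply(names(collection), function(nm) {
        members <- intersect(collection[[nm]], universe)
        ov <- intersect(query, members)
        data.frame(set = nm, k = length(ov), K = length(members), n = n,
                   N = N, overlap = paste(sort(ov), collapse = ","),
                   stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, rows)
    if (is.null(res) || !nrow(res))
        return(data.frame(set = character(), k = integer(), K = integer(),
                          n = integer(), N = integer(), p = numeric(),
                          q = numeric(), overlap = character()))
    res$p <- hypergeomUpperTail(res$k, res$K, res$n, res$N)
    res$q <- adjustBH(res$p)
    res <- res[res$k >= minCount & res$p < alpha, , drop = FALSE]
    res <- res[order(res$p, res$set), c("set", "k", "K", "n", "N", "p", "q", "overlap")]
    rownames(res) <- NULL
    res
}
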