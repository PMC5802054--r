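#' @include neighbors.R
NULL

#' Clustering result
#'
#' @slot labels Per-cell community id: contiguous integers from 0,
#'   ordered by decreasing community size.
#' @slot modularity Modularity Q of the final partition.
#' @slot resolution Resolution parameter gamma.
#' @slot seed Seed of the node-shuffling generator.
#' @aliases ClusterResult
#' @exportClass ClusterResult
setClass("ClusterResult",
    representation(labels = "integer", modularity = "numeric",
                   resolution = "numeric", seed = "integer"))

setValidity("ClusterResult", function(object) {
    lab <- object@labels
    if (length(lab) && !identical(sort(unique(lab)),
                                  seq_len(length(unique(lab))) - 1L))
        return("labels must be contiguous integers starting at 0")
    if (length(object@modularity) == 1 &&
        (object@modularity < -0.5 - 1e-9 || object@modularity > 1 + 1e-9))
        return("modularity out of [-0.5, 1]")
    TRUE
})

setMethod("show", "ClusterResult", function(object) {
    cat(sprintf("ClusterResult: %d cells, %d communities, Q = %.4f (gamma = %g, seed = %d)\n",
                length(object@labels), length(unique(object@labels)),
                object@modularity, object@resolution, object@seed))
})

#' Modularity of a partition
#'
#' \deqn{Q = \sum_c \left[\frac{e_c}{m} - \gamma \left(\frac{d_c}{2m}\right)^2\right]}
#' where \eqn{e_c} is the edge weight inside community c (each
#' undirected edge once), \eqn{d_c} the sum of (weighted) degrees in c,
#' and m the total edge weight.
#'
#' @param W Symmetric weighted adjacency matrix (dense or sparse, zero
#'   diagonal).
#' @param labels Integer community label per node.
#' @param gamma Resolution parameter (default 1).
#' @return The modularity Q.
#' @export
modularityScore <- function(W, labels, gamma = 1) {
    n <- nrow(W)
    if (length(labels) != n)
        stopf("labels has length %d but the graph has %d nodes",
              length(labels), n)
    deg <- rowSumsAny(W)
    m <- sum(deg) / 2
    if (m == 0) return(0)
    lab <- as.integer(factor(labels))
    ## generalMatrix first: symmetric storage keeps only one triangle
    Wt <- methods::as(methods::as(Matrix::Matrix(W, sparse = TRUE),
                                  "generalMatrix"), "TsparseMatrix")
    same <- lab[Wt@i + 1L] == lab[Wt@j + 1L]
    ec <- sum(Wt@x[same]) / 2          # each undirected edge counted twice in W
    dc <- tapply(deg, lab, sum)
    sum(ec) / m - gamma * sum((dc / (2 * m))^2)
}

#' Louvain community detection
#'
#' Two-phase Louvain modularity optimization on the connectivity graph:
#' local moving of nodes (in a seeded shuffled order) to the neighboring
#' community with the largest positive gain until no move improves, then
#' aggregation of communities into a supergraph, repeated until
#' convergence.  Final labels are renumbered by decreasing community
#' size and the modularity of the partition is reported.
#'
#' @param g A [NeighborGraph-class] with connectivities, or a symmetric
#'   weighted adjacency matrix.
#' @param resolution Resolution gamma (default 1; larger values favor
#'   more, smaller communities).
#' @param seed Seed for the node-order shuffle (default 0).
#' @param restarts Number of full seeded runs, keeping the best partition
#'   by modularity.  Default: scaled to graph size (up to 10 on tiny
#'   graphs, where greedy moving is most order-sensitive; 2 on large
#'   ones, where a single run is reliable and restarts are costly).
#' @return A [ClusterResult-class].
#' @export
louvainCluster <- function(g, resolution = 1, seed = 0, restarts = NULL) {
    W <- if (methods::is(g, "NeighborGraph")) {
        if (is.null(g@conn))
            stopf("connectivities missing; run gaussianConnectivities() first")
        g@conn
    } else g
    n <- nrow(W)
    if (is.null(n) || n == 0) stopf("empty graph")
    Wt <- methods::as(methods::as(Matrix::Matrix(W, sparse = TRUE),
                                  "generalMatrix"), "TsparseMatrix")
    keep <- Wt@i < Wt@j & Wt@x > 0
    if (is.null(restarts))
        restarts <- max(2L, min(10L, as.integer(ceiling(256 / n))))
    labels <- .louvainCpp(n, Wt@i[keep], Wt@j[keep], Wt@x[keep],
                          as.numeric(resolution), as.integer(seed),
                          as.integer(restarts))
    ## renumber by decreasing community size (ties: first appearance)
    sizes <- table(labels)
    ord <- order(-as.integer(sizes), as.integer(names(sizes)))
    remap <- integer(length(sizes))
    remap[as.integer(names(sizes)[ord]) + 1L] <- seq_along(ord) - 1L
    labels <- remap[labels + 1L]
    q <- modularityScore(W, labels, gamma = resolution)
    new("ClusterResult", labels = as.integer(labels), modularity = q,
        resolution = as.numeric(resolution), seed = as.integer(seed))
}
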