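#' @include AnnMatrix-class.R
NULL

#' NeighborGraph: the shared kNN graph of observations
#'
#' One graph object derived from a single matrix of coordinates (by
#' convention PCA scores), reused by every downstream tool — diffusion
#' maps, pseudotime, clustering, and layout — so all of them see a
#' consistent representation of the data.
#'
#' Built in stages: [knnGraph()] populates the exact k-nearest-neighbor
#' distances; [gaussianConnectivities()] adds adaptive Gaussian edge
#' weights \eqn{W_{ij} = \exp(-d_{ij}^2 / (\sigma_i^2 + \sigma_j^2))}
#' with \eqn{\sigma_i} the distance to the k-th neighbor, symmetrized by
#' elementwise maximum; [transitionMatrix()] adds the row-stochastic
#' random-walk operator (optionally density-normalized) and its symmetric
#' conjugate.
#'
#' @slot nObs Number of observations.
#' @slot k Neighbors per node.
#' @slot nnIdx,nnDist n-by-k matrices: for each observation, the indices
#'   and Euclidean distances of its k nearest neighbors (self excluded,
#'   ties broken by lower index), sorted by increasing distance.
#' @slot dist Sparse n-by-n matrix holding the same kNN distances.
#' @slot conn Sparse symmetric connectivity matrix W, entries in (0, 1].
#' @slot sigmas Per-node kernel width.
#' @slot trans Row-stochastic transition matrix T.
#' @slot transSym Symmetric conjugate of T (same spectrum).
#' @slot degreeNorm Per-node density normalizer z (row sums of W), or
#'   `numeric(0)` when density normalization is off.
#' @slot dSum Row sums of the (possibly density-normalized) kernel.
#' @aliases NeighborGraph
#' @exportClass NeighborGraph
setClass("NeighborGraph",
    representation(nObs = "integer", k = "integer",
                   nnIdx = "matrix", nnDist = "matrix",
                   dist = "ANY", conn = "ANY",
                   sigmas = "numeric", trans = "ANY", transSym = "ANY",
                   degreeNorm = "numeric", dSum = "numeric"),
    prototype(dist = NULL, conn = NULL, trans = NULL, transSym = NULL,
              sigmas = numeric(0), degreeNorm = numeric(0),
              dSum = numeric(0)))

setValidity("NeighborGraph", function(object) {
    msg <- character(0)
    n <- object@nObs
    if (nrow(object@nnIdx) != n || ncol(object@nnIdx) != object@k)
        msg <- c(msg, "nnIdx must be nObs x k")
    if (!identical(dim(object@nnIdx), dim(object@nnDist)))
        msg <- c(msg, "nnIdx and nnDist must have the same shape")
    if (any(object@nnIdx == matrix(seq_len(n), n, object@k)))
        msg <- c(msg, "self must not appear in neighbor lists")
    if (length(msg)) msg else TRUE
})

setMethod("show", "NeighborGraph", function(object) {
    parts <- c("distances",
               if (!is.null(object@conn)) "connectivities",
               if (!is.null(object@trans)) "transitions")
    cat(sprintf("NeighborGraph: %d observations, k = %d [%s]\n",
                object@nObs, object@k, paste(parts, collapse = ", ")))
})

#' @rdname knnDistances
#' @export
setMethod("knnDistances", "NeighborGraph", function(x) x@dist)

#' @rdname knnDistances
#' @export
setMethod("connectivities", "NeighborGraph", function(x) x@conn)

#' @rdname knnDistances
#' @export
setMethod("kernelWidths", "NeighborGraph", function(x) x@sigmas)

#' @rdname knnDistances
#' @export
setMethod("transitions", "NeighborGraph", function(x) x@trans)

#' Blocked pairwise Euclidean distances
#'
#' `blockedPairwiseDistances` returns an iterator over row blocks of the
#' full pairwise distance matrix: each call yields
#' `list(rows = <row indices>, block = <length(rows) x n matrix>)` and
#' `NULL` when exhausted.  Every block is computed via the quadratic
#' expansion \eqn{\sqrt{\max(0, \|q\|^2 + \|x\|^2 - 2 Q X^\top)}} so the
#' dominant cost is one matrix product per block and peak memory stays at
#' `O(blockSize * n)`.  `pairwiseDistances` assembles the full matrix
#' from the same blocks.
#'
#' @param X Numeric n-by-d matrix (d >= 1).
#' @param blockSize Rows per block (>= 1).
#' @return For `blockedPairwiseDistances`, a function (the iterator); for
#'   `pairwiseDistances`, the full n-by-n distance matrix.
#' @export
blockedPairwiseDistances <- function(X, blockSize) {
    X <- as.matrix(X)
    if (ncol(X) == 0) stopf("X must have at least one column (d >= 1)")
    if (blockSize < 1) stopf("blockSize must be >= 1")
    n <- nrow(X)
    start <- 1L
    function() {
        if (start > n) return(NULL)
        rows <- start:min(n, start + as.integer(blockSize) - 1L)
        start <<- rows[length(rows)] + 1L
        list(rows = rows, block = .distBlockCpp(X, rows))
    }
}

#' @rdname blockedPairwiseDistances
#' @export
pairwiseDistances <- function(X, blockSize = nrow(X)) {
    it <- blockedPairwiseDistances(X, blockSize)
    n <- nrow(X)
    out <- matrix(0, n, n)
    while (!is.null(b <- it())) out[b$rows, ] <- b$block
    out
}

#' Build the exact kNN graph
#'
#' For every observation, the `k` nearest other observations by Euclidean
#' distance, computed with the blocked distance engine (results are
#' independent of `blockSize`).  Ties are broken deterministically by the
#' lower index.
#'
#' @param X Numeric n-by-d matrix of coordinates (by convention PCA
#'   scores), or an [AnnMatrix-class] whose `X` is used directly.
#' @param k Number of neighbors, `1 <= k <= n - 1`.
#' @param blockSize Rows per distance block (default 1024).
#' @return A [NeighborGraph-class] with distances populated.
#' @export
knnGraph <- function(X, k, blockSize = 1024) {
    if (methods::is(X, "AnnMatrix")) X <- as.matrix(xData(X))
    X <- as.matrix(X)
    n <- nrow(X)
    if (k < 1 || k >= n) stopf("k must satisfy 1 <= k <= n - 1 (n = %d)", n)
    res <- .knnBlockedCpp(X, as.integer(k), as.integer(blockSize))
    dist <- Matrix::sparseMatrix(i = rep(seq_len(n), k),
                                 j = as.vector(res$idx),
                                 x = as.vector(res$dist),
                                 dims = c(n, n), repr = "C")
    new("NeighborGraph", nObs = n, k = as.integer(k),
        nnIdx = res$idx, nnDist = res$dist, dist = dist)
}

#' Adaptive Gaussian connectivities
#'
#' Kernel width \eqn{\sigma_i} is the distance from observation i to its
#' k-th nearest neighbor (local scaling); each stored kNN pair gets the
#' weight \eqn{W_{ij} = \exp(-d_{ij}^2/(\sigma_i^2 + \sigma_j^2))}, the
#' matrix is symmetrized by elementwise maximum (union of the two
#' neighborhoods), and the diagonal stays zero.  Observations whose k-th
#' neighbor is at distance 0 (saturating duplicates) get the smallest
#' positive width, with a warning.
#'
#' @param g A [NeighborGraph-class] from [knnGraph()].
#' @return `g` with `conn` and `sigmas` populated.
#' @export
gaussianConnectivities <- function(g) {
    stopifnot(methods::is(g, "NeighborGraph"))
    n <- g@nObs
    sig <- g@nnDist[, g@k]
    if (any(sig == 0)) {
        pos <- sig[sig > 0]
        if (!length(pos))
            stopf("all kernel widths are zero (all points identical?)")
        warnf("%d observation(s) with zero kernel width; using the smallest positive width", sum(sig == 0))
        sig[sig == 0] <- min(pos)
    }
    i <- rep(seq_len(n), g@k)
    j <- as.vector(g@nnIdx)
    d <- as.vector(g@nnDist)
    w <- exp(-d^2 / (sig[i]^2 + sig[j]^2))
    W <- Matrix::sparseMatrix(i = i, j = j, x = w, dims = c(n, n), repr = "C")
    Wt <- Matrix::t(W)
    W <- (W + Wt + abs(W - Wt)) / 2    # elementwise max, symmetric by construction
    g@conn <- methods::as(W, "CsparseMatrix")
    g@sigmas <- sig
    g
}

#' Random-walk transition operator
#'
#' From the connectivities W: optionally removes sampling-density bias by
#' the conjugation \eqn{\tilde K_{ij} = W_{ij}/(z_i z_j)} with
#' \eqn{z_i = \sum_j W_{ij}}, then row-normalizes to the stochastic
#' matrix \eqn{T_{ij} = \tilde K_{ij} / \sum_j \tilde K_{ij}}.  The
#' symmetric conjugate \eqn{T_{sym} = D^{-1/2} \tilde K D^{-1/2}} (same
#' spectrum as T) is stored for the eigensolver.
#'
#' @param g A [NeighborGraph-class] with connectivities.
#' @param densityNormalize Apply the density correction? (default `TRUE`).
#' @return `g` with `trans`, `transSym`, `degreeNorm`, `dSum` populated.
#' @export
transitionMatrix <- function(g, densityNormalize = TRUE) {
    stopifnot(methods::is(g, "NeighborGraph"))
    if (is.null(g@conn)) stopf("connectivities missing; run gaussianConnectivities() first")
    W <- g@conn
    z <- Matrix::rowSums(W)
    if (any(z == 0))
        stopf("isolated observation(s) in the graph; increase k")
    K <- W
    if (densityNormalize) {
        iz <- Matrix::Diagonal(x = 1 / z)
        K <- iz %*% W %*% iz
        g@degreeNorm <- z
    } else {
        g@degreeNorm <- numeric(0)
    }
    D <- Matrix::rowSums(K)
    g@trans <- methods::as(Matrix::Diagonal(x = 1 / D) %*% K, "CsparseMatrix")
    s <- 1 / sqrt(D)
    g@transSym <- methods::as(
        Matrix::Diagonal(x = s) %*% K %*% Matrix::Diagonal(x = s),
        "CsparseMatrix")
    g@dSum <- D
    g
}

#' One-call graph construction
#'
#' Convenience wrapper: [knnGraph()] then [gaussianConnectivities()] then
#' [transitionMatrix()].
#'
#' @inheritParams knnGraph
#' @inheritParams transitionMatrix
#' @return A fully populated [NeighborGraph-class].
#' @export
buildNeighborGraph <- function(X, k, blockSize = 1024,
                               densityNormalize = TRUE) {
    transitionMatrix(gaussianConnectivities(knnGraph(X, k, blockSize)),
                     densityNormalize = densityNormalize)
}
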