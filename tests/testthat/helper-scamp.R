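# Shared fixtures and oracles for the test suite.

# Small random annotated matrix with both axis tables and nested uns.
makeRandomAnnMatrix <- function(nObs = 20, nVar = 10, sparse = FALSE,
                                seed = 1) {
    set.seed(seed)
    X <- if (sparse) {
        Matrix::rsparsematrix(nObs, nVar, density = 0.3,
                              rand.x = function(n) stats::rpois(n, 4) + 1)
    } else {
        matrix(stats::rpois(nObs * nVar, 5), nObs, nVar)
    }
    AnnMatrix(X,
              obsNames = paste0("c", seq_len(nObs)),
              varNames = paste0("g", seq_len(nVar)),
              obs = data.frame(
                  batch = factor(rep_len(c("b1", "b2"), nObs)),
                  depth = stats::runif(nObs)),
              var = data.frame(kind = rep_len(c("x", "y"), nVar)),
              uns = list(note = "fixture", params = list(alpha = 0.5,
                         ids = 1:3), flag = TRUE))
}

# Best label-matching agreement between two small partitions.
permAgreement <- function(a, b) {
    perms <- function(v) {
        if (length(v) <= 1) return(list(v))
        do.call(c, lapply(seq_along(v), function(i)
            lapply(perms(v[-i]), function(p) c(v[i], p))))
    }
    labs <- sort(unique(c(a, b)))
    best <- 0
    for (p in perms(labs))
        best <- max(best, mean(p[match(a, labs)] == b))
    best
}

# All set partitions of n elements as label vectors (restricted growth
# strings); Bell(8) = 4140.
allPartitions <- function(n) {
    out <- list()
    rec <- function(labels, mx) {
        i <- length(labels) + 1L
        if (i > n) { out[[length(out) + 1L]] <<- labels; return(invisible()) }
        for (b in seq_len(mx + 1L)) rec(c(labels, b), max(mx, b))
        invisible()
    }
    rec(integer(0), 0L)
    out
}

# Fast dense modularity for brute-force searches on tiny graphs.
denseModularity <- function(W, labels, gamma = 1) {
    deg <- rowSums(W)
    m <- sum(deg) / 2
    if (m == 0) return(0)
    same <- outer(labels, labels, "==")
    ec <- sum(W[same]) / 2
    dc <- tapply(deg, labels, sum)
    ec / m - gamma * sum((dc / (2 * m))^2)
}

bruteForceBestModularity <- function(W, gamma = 1) {
    parts <- allPartitions(nrow(W))
    best <- -Inf; bestLab <- NULL
    for (p in parts) {
        q <- denseModularity(W, p, gamma)
        if (q > best) { best <- q; bestLab <- p }
    }
    list(q = best, labels = bestLab)
}

# The classic two-triangles-plus-bridge graph (nodes 1:3 and 4:6).
twoCliqueBridge <- function() {
    W <- matrix(0, 6, 6)
    for (e in list(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6),
                   c(3, 4))) {
        W[e[1], e[2]] <- 1; W[e[2], e[1]] <- 1
    }
    W
}

# NeighborGraph directly from a symmetric 0/1 connectivity matrix (for
# spectral tests on hand-built graphs).
graphFromConn <- function(W) {
    W <- methods::as(Matrix::Matrix(W, sparse = TRUE), "generalMatrix")
    n <- nrow(W)
    k <- min(Matrix::rowSums(W != 0))
    nnIdx <- t(apply(as.matrix(W), 1, function(r) which(r != 0)[seq_len(k)]))
    g <- new("NeighborGraph", nObs = as.integer(n), k = as.integer(k),
             nnIdx = matrix(as.integer(nnIdx), n, k),
             nnDist = matrix(1, n, k), dist = W,
             conn = methods::as(W, "CsparseMatrix"))
    scamp::transitionMatrix(g)
}

expect_no_error <- function(expr) expect_error(expr, NA)
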