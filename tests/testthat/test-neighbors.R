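test_that("blocked distances match a double-loop Euclidean oracle", {
    set.seed(1)
    X <- matrix(rnorm(500), 50, 10)
    oracle <- matrix(0, 50, 50)
    for (i in 1:50) for (j in 1:50)
        oracle[i, j] <- sqrt(sum((X[i, ] - X[j, ])^2))
    for (bs in c(1, 7, 50)) {
        expect_lt(max(abs(pairwiseDistances(X, bs) - oracle)), 1e-6)
    }
    ## the iterator yields consecutive row blocks that tile the matrix
    it <- blockedPairwiseDistances(X, 7)
    rows <- integer(0)
    while (!is.null(b <- it())) {
        expect_equal(dim(b$block), c(length(b$rows), 50))
        rows <- c(rows, b$rows)
    }
    expect_equal(rows, 1:50)
})

test_that("degenerate distance inputs are handled", {
    X <- rbind(c(1, 2), c(1, 2), c(4, 6))
    D <- pairwiseDistances(X)
    expect_equal(D[1, 2], 0)                       # identical rows, clamped
    expect_equal(pairwiseDistances(matrix(c(0, 3), 2, 1))[1, 2], 3)
    expect_error(pairwiseDistances(matrix(numeric(0), 2, 0)), "column")
})

test_that("kNN excludes self, breaks ties by lower index, and is block-invariant", {
    X <- matrix(c(0, 1, 2, 3), 4, 1)
    g <- knnGraph(X, k = 1)
    expect_equal(as.vector(g@nnIdx), c(2, 1, 2, 3))  # middle points pick lower

    set.seed(2)
    Y <- matrix(rnorm(200), 20, 10)
    gs <- lapply(c(1, 3, 20), function(bs) knnGraph(Y, k = 4, blockSize = bs))
    for (g2 in gs[-1]) {
        expect_identical(g2@nnIdx, gs[[1]]@nnIdx)
        ## distances agree up to BLAS accumulation round-off
        expect_lt(max(abs(g2@nnDist - gs[[1]]@nnDist)), 1e-9)
    }
    expect_true(all(gs[[1]]@nnIdx != matrix(1:20, 20, 4)))
    ## brute-force oracle
    D <- as.matrix(dist(Y)); diag(D) <- Inf
    oracleIdx <- t(apply(D, 1, function(r) order(r)[1:4]))
    expect_equal(unname(gs[[1]]@nnIdx), unname(oracleIdx))
    expect_error(knnGraph(Y, k = 20), "k must satisfy")
})

test_that("permuting input rows permutes the graph consistently", {
    set.seed(3)
    X <- matrix(rnorm(150), 15, 10)
    g <- knnGraph(X, k = 3)
    perm <- sample(15)
    gp <- knnGraph(X[perm, ], k = 3)
    ## neighbor sets map through the permutation: row i of X is row
    ## inv[i] of the permuted matrix, and neighbor ids map back via perm
    inv <- match(seq_len(15), perm)
    for (i in 1:15)
        expect_setequal(perm[gp@nnIdx[inv[i], ]], g@nnIdx[i, ])
})

test_that("gaussian connectivities are symmetric with the adaptive kernel", {
    set.seed(4)
    X <- matrix(rnorm(60), 12, 5)
    g <- gaussianConnectivities(knnGraph(X, k = 4))
    W <- g@conn
    expect_identical(as.matrix(W), t(as.matrix(W)))   # exact symmetry
    expect_true(all(W@x > 0 & W@x <= 1))
    expect_equal(unname(g@sigmas), unname(g@nnDist[, 4]))
    expect_true(all(Matrix::diag(W) == 0))

    ## stored pair weights follow exp(-d^2/(s_i^2+s_j^2)) before symmetrization
    i <- 1; j <- g@nnIdx[1, 2]; d <- g@nnDist[1, 2]
    expected <- exp(-d^2 / (g@sigmas[i]^2 + g@sigmas[j]^2))
    expect_gte(W[i, j], expected - 1e-12)  # max-symmetrization can only raise

    ## duplicated points saturating the list: width fallback + weight 1
    Xd <- rbind(c(0, 0), c(0, 0), c(5, 5), c(9, 9))
    expect_warning(gd <- gaussianConnectivities(knnGraph(Xd, k = 1)),
                   "zero kernel width")
    expect_equal(gd@conn[1, 2], 1)
})

test_that("connectivity decreases with distance for fixed widths", {
    X <- matrix(c(0, 1, 3), 3, 1)
    g <- gaussianConnectivities(knnGraph(X, k = 2))
    expect_gt(g@conn[1, 2], g@conn[1, 3])
})

test_that("transition operator is row-stochastic with unit top eigenvalue", {
    set.seed(5)
    X <- matrix(rnorm(100), 10, 10)
    g <- buildNeighborGraph(X, k = 4)
    T1 <- as.matrix(g@trans)
    expect_lt(max(abs(rowSums(T1) - 1)), 1e-10)
    expect_true(all(T1 >= 0))
    ev <- eigen(T1)$values
    expect_equal(max(Mod(ev)), 1, tolerance = 1e-8)

    ## T and its symmetric conjugate share the spectrum
    evs <- eigen(as.matrix(g@transSym), symmetric = TRUE)$values
    expect_equal(sort(Re(ev)), sort(evs), tolerance = 1e-8)

    ## degree normalizer exposed when density-normalizing
    expect_equal(unname(g@degreeNorm), unname(Matrix::rowSums(g@conn)))
    g2 <- transitionMatrix(gaussianConnectivities(knnGraph(X, 4)),
                           densityNormalize = FALSE)
    expect_lt(max(abs(Matrix::rowSums(g2@trans) - 1)), 1e-10)
})
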