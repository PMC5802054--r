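test_that("diffusion map has unit top eigenvalue with constant first component", {
    set.seed(1)
    X <- matrix(rnorm(50 * 5), 50, 5)
    g <- buildNeighborGraph(X, k = 8)
    dm <- diffusionMap(g, nComps = 10)
    expect_equal(dm@eigenvalues[1], 1, tolerance = 1e-8)
    psi0 <- dm@components[, 1]
    expect_lt(sd(psi0) / abs(mean(psi0)), 1e-6)
    expect_true(all(diff(dm@eigenvalues) < 1e-12))
    ## eigenvectors of the symmetric conjugate are orthonormal
    expect_lt(max(abs(crossprod(dm@vectors) - diag(11))), 1e-8)
})

test_that("two disconnected cliques give eigenvalue 1 with multiplicity 2", {
    W <- matrix(0, 10, 10)
    W[1:5, 1:5] <- 1; W[6:10, 6:10] <- 1
    diag(W) <- 0
    g <- graphFromConn(W)
    dm <- diffusionMap(g, nComps = 8)
    expect_equal(dm@eigenvalues[1:2], c(1, 1), tolerance = 1e-8)
    expect_lt(dm@eigenvalues[3], 1 - 1e-8)
    ## dpt excludes the disconnected direction with a warning
    expect_warning(dptDistance(dm, 1, 6), "eigenvalue >= 1")
})

test_that("dpt is a metric equal to the accumulated-transition row distance", {
    set.seed(3)
    X <- matrix(rnorm(15 * 4), 15, 4)
    g <- buildNeighborGraph(X, k = 5)
    dm <- diffusionMap(g, nComps = 14)

    ## explicit oracle: M = (I - (T_sym - u0 u0^T))^-1 - I, row distances
    Ts <- as.matrix(g@transSym)
    e <- eigen(Ts, symmetric = TRUE)
    u0 <- e$vectors[, 1]
    M <- solve(diag(15) - (Ts - u0 %o% u0)) - diag(15)
    Dm <- as.matrix(dist(M))
    for (x in 1:14) for (y in (x + 1):15) {
        expect_lt(abs(dptDistance(dm, x, y, nDcs = 14) - Dm[x, y]) / Dm[x, y],
                  1e-6)
    }

    ## metric axioms, exhaustively on 20 cells
    set.seed(4)
    X2 <- matrix(rnorm(20 * 3), 20, 3)
    dm2 <- diffusionMap(buildNeighborGraph(X2, k = 6), 10)
    D <- sapply(1:20, function(y) dptDistance(dm2, y, 1:20))
    expect_equal(diag(D), rep(0, 20))
    expect_equal(D, t(D))
    for (x in 1:20) for (y in 1:20) for (z in 1:20)
        if (D[x, z] > D[x, y] + D[y, z] + 1e-12)
            fail(sprintf("triangle inequality violated at (%d,%d,%d)", x, y, z))
    succeed()
})

test_that("pseudotime is anchored at the root, normalized, and orders a chain", {
    set.seed(5)
    pos <- sort(runif(100))
    X <- cbind(10 * pos, matrix(rnorm(200, 0, 0.1), 100, 2))
    g <- buildNeighborGraph(X, k = 10)
    dm <- diffusionMap(g, 10)
    root <- which.min(pos)
    r <- dptPseudotime(dm, root)
    expect_equal(r@pseudotime[root], 0)
    expect_equal(max(r@pseudotime), 1)
    expect_gte(cor(r@pseudotime, pos, method = "spearman"), 0.95)
    expect_error(dptPseudotime(dm, 200), "root")

    ## invariant under permutation of cell order
    perm <- sample(100)
    dmp <- diffusionMap(buildNeighborGraph(X[perm, ], k = 10), 10)
    rp <- dptPseudotime(dmp, which(perm == root))
    expect_equal(rp@pseudotime[order(perm)], r@pseudotime, tolerance = 1e-6)
})

test_that("branching detection labels a bifurcation and leaves a line whole", {
    br <- generateBranching(300, 300, seed = 0)
    r <- logTransform(normalizeTotal(br))
    g <- buildNeighborGraph(runPca(r, 20, seed = 0)@scores, k = 15)
    dm <- diffusionMap(g, 15)
    root <- which.min(obsTable(r)$true_time)

    ## nBranchings = 0: single segment
    r0 <- detectBranching(dm, root, nBranchings = 0)
    expect_true(all(r0@segments == 0))

    r1 <- detectBranching(dm, root, nBranchings = 1)
    tb <- as.integer(as.character(obsTable(r)$true_branch))
    expect_equal(sort(unique(r1@segments)), 0:2)
    expect_equal(r1@segments[root], 0L)          # trunk holds the root
    expect_gte(permAgreement(r1@segments, tb), 0.9)

    ## unbranched fixture: the split degenerates, >= 90% stay together
    lin <- generateBranching(300, 300, seed = 1, branchTime = 0.999)
    rl <- logTransform(normalizeTotal(lin))
    gl <- buildNeighborGraph(runPca(rl, 20, seed = 0)@scores, k = 15)
    dl <- detectBranching(diffusionMap(gl, 15),
                          which.min(obsTable(rl)$true_time), nBranchings = 1)
    expect_gte(max(table(dl@segments)) / 300, 0.9)
})

test_that("force-directed layout balances a single edge near the optimal length", {
    W <- Matrix::sparseMatrix(i = c(1, 2), j = c(2, 1), x = c(1, 1),
                              dims = c(2, 2))
    g <- new("NeighborGraph", nObs = 2L, k = 1L,
             nnIdx = matrix(c(2L, 1L), 2, 1), nnDist = matrix(1, 2, 1),
             dist = W, conn = methods::as(W, "CsparseMatrix"))
    ly <- frLayout(g, iterations = 200, seed = 1)
    d <- sqrt(sum((ly@coords[1, ] - ly@coords[2, ])^2))
    kOpt <- 1   # area = n = 2, k = sqrt(area/n)
    expect_lt(abs(d - kOpt) / kOpt, 0.2)

    ly2 <- frLayout(g, iterations = 200, seed = 1)
    expect_identical(ly@coords, ly2@coords)
})

test_that("layout coordinates stay finite on larger graphs", {
    set.seed(6)
    X <- matrix(rnorm(500 * 5), 500, 5)
    g <- buildNeighborGraph(X, k = 8)
    ly <- frLayout(g, iterations = 30, seed = 2)
    expect_true(all(is.finite(ly@coords)))
    expect_equal(dim(ly@coords), c(500, 2))
})
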