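test_that("filterAxis removes low-coverage cells and genes and reports them", {
    X <- matrix(c(5, 0, 2,
                  0, 0, 0,
                  3, 0, 1), 3, 3, byrow = TRUE)
    a <- AnnMatrix(X, obsNames = c("c1", "c2", "c3"),
                   varNames = c("g1", "g2", "g3"))
    f <- filterAxis(a, "obs", minCounts = 1)
    expect_equal(obsNames(f), c("c1", "c3"))
    expect_equal(uns(f)$filter_log[[1]]$removed, "c2")

    ## gene detected in 1 of 3 cells, threshold 2 -> removed
    g <- filterAxis(a, "var", minEntities = 2)
    expect_equal(varNames(g), c("g1", "g3"))

    expect_error(filterAxis(a, "obs"), "at least one")
    expect_error(filterAxis(a, "obs", minCounts = 100), "review the thresholds")
})

test_that("normalizeTotal scales rows to the target and defaults to the median", {
    a <- AnnMatrix(matrix(c(1, 3), 1, 2))
    n <- normalizeTotal(a, targetSum = 10)
    expect_equal(as.vector(xData(n)), c(2.5, 7.5))

    b <- AnnMatrix(matrix(c(1, 1, 2, 2, 3, 3), 3, 2, byrow = TRUE))
    nb <- normalizeTotal(b)   # row sums 2, 4, 6 -> target 4
    expect_equal(unname(rowSums(xData(nb))), c(4, 4, 4))

    z <- AnnMatrix(matrix(c(1, 1, 0, 0), 2, 2, byrow = TRUE))
    expect_warning(nz <- normalizeTotal(z, 10), "zero total")
    expect_equal(as.vector(xData(nz)[2, ]), c(0, 0))

    neg <- AnnMatrix(matrix(c(-1, 2), 1, 2))
    expect_error(normalizeTotal(neg), "nonnegative")
})

test_that("normalized row sums hit the target within 1e-8 relative error", {
    a <- makeRandomAnnMatrix(30, 15, sparse = TRUE, seed = 3)
    n <- normalizeTotal(a, 1e4)
    rs <- Matrix::rowSums(xData(n))
    nz <- Matrix::rowSums(xData(a)) > 0
    expect_true(all(abs(rs[nz] - 1e4) / 1e4 < 1e-8))
})

test_that("logTransform is exact, sparsity-preserving and idempotence-guarded", {
    a <- AnnMatrix(matrix(c(0, exp(1) - 1), 1, 2))
    l <- logTransform(a)
    expect_equal(as.vector(xData(l)), c(0, 1))
    expect_true(uns(l)$log1p)
    expect_warning(l2 <- logTransform(l), "already")
    expect_equal(xData(l2), xData(l))

    s <- makeRandomAnnMatrix(10, 6, sparse = TRUE)
    ls <- logTransform(s)
    expect_equal(length(xData(ls)@x), length(xData(s)@x))
})

test_that("highly variable gene standardization matches a direct recomputation", {
    ## 6 genes, 2 bins, hand-checkable layout
    set.seed(5)
    X <- cbind(
        matrix(rpois(30, 2), 10, 3),             # low-mean bin
        matrix(rpois(30, 20), 10, 3))            # high-mean bin
    a <- AnnMatrix(X)
    hv <- highlyVariableGenes(a, nTop = 2, nBins = 2, flavor = "meanstd")

    mu <- colMeans(X)
    dd <- apply(X, 2, var) / mu
    z <- numeric(6)
    for (b in split(seq_len(6), cut(mu, unique(quantile(mu, c(0, .5, 1))),
                                    include.lowest = TRUE)))
        z[b] <- (dd[b] - mean(dd[b])) / sd(dd[b])
    expect_equal(hv$dispersions_norm, z, ignore_attr = TRUE)
    expect_equal(which(hv$highly_variable),
                 sort(order(z, decreasing = TRUE)[1:2]))

    ## medianmad flavor recomputation
    hv2 <- highlyVariableGenes(a, nTop = 2, nBins = 2, flavor = "medianmad")
    z2 <- numeric(6)
    for (b in split(seq_len(6), cut(mu, unique(quantile(mu, c(0, .5, 1))),
                                    include.lowest = TRUE)))
        z2[b] <- (dd[b] - median(dd[b])) / mad(dd[b])
    expect_equal(hv2$dispersions_norm, z2, ignore_attr = TRUE)
})

test_that("constant and undetected genes are never preferred", {
    X <- cbind(matrix(rpois(40, 5) + 1, 10, 4), 3, 0)
    a <- AnnMatrix(X)
    hv <- suppressWarnings(highlyVariableGenes(a, nTop = 3, nBins = 2))
    expect_equal(hv$dispersions[5], 0)   # constant gene: var 0
    expect_equal(hv$dispersions[6], 0)   # undetected gene: defined 0
    expect_false(hv$highly_variable[6])

    hvAll <- suppressWarnings(highlyVariableGenes(a, nTop = 6, nBins = 2))
    expect_true(all(hvAll$highly_variable))
    expect_error(highlyVariableGenes(a, nTop = 7), "exceeds")
})

test_that("HVG selection is permutation-equivariant", {
    a <- makeRandomAnnMatrix(40, 12, seed = 9)
    hv <- highlyVariableGenes(a, nTop = 4, nBins = 3)
    perm <- sample(12)
    hvp <- highlyVariableGenes(a[, perm], nTop = 4, nBins = 3)
    expect_equal(hvp$highly_variable, hv$highly_variable[perm])
    expect_equal(hvp$dispersions_norm, hv$dispersions_norm[perm],
                 ignore_attr = TRUE)
})

test_that("regressOut produces exact residuals", {
    set.seed(2)
    n <- 30
    cov1 <- rnorm(n); cov2 <- runif(n)
    X <- cbind(2 + 3 * cov1,                     # exactly linear -> residual 0
               matrix(rnorm(n * 4), n, 4))
    a <- AnnMatrix(X, obs = data.frame(c1 = cov1, c2 = cov2))
    r <- regressOut(a, c("c1", "c2"))
    R <- as.matrix(xData(r))
    expect_lt(max(abs(R[, 1])), 1e-10)
    ## residuals orthogonal to covariates and mean zero
    expect_lt(max(abs(crossprod(cbind(cov1, cov2), R))), 1e-8)
    expect_lt(max(abs(colMeans(R))), 1e-8)

    ## constant covariate: residuals equal centered expression (collinear
    ## with intercept, dropped with a warning)
    b <- AnnMatrix(X, obs = data.frame(c1 = rep(2, n)))
    expect_warning(rb <- regressOut(b, "c1"), "collinear")
    expect_equal(as.matrix(xData(rb)), scale(X, scale = FALSE),
                 ignore_attr = TRUE)
})

test_that("scaleClip standardizes with sample sd and clips symmetrically", {
    a <- AnnMatrix(cbind(c(1, 2, 3), c(7, 7, 7)))
    s <- scaleClip(a)
    expect_equal(as.vector(xData(s)[, 1]), c(-1, 0, 1))  # sd(1,2,3) = 1
    expect_equal(as.vector(xData(s)[, 2]), c(0, 0, 0))

    b <- AnnMatrix(matrix(c(rep(0, 99), 120), 100, 1))
    sb <- scaleClip(b, maxValue = 5)
    expect_equal(max(xData(sb)), 5)
    expect_equal(min(xData(sb)), max(-5, min(scale(matrix(c(rep(0, 99), 120))))))

    r <- makeRandomAnnMatrix(25, 8, seed = 13)
    sr <- scaleClip(r)
    expect_lt(max(abs(colMeans(xData(sr)))), 1e-8)
    expect_equal(unname(apply(xData(sr), 2, sd)), rep(1, 8))
})

test_that("pca satisfies its reconstruction and determinism contracts", {
    ## 2-D points on a line
    t <- seq(-1, 1, length.out = 20)
    a <- AnnMatrix(cbind(t, 2 * t))
    p <- runPca(a, 2)
    expect_equal(p@explainedVarianceRatio, c(1, 0), tolerance = 1e-10)

    r <- makeRandomAnnMatrix(15, 6, seed = 21)
    X <- as.matrix(xData(r))
    pf <- runPca(r, 6)
    Xc <- scale(X, scale = FALSE)
    expect_lt(max(abs(pf@scores %*% t(pf@components) - Xc)), 1e-8)
    ## loadings orthonormal, scores covariance diagonal
    expect_lt(max(abs(crossprod(pf@components) - diag(6))), 1e-8)
    cv <- cov(pf@scores)
    expect_lt(max(abs(cv - diag(diag(cv)))), 1e-8)
    ## non-increasing variance ratios summing to <= 1
    expect_true(all(diff(pf@explainedVarianceRatio) < 1e-12))
    expect_lte(sum(pf@explainedVarianceRatio), 1 + 1e-9)

    big <- makeRandomAnnMatrix(300, 120, seed = 22)
    p1 <- runPca(big, 10, seed = 4)
    p2 <- runPca(big, 10, seed = 4)
    expect_identical(p1@scores, p2@scores)
    ## sign convention: largest-magnitude loading entry positive
    expect_true(all(apply(p1@components, 2,
                          function(v) v[which.max(abs(v))] > 0)))
    expect_error(runPca(r, 20), "exceeds")
})

test_that("recipe equals the manual chain and logs its seven steps", {
    a <- generateMixture(200, 120, 3, separation = 6, seed = 8)
    r <- recipeBenchmark(a, nTopGenes = 50)
    expect_equal(dim(r)[2], 50)
    expect_lte(dim(r)[1], 200)
    expect_length(uns(r)$recipe_log, 7)

    m <- filterAxis(a, "obs", minCounts = 1)
    m <- normalizeTotal(m)
    hv <- highlyVariableGenes(m, nTop = 50, flavor = "medianmad")
    m <- m[, hv$highly_variable]
    m <- normalizeTotal(m)
    m <- logTransform(m)
    m <- scaleClip(m, 10)
    expect_equal(as.matrix(xData(r)), as.matrix(xData(m)))
    expect_equal(varNames(r), varNames(m))
})
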