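makeGroupedMatrix <- function() {
    ## gene 1 separates the printed example groups; genes 2-4 random
    set.seed(1)
    X <- cbind(c(3, 4, 5, 1, 1, 2),
               matrix(rpois(18, 5), 6, 3))
    AnnMatrix(X, obs = data.frame(grp = factor(rep(c("A", "B"), each = 3))),
              uns = list(log1p = TRUE))
}

test_that("Welch statistic matches the hand-computed 3-vs-3 example", {
    a <- makeGroupedMatrix()
    rr <- rankGenesGroups(a, "grp", method = "ttest", nGenes = 4)
    tA <- rr@tables$A
    ## group [3,4,5] vs rest [1,1,2]: t = (4 - 4/3)/sqrt(1/3 + (1/3)/3) = 4
    expect_equal(tA$score[tA$gene == "var1"], 4, tolerance = 1e-12)

    ## agreement with stats::t.test on every gene
    X <- as.matrix(xData(a))
    for (j in 1:4) {
        tt <- t.test(X[1:3, j], X[4:6, j])
        expect_equal(tA$score[tA$gene == paste0("var", j)],
                     unname(tt$statistic), tolerance = 1e-10)
        expect_equal(tA$pval[tA$gene == paste0("var", j)],
                     tt$p.value, tolerance = 1e-10)
    }
})

test_that("rank-sum z matches the exhaustive example and wilcox.test", {
    a <- AnnMatrix(matrix(c(1, 2, 3, 4, 5, 6), ncol = 1),
                   obs = data.frame(grp = factor(rep(c("A", "B"), each = 3))),
                   uns = list(log1p = TRUE))
    rr <- rankGenesGroups(a, "grp", method = "wilcoxon", nGenes = 1)
    ## complete separation, U = 0: z = (6 - 10.5)/sqrt(5.25) = -1.9640
    expect_equal(rr@tables$A$score, -4.5 / sqrt(5.25), tolerance = 1e-6)
    expect_equal(rr@tables$A$score, -1.964, tolerance = 1e-3)

    ## p agrees with the normal approximation of wilcox.test (no continuity)
    wt <- wilcox.test(1:3, 4:6, correct = FALSE, exact = FALSE)
    expect_equal(rr@tables$A$pval, wt$p.value, tolerance = 1e-10)

    ## ties are corrected: compare against wilcox.test with ties
    set.seed(2)
    X <- matrix(sample(1:4, 60, TRUE), 12, 5)
    b <- AnnMatrix(X, obs = data.frame(grp = factor(rep(c("A", "B"), each = 6))),
                   uns = list(log1p = TRUE))
    rb <- rankGenesGroups(b, "grp", method = "wilcoxon", nGenes = 5)
    for (j in 1:5) {
        wt <- suppressWarnings(wilcox.test(X[1:6, j], X[7:12, j],
                                           correct = FALSE, exact = FALSE))
        expect_equal(rb@tables$A$pval[rb@tables$A$gene == paste0("var", j)],
                     wt$p.value, tolerance = 1e-8)
    }
})

test_that("degenerate groups and swaps behave as documented", {
    ## group identical to rest: t = 0, p = 1
    a <- AnnMatrix(matrix(rep(c(1, 2), 4), 4, 2),
                   obs = data.frame(grp = factor(c("A", "A", "B", "B"))),
                   uns = list(log1p = TRUE))
    rr <- rankGenesGroups(a, "grp", method = "ttest", nGenes = 2)
    expect_equal(rr@tables$A$score, c(0, 0))
    expect_equal(rr@tables$A$pval, c(1, 1))

    ## swapping group and rest negates the t score
    b <- makeGroupedMatrix()
    rb <- rankGenesGroups(b, "grp", method = "ttest", nGenes = 4)
    sA <- rb@tables$A[order(rb@tables$A$gene), ]
    sB <- rb@tables$B[order(rb@tables$B$gene), ]
    expect_equal(sA$score, -sB$score)

    ## groups with < 2 cells are skipped with a warning
    cc <- AnnMatrix(matrix(rnorm(8), 4, 2),
                    obs = data.frame(grp = factor(c("A", "B", "B", "B"))),
                    uns = list(log1p = TRUE))
    ## both sides degenerate here: A has 1 cell, so B's complement does too
    w <- capture_warnings(rc <- rankGenesGroups(cc, "grp", nGenes = 2))
    expect_true(all(grepl("fewer than 2", w)))
    expect_false("A" %in% rc@groups)

    ## unflagged matrices warn about the log assumption
    d <- AnnMatrix(matrix(rnorm(8), 4, 2),
                   obs = data.frame(grp = factor(c("A", "A", "B", "B"))))
    expect_warning(rankGenesGroups(d, "grp", nGenes = 1), "log")
})

test_that("BH adjustment is monotone and fold changes use expm1 means", {
    set.seed(3)
    X <- matrix(rnorm(400, 5), 40, 10)
    X[1:20, 1] <- X[1:20, 1] + 2
    a <- AnnMatrix(X, obs = data.frame(grp = factor(rep(c("A", "B"), each = 20))),
                   uns = list(log1p = TRUE))
    rr <- rankGenesGroups(a, "grp", method = "ttest", nGenes = 10)
    tab <- rr@tables$A
    ord <- order(tab$pval)
    expect_true(all(diff(tab$padj[ord]) >= -1e-12))
    ## BH depends only on the ranks, so recomputing on the reordered
    ## vector must reproduce the stored adjustments elementwise
    expect_equal(tab$padj, p.adjust(tab$pval, "BH"), tolerance = 1e-12)

    mu1 <- colMeans(X[1:20, ]); mu2 <- colMeans(X[21:40, ])
    l2 <- log2((expm1(mu1) + 1e-9) / (expm1(mu2) + 1e-9))
    expect_equal(tab$log2fc, l2[match(tab$gene, paste0("var", 1:10))],
                 ignore_attr = TRUE)
    ## scores are sorted descending per group
    expect_true(all(diff(tab$score) <= 1e-12))
})
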