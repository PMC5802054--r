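#' @include AnnMatrix-class.R
NULL

#' Marker-gene ranking result
#'
#' One ranking per group (group vs rest of cells): gene names ordered by
#' decreasing score, the scores (Welch t or rank-sum z statistics), raw
#' and Benjamini–Hochberg adjusted two-sided p-values, and log2 fold
#' changes.
#'
#' @slot groups Group names.
#' @slot tables Named list of per-group `data.frame`s with columns
#'   `gene`, `score`, `pval`, `padj`, `log2fc`, sorted by decreasing
#'   score and truncated to the requested number of genes.
#' @slot method `"ttest"` or `"wilcoxon"`.
#' @aliases RankResult
#' @exportClass RankResult
setClass("RankResult",
    representation(groups = "character", tables = "list",
                   method = "character"))

setMethod("show", "RankResult", function(object) {
    cat(sprintf("RankResult (%s): %d group(s)\n", object@method,
                length(object@groups)))
    for (gr in object@groups) {
        top <- head(object@tables[[gr]]$gene, 3)
        cat(sprintf("  %s: %s, ...\n", gr, paste(top, collapse = ", ")))
    }
})

#' Rank marker genes per group
#'
#' For every group in a categorical observation column, tests each gene
#' for differential expression of the group against all remaining cells.
#' `method = "ttest"` uses the Welch statistic
#' \eqn{t = (\mu_1 - \mu_2)/\sqrt{s_1^2/n_1 + s_2^2/n_2}} with
#' Welch–Satterthwaite degrees of freedom; `method = "wilcoxon"` the
#' rank-sum z with tie correction (normal approximation, no continuity
#' correction).  Two-sided p-values are Benjamini–Hochberg adjusted
#' across genes within each group.  Log2 fold changes are computed on
#' `expm1`-backtransformed group means with pseudocount 1e-9.  Groups
#' with fewer than 2 cells are skipped with a warning.
#'
#' @param a An [AnnMatrix-class]; `X` should be log-transformed (a
#'   warning is emitted otherwise).
#' @param groupCol Name of a categorical (factor or character) column of
#'   `obsTable(a)`.
#' @param method `"ttest"` (default) or `"wilcoxon"`.
#' @param nGenes Number of top genes per group (default 100).
#' @return A [RankResult-class].
#' @export
rankGenesGroups <- function(a, groupCol, method = c("ttest", "wilcoxon"),
                            nGenes = 100) {
    method <- match.arg(method)
    ot <- obsTable(a)
    if (!groupCol %in% colnames(ot))
        stopf("obs column '%s' not found", groupCol)
    grp <- as.factor(ot[[groupCol]])
    if (!isTRUE(uns(a)$log1p))
        warnf("X does not appear to be log-transformed (no log1p flag); statistics assume log scale")
    X <- as.matrix(xData(a))
    genes <- varNames(a)
    n <- nrow(X)
    nGenes <- min(nGenes, ncol(X))

    tables <- list(); groups <- character(0)
    for (gr in levels(grp)) {
        inGrp <- grp == gr
        n1 <- sum(inGrp); n2 <- n - n1
        if (n1 < 2 || n2 < 2) {
            warnf("group '%s' has fewer than 2 cells on one side; skipped", gr)
            next
        }
        if (method == "ttest") {
            st <- welchTest(X[inGrp, , drop = FALSE], X[!inGrp, , drop = FALSE])
        } else {
            st <- wilcoxonTest(X, inGrp)
        }
        mu1 <- colMeans(X[inGrp, , drop = FALSE])
        mu2 <- colMeans(X[!inGrp, , drop = FALSE])
        ## expm1 back-transform assumes log1p-scale input; on scaled data
        ## the ratio can go nonpositive, reported as NA
        ratio <- (expm1(mu1) + 1e-9) / (expm1(mu2) + 1e-9)
        l2fc <- rep(NA_real_, length(ratio))
        l2fc[ratio > 0] <- log2(ratio[ratio > 0])
        padj <- stats::p.adjust(st$p, method = "BH")
        ord <- order(st$stat, decreasing = TRUE)[seq_len(nGenes)]
        tables[[gr]] <- data.frame(gene = genes[ord], score = st$stat[ord],
                                   pval = st$p[ord], padj = padj[ord],
                                   log2fc = l2fc[ord],
                                   stringsAsFactors = FALSE)
        groups <- c(groups, gr)
    }
    new("RankResult", groups = groups, tables = tables, method = method)
}

## Vectorized Welch t over the columns of two matrices.
welchTest <- function(A, B) {
    n1 <- nrow(A); n2 <- nrow(B)
    m1 <- colMeans(A); m2 <- colMeans(B)
    v1 <- colMeanVar(A)$var; v2 <- colMeanVar(B)$var
    se2 <- v1 / n1 + v2 / n2
    t <- ifelse(se2 > 0, (m1 - m2) / sqrt(se2), 0)
    df <- ifelse(se2 > 0,
                 se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1))),
                 1)
    p <- ifelse(se2 > 0, 2 * stats::pt(-abs(t), df), 1)
    list(stat = t, p = p)
}

## Vectorized rank-sum z over the columns of X for the mask `inGrp`:
## tie-corrected normal approximation, no continuity correction.
wilcoxonTest <- function(X, inGrp) {
    n <- nrow(X); n1 <- sum(inGrp); n2 <- n - n1
    stat <- numeric(ncol(X)); p <- numeric(ncol(X))
    Rk <- apply(X, 2, rank)
    W1 <- colSums(Rk[inGrp, , drop = FALSE])
    mu <- n1 * (n + 1) / 2
    tieTerm <- apply(X, 2, function(col) {
        tt <- table(col)
        sum(tt^3 - tt)
    })
    sig2 <- n1 * n2 / 12 * ((n + 1) - tieTerm / (n * (n - 1)))
    z <- ifelse(sig2 > 0, (W1 - mu) / sqrt(sig2), 0)
    list(stat = z, p = ifelse(sig2 > 0, 2 * stats::pnorm(-abs(z)), 1))
}
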