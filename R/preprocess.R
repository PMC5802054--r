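#' @include AnnMatrix-class.R
NULL

#' Filter observations or variables by coverage
#'
#' Removes observations whose total count falls below `minCounts`, and/or
#' entities detected (nonzero) in fewer than `minEntities` elements of the
#' other axis.  Both thresholds work on either axis; at least one must be
#' given.  The names of removed entities are appended to
#' `uns(a)$filter_log`.
#'
#' @param a An [AnnMatrix-class] with nonnegative `X`.
#' @param axis `"obs"` (cells) or `"var"` (genes).
#' @param minCounts Minimum total count along the axis.
#' @param minEntities Minimum number of nonzero entries along the axis
#'   (for genes: detected in at least this many cells).
#' @return The filtered `AnnMatrix`.
#' @export
filterAxis <- function(a, axis = c("obs", "var"), minCounts = NULL,
                       minEntities = NULL) {
    axis <- match.arg(axis)
    if (is.null(minCounts) && is.null(minEntities))
        stopf("give at least one of minCounts, minEntities")
    X <- xData(a)
    margin <- if (axis == "obs") 1L else 2L
    totals <- if (margin == 1L) rowSumsAny(X) else
        if (isSparse(X)) Matrix::colSums(X) else colSums(X)
    nnz <- if (isSparse(X)) {
        if (margin == 1L) Matrix::rowSums(X != 0) else Matrix::colSums(X != 0)
    } else {
        if (margin == 1L) rowSums(X != 0) else colSums(X != 0)
    }
    keep <- rep(TRUE, dim(a)[margin])
    if (!is.null(minCounts)) keep <- keep & totals >= minCounts
    if (!is.null(minEntities)) keep <- keep & nnz >= minEntities
    if (!any(keep))
        stopf("filterAxis would remove every %s; review the thresholds", axis)
    removed <- (if (axis == "obs") obsNames(a) else varNames(a))[!keep]
    out <- if (axis == "obs") a[keep, ] else a[, keep]
    log <- uns(out)$filter_log
    if (is.null(log)) log <- list()
    log[[sprintf("step%d_%s", length(log) + 1L, axis)]] <-
        list(axis = axis, removed = removed)
    u <- uns(out); u$filter_log <- log; uns(out) <- u
    out
}

#' Total-count normalization
#'
#' Scales every observation (cell) so that its total count equals
#' `targetSum`; the default target is the median of the pre-normalization
#' row sums.  Rows summing to zero are left unchanged with a warning.
#'
#' @param a An [AnnMatrix-class] with nonnegative `X`.
#' @param targetSum Positive target total per cell, or `NULL` for the
#'   median rule.
#' @return The normalized `AnnMatrix` (sparsity preserved).
#' @export
normalizeTotal <- function(a, targetSum = NULL) {
    X <- xData(a)
    if (minValue(X) < 0)
        stopf("normalizeTotal requires nonnegative values; normalize before log/scale")
    sums <- rowSumsAny(X)
    if (is.null(targetSum)) targetSum <- stats::median(sums)
    if (!is.numeric(targetSum) || targetSum <= 0)
        stopf("targetSum must be a positive number")
    zero <- sums == 0
    if (any(zero))
        warnf("%d observation(s) with zero total left unchanged", sum(zero))
    fac <- ifelse(zero, 1, targetSum / sums)
    X2 <- if (isSparse(X)) Matrix::Diagonal(x = fac) %*% X
          else X * fac
    if (isSparse(X2)) X2 <- methods::as(X2, "CsparseMatrix")
    xData(a) <- X2
    a
}

minValue <- function(X) {
    if (isSparse(X)) {
        if (length(X@x) == 0) 0 else min(0, min(X@x))
    } else min(X)
}

#' Elementwise log(1 + x) transform
#'
#' Applies `log1p` to every entry, preserving the sparsity pattern, and
#' records the flag `uns(a)$log1p`.  Calling it again on an
#' already-flagged matrix is a warning no-op (idempotence guard).
#'
#' @param a An [AnnMatrix-class] with nonnegative `X`.
#' @return The transformed `AnnMatrix`.
#' @export
logTransform <- function(a) {
    if (isTRUE(uns(a)$log1p)) {
        warnf("matrix is already log1p-transformed; returning unchanged")
        return(a)
    }
    X <- xData(a)
    if (minValue(X) < 0) stopf("log1p requires nonnegative values")
    if (isSparse(X)) X@x <- log1p(X@x) else X <- log1p(X)
    xData(a) <- X
    u <- uns(a); u$log1p <- TRUE; uns(a) <- u
    a
}

#' Highly variable gene selection
#'
#' Computes the per-gene mean \eqn{\mu_g} and dispersion
#' \eqn{d_g = var_g / \mu_g} on normalized (un-logged) values, bins the
#' genes into `nBins` equal-frequency bins of \eqn{\mu_g}, standardizes
#' the dispersions within each bin — by bin mean and sample standard
#' deviation (`flavor = "meanstd"`) or, robustly, by bin median and MAD
#' (`flavor = "medianmad"`, the default) — and flags the `nTop` genes
#' with the largest standardized dispersion.  Genes with \eqn{\mu_g = 0}
#' have dispersion 0 and rank last; singleton bins and bins with zero
#' spread get a standardized dispersion of 0 (with a warning).
#'
#' @param a An [AnnMatrix-class], normalized but not yet log-scaled.
#' @param nTop Number of genes to flag (`<= nVar(a)`).
#' @param nBins Number of equal-frequency mean bins (default 20).
#' @param flavor `"medianmad"` or `"meanstd"`.
#' @return A `data.frame` with one row per gene (row names = gene names)
#'   and columns `means`, `dispersions`, `dispersions_norm`,
#'   `highly_variable`.
#' @export
highlyVariableGenes <- function(a, nTop, nBins = 20,
                                flavor = c("medianmad", "meanstd")) {
    flavor <- match.arg(flavor)
    nv <- nVar(a)
    if (nTop > nv) stopf("nTop = %d exceeds the number of genes (%d)", nTop, nv)
    if (nTop < 1) stopf("nTop must be >= 1")
    X <- xData(a)
    mv <- colMeanVar(X)
    mu <- mv$mean
    disp <- ifelse(mu > 0, mv$var / mu, 0)

    br <- unique(stats::quantile(mu, probs = seq(0, 1, length.out = nBins + 1)))
    bin <- if (length(br) > 2) cut(mu, breaks = br, include.lowest = TRUE)
           else factor(rep(1L, nv))
    z <- numeric(nv)
    degenerate <- FALSE
    for (lv in levels(bin)) {
        sel <- which(bin == lv)
        d <- disp[sel]
        if (length(sel) < 2) { z[sel] <- 0; degenerate <- TRUE; next }
        if (flavor == "meanstd") {
            s <- stats::sd(d)
            if (!is.finite(s) || s == 0) { z[sel] <- 0; degenerate <- TRUE }
            else z[sel] <- (d - mean(d)) / s
        } else {
            m <- stats::mad(d)
            if (!is.finite(m) || m == 0) { z[sel] <- 0; degenerate <- TRUE }
            else z[sel] <- (d - stats::median(d)) / m
        }
    }
    if (degenerate)
        warnf("bin(s) with a single gene or zero dispersion spread: standardized dispersion set to 0 there")

    rankKey <- z
    rankKey[mu == 0] <- -Inf   # undetected genes are never preferred
    ord <- order(rankKey, decreasing = TRUE)
    hv <- logical(nv)
    hv[ord[seq_len(nTop)]] <- TRUE
    data.frame(means = mu, dispersions = disp, dispersions_norm = z,
               highly_variable = hv, row.names = varNames(a))
}

#' Regress out confounding covariates
#'
#' Per gene, fits ordinary least squares of expression on an intercept
#' plus the named numeric observation columns and replaces `X` by the
#' residuals (dense output).  A rank-deficient design drops the collinear
#' column(s) with a warning.
#'
#' @param a An [AnnMatrix-class].
#' @param covariateCols Names of numeric columns of `obsTable(a)`.
#' @return The `AnnMatrix` with residual (dense) `X`.
#' @export
regressOut <- function(a, covariateCols) {
    ot <- obsTable(a)
    missing <- setdiff(covariateCols, colnames(ot))
    if (length(missing))
        stopf("obs column(s) not found: %s", paste(missing, collapse = ", "))
    covs <- ot[, covariateCols, drop = FALSE]
    if (!all(vapply(covs, is.numeric, logical(1))))
        stopf("covariate columns must be numeric")
    D <- cbind(`(Intercept)` = 1, as.matrix(covs))
    qrD <- qr(D)
    if (qrD$rank < ncol(D)) {
        drop <- colnames(D)[qrD$pivot[(qrD$rank + 1):ncol(D)]]
        warnf("rank-deficient design; dropping collinear column(s): %s",
              paste(drop, collapse = ", "))
        D <- D[, qrD$pivot[seq_len(qrD$rank)], drop = FALSE]
        qrD <- qr(D)
    }
    X <- as.matrix(xData(a))
    beta <- qr.coef(qrD, X)
    xData(a) <- X - D %*% beta
    a
}

#' Standardize genes and clip extremes
#'
#' Per gene: subtract the mean and divide by the sample standard
#' deviation (denominator `n - 1`); zero-variance genes are set to 0.
#' If `maxValue` is given, standardized values are clipped symmetrically
#' to `[-maxValue, maxValue]`.  Output is dense.
#'
#' @param a An [AnnMatrix-class].
#' @param maxValue Optional positive clip bound.
#' @return The scaled `AnnMatrix`.
#' @export
scaleClip <- function(a, maxValue = NULL) {
    X <- as.matrix(xData(a))
    mv <- colMeanVar(X)
    s <- sqrt(mv$var)
    s[s == 0] <- 1
    X <- sweep(X, 2, mv$mean, "-")
    X <- sweep(X, 2, s, "/")
    X[, mv$var == 0] <- 0
    if (!is.null(maxValue)) {
        if (maxValue <= 0) stopf("maxValue must be positive")
        X[X > maxValue] <- maxValue
        X[X < -maxValue] <- -maxValue
    }
    xData(a) <- X
    a
}

#' Principal component analysis result
#'
#' @slot components Variables-by-components orthonormal loading matrix.
#' @slot scores Observations-by-components coordinates of the centered
#'   data.
#' @slot explainedVarianceRatio Fraction of total variance per component
#'   (non-increasing, sums to at most 1).
#' @slot seed Seed used for the randomized solver.
#' @aliases PcaResult
#' @exportClass PcaResult
setClass("PcaResult",
    representation(components = "matrix", scores = "matrix",
                   explainedVarianceRatio = "numeric", seed = "integer"))

setMethod("show", "PcaResult", function(object) {
    cat(sprintf("PcaResult: %d components over %d observations x %d variables\n",
                ncol(object@scores), nrow(object@scores),
                nrow(object@components)))
    cat("  explained variance ratio:",
        paste(sprintf("%.3f", head(object@explainedVarianceRatio, 5)),
              collapse = ", "),
        if (length(object@explainedVarianceRatio) > 5) "..." else "", "\n")
})

#' Principal component analysis
#'
#' Centers the data and computes the top `nComps` principal components,
#' with a deterministic sign convention: the largest-magnitude entry of
#' every loading vector is positive.  Small problems use an exact SVD;
#' larger ones a seeded truncated SVD.
#'
#' @param a An [AnnMatrix-class] (typically scaled).
#' @param nComps Number of components, `<= min(nObs, nVar)`.
#' @param seed Integer seed for the truncated solver.
#' @return A [PcaResult-class].
#' @export
runPca <- function(a, nComps = 50, seed = 0) {
    X <- xData(a)
    n <- nrow(X); p <- ncol(X)
    if (nComps > min(n, p))
        stopf("nComps = %d exceeds min(nObs, nVar) = %d", nComps, min(n, p))
    mu <- colMeansAny(X)
    totalVar <- sum(colMeanVar(X)$var)
    small <- min(n, p) <= 100 || nComps > min(n, p) / 2
    if (small) {
        Xc <- as.matrix(X)
        Xc <- sweep(Xc, 2, mu, "-")
        sv <- svd(Xc, nu = nComps, nv = nComps)
        d <- sv$d[seq_len(nComps)]
        U <- sv$u; V <- sv$v
    } else {
        set.seed(seed)
        sv <- irlba::irlba(X, nv = nComps, center = mu)
        d <- sv$d
        U <- sv$u; V <- sv$v
    }
    ## sign convention: largest |loading| entry positive
    for (cpt in seq_len(nComps)) {
        w <- which.max(abs(V[, cpt]))
        if (V[w, cpt] < 0) { V[, cpt] <- -V[, cpt]; U[, cpt] <- -U[, cpt] }
    }
    scores <- U * rep(d, each = n)
    evr <- (d^2 / (n - 1)) / totalVar
    new("PcaResult", components = V, scores = scores,
        explainedVarianceRatio = evr, seed = as.integer(seed))
}

#' Composite preprocessing recipe
#'
#' The benchmark preprocessing pipeline: drop zero-count cells,
#' total-count normalize, select highly variable genes (median/MAD
#' flavor), subset to them, re-normalize, `log1p`, and scale with
#' clipping at 10.  Each step is recorded in `uns$recipe_log`.
#'
#' @param a An [AnnMatrix-class] of raw counts.
#' @param nTopGenes Number of highly variable genes to keep.
#' @return The preprocessed `AnnMatrix` (dense, `nTopGenes` columns).
#' @export
recipeBenchmark <- function(a, nTopGenes) {
    log <- character(0)
    a <- filterAxis(a, "obs", minCounts = 1)
    log <- c(log, "filter_cells")
    a <- normalizeTotal(a)
    log <- c(log, "normalize_total")
    hvg <- highlyVariableGenes(a, nTop = nTopGenes, flavor = "medianmad")
    log <- c(log, "highly_variable_genes")
    a <- a[, hvg$highly_variable]
    log <- c(log, "subset_hvg")
    a <- normalizeTotal(a)
    log <- c(log, "normalize_total")
    a <- logTransform(a)
    log <- c(log, "log1p")
    a <- scaleClip(a, maxValue = 10)
    log <- c(log, "scale_clip")
    u <- uns(a); u$recipe_log <- log; uns(a) <- u
    a
}
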