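#' @include AnnMatrix-class.R
NULL

## Shared latent -> counts mapping for the synthetic generators: latent
## coordinates act on the per-gene log mean through a random nonnegative
## loading matrix.  Loadings are sharpened (entrywise cubed, then column
## L1-normalized) so each gene responds predominantly to one latent
## program, the way real marker genes do; the log mean is then shifted by
## a per-gene base level (log-normal, sd `baseMeanSdLog`, rescaled so the
## expected per-cell total is `targetDepth`) and a per-cell library-size
## factor (log-normal, sd `libSdLog`), and counts are sampled as
## overdispersed negative binomials with fixed dispersion
## (size = 1/dispersion).  Generated blockwise so large fixtures never
## hold a dense mean matrix.
latentToCounts <- function(Z, nGenes, dispersion = 0.1, libSdLog = 0.3,
                           signalScale = 1, targetDepth = 2500,
                           baseMeanSdLog = 1) {
    nCells <- nrow(Z)
    d <- ncol(Z)
    A <- matrix(abs(stats::rnorm(d * nGenes)), d, nGenes)^3
    A <- sweep(A, 2, colSums(A), "/")
    baseMean <- exp(stats::rnorm(nGenes, 0, baseMeanSdLog))
    ## rescale so that the mean per-cell total count is ~targetDepth,
    ## independent of nGenes (the exp-signal inflation is estimated on a
    ## subsample of cells)
    sub <- Z[seq_len(min(nCells, 200L)), , drop = FALSE]
    infl <- colMeans(exp(signalScale * (sub %*% A)))
    baseMean <- baseMean * targetDepth / sum(baseMean * infl)
    libFac <- exp(stats::rnorm(nCells, 0, libSdLog))

    blockRows <- max(1L, min(nCells, as.integer(ceiling(2e6 / nGenes))))
    blocks <- list()
    for (start in seq.int(1L, nCells, by = blockRows)) {
        rows <- start:min(nCells, start + blockRows - 1L)
        mu <- exp(signalScale * (Z[rows, , drop = FALSE] %*% A))
        mu <- sweep(mu, 2, baseMean, "*") * libFac[rows]
        cnt <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                     size = 1 / dispersion),
                      nrow = length(rows))
        blocks[[length(blocks) + 1L]] <- methods::as(Matrix::Matrix(cnt, sparse = TRUE),
                                                     "CsparseMatrix")
    }
    out <- if (length(blocks) == 1) blocks[[1]] else do.call(rbind, blocks)
    methods::as(out, "dMatrix")
}

#' Gaussian-mixture count fixture
#'
#' Synthetic cells from `nClusters` well-defined populations: latent
#' points are drawn from 10-dimensional Gaussians with unit
#' within-cluster standard deviation whose centers sit at pairwise
#' distance `separation`, then mapped to overdispersed
#' negative-binomial counts (see the package vignette for the noise
#' model).  Ground-truth labels are stored in the `true_cluster` obs
#' column and the generating parameters in `uns$fixture_spec`.
#'
#' @param nCells,nGenes Output dimensions.
#' @param nClusters Number of populations (<= 10).
#' @param separation Effect size: latent distance between cluster
#'   centers in units of the within-cluster standard deviation (> 0).
#' @param seed Random seed; identical seeds give identical matrices.
#' @param dispersion Negative-binomial dispersion (default 0.1).
#' @param libSdLog Log-normal sd of the library-size factor (default 0.3).
#' @return A sparse integer-count [AnnMatrix-class].
#' @export
generateMixture <- function(nCells = 600, nGenes = 300, nClusters = 3,
                            separation = 8, seed = 0, dispersion = 0.1,
                            libSdLog = 0.3) {
    if (separation <= 0) stopf("separation must be positive")
    latentDim <- 10L
    if (nClusters > latentDim)
        stopf("nClusters must be <= %d", latentDim)
    set.seed(seed)
    cl <- sample(rep_len(seq_len(nClusters), nCells))
    centers <- diag(latentDim)[seq_len(nClusters), , drop = FALSE] *
        separation / sqrt(2)
    Z <- centers[cl, , drop = FALSE] +
        matrix(stats::rnorm(nCells * latentDim), nCells, latentDim)
    X <- latentToCounts(Z, nGenes, dispersion = dispersion,
                        libSdLog = libSdLog)
    AnnMatrix(X, obsNames = paste0("cell", seq_len(nCells)),
              varNames = paste0("gene", seq_len(nGenes)),
              obs = data.frame(true_cluster = factor(cl - 1L)),
              uns = list(fixture_spec = list(kind = "mixture",
                  n_cells = as.numeric(nCells), n_genes = as.numeric(nGenes),
                  n_clusters = as.numeric(nClusters),
                  separation = as.numeric(separation),
                  dispersion = dispersion, lib_sd_log = libSdLog,
                  seed = as.numeric(seed))))
}

#' Bifurcating-trajectory count fixture
#'
#' Cells along a Y-shaped curve: uniform times in [0, 1], a common trunk
#' up to `branchTime`, then one of two divergent branches; latent
#' positions (10-dimensional, path length `separation`, isotropic noise
#' `noiseSd`) are mapped to counts as in [generateMixture()].  Ground
#' truth is stored in obs columns `true_time` and `true_branch` (trunk =
#' 0, branches = 1 and 2).
#'
#' @inheritParams generateMixture
#' @param nBranches Number of branches after the trunk (only 2
#'   supported).
#' @param branchTime Time of the branch point (default 0.4).
#' @param noiseSd Latent isotropic noise sd (default 0.2, a clearly
#'   resolved developmental axis relative to the path length).
#' @return A sparse integer-count [AnnMatrix-class].
#' @export
generateBranching <- function(nCells = 300, nGenes = 300, nBranches = 2,
                              separation = 8, seed = 0, branchTime = 0.4,
                              noiseSd = 0.2, dispersion = 0.1,
                              libSdLog = 0.3) {
    if (nBranches != 2) stopf("only nBranches = 2 is supported")
    if (separation <= 0) stopf("separation must be positive")
    latentDim <- 10L
    set.seed(seed)
    tt <- stats::runif(nCells)
    br <- ifelse(tt < branchTime, 0L,
                 sample(c(1L, 2L), nCells, replace = TRUE))
    basis <- qr.Q(qr(matrix(stats::rnorm(latentDim * 3), latentDim, 3)))
    v0 <- basis[, 1]; v1 <- basis[, 2]; v2 <- basis[, 3]
    P <- matrix(0, nCells, latentDim)
    trunkEnd <- branchTime * separation
    for (i in seq_len(nCells)) {
        s <- tt[i] * separation
        P[i, ] <- if (br[i] == 0L) s * v0
                  else trunkEnd * v0 + (s - trunkEnd) *
                      (if (br[i] == 1L) v1 else v2)
    }
    Z <- P + matrix(stats::rnorm(nCells * latentDim, 0, noiseSd),
                    nCells, latentDim)
    X <- latentToCounts(Z, nGenes, dispersion = dispersion,
                        libSdLog = libSdLog)
    AnnMatrix(X, obsNames = paste0("cell", seq_len(nCells)),
              varNames = paste0("gene", seq_len(nGenes)),
              obs = data.frame(true_time = tt, true_branch = factor(br)),
              uns = list(fixture_spec = list(kind = "branching",
                  n_cells = as.numeric(nCells), n_genes = as.numeric(nGenes),
                  n_branches = as.numeric(nBranches),
                  separation = as.numeric(separation),
                  branch_time = branchTime, noise_sd = noiseSd,
                  dispersion = dispersion, lib_sd_log = libSdLog,
                  seed = as.numeric(seed))))
}
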