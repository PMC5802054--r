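#' @include neighbors.R
NULL

#' Diffusion map result
#'
#' Eigenpairs of the random-walk transition operator, computed through
#' its symmetric conjugate.  `vectors` are the orthonormal eigenvectors
#' of the symmetric conjugate (used for diffusion-pseudotime distances);
#' `components` are the back-transformed right eigenvectors of T itself
#' (the diffusion components used as embedding coordinates; the first is
#' constant).  Eigenvalues are sorted non-increasing with
#' \eqn{\lambda_0 = 1}.
#'
#' @slot eigenvalues Numeric vector, length `nComps + 1`.
#' @slot vectors n-by-(nComps+1) orthonormal eigenvector matrix.
#' @slot components n-by-(nComps+1) diffusion components.
#' @aliases DiffusionResult
#' @exportClass DiffusionResult
setClass("DiffusionResult",
    representation(eigenvalues = "numeric", vectors = "matrix",
                   components = "matrix"))

setMethod("show", "DiffusionResult", function(object) {
    cat(sprintf("DiffusionResult: %d eigenpairs over %d observations\n",
                length(object@eigenvalues), nrow(object@vectors)))
    cat("  eigenvalues:",
        paste(sprintf("%.4f", head(object@eigenvalues, 6)), collapse = ", "),
        if (length(object@eigenvalues) > 6) "..." else "", "\n")
})

#' Diffusion pseudotime result
#'
#' @slot root Root observation index.
#' @slot pseudotime Per-cell pseudotime in [0, 1] (0 at the root).
#' @slot segments Per-cell integer branch label (trunk = 0).
#' @slot dptToRoot Raw diffusion-pseudotime distances to the root.
#' @aliases DptResult
#' @exportClass DptResult
setClass("DptResult",
    representation(root = "integer", pseudotime = "numeric",
                   segments = "integer", dptToRoot = "numeric"))

setMethod("show", "DptResult", function(object) {
    ns <- length(unique(object@segments))
    cat(sprintf("DptResult: %d cells, root = %d, %d segment(s)\n",
                length(object@pseudotime), object@root, max(ns, 1L)))
})

#' Force-directed layout result
#'
#' @slot coords n-by-2 finite coordinates.
#' @slot iterations Iterations run.
#' @slot seed Seed used for the initial positions.
#' @aliases LayoutResult
#' @exportClass LayoutResult
setClass("LayoutResult",
    representation(coords = "matrix", iterations = "integer",
                   seed = "integer"))

setMethod("show", "LayoutResult", function(object) {
    cat(sprintf("LayoutResult: %d points, %d iterations (seed %d)\n",
                nrow(object@coords), object@iterations, object@seed))
})

#' Diffusion maps
#'
#' Computes the top `nComps + 1` eigenpairs of the transition operator T
#' via its symmetric conjugate (dense solver for small graphs, Lanczos
#' otherwise), back-transforms the eigenvectors by \eqn{D^{-1/2}} to
#' diffusion components, and applies the same deterministic sign
#' convention as [runPca()].  With density normalization the leading
#' component is constant and \eqn{\lambda_0 = 1}.
#'
#' @param g A [NeighborGraph-class] with the transition matrix present.
#' @param nComps Number of non-trivial components (default 15).
#' @return A [DiffusionResult-class].
#' @export
diffusionMap <- function(g, nComps = 15) {
    stopifnot(methods::is(g, "NeighborGraph"))
    if (is.null(g@transSym))
        stopf("transition matrix missing; run transitionMatrix() first")
    n <- g@nObs
    m <- nComps + 1L
    if (m > n) stopf("nComps + 1 = %d exceeds the number of observations", m)
    Ts <- g@transSym
    if (n <= 400 || m > n / 3) {
        eig <- eigen(as.matrix(Ts), symmetric = TRUE)
        vals <- eig$values[seq_len(m)]
        vecs <- eig$vectors[, seq_len(m), drop = FALSE]
    } else {
        eig <- tryCatch(
            RSpectra::eigs_sym(Ts, k = m, which = "LA"),
            error = function(e)
                stopf("eigensolver failed (%s); try larger k or fewer components",
                      conditionMessage(e)))
        ord <- order(eig$values, decreasing = TRUE)
        vals <- eig$values[ord]
        vecs <- eig$vectors[, ord, drop = FALSE]
    }
    for (cpt in seq_len(ncol(vecs))) {
        w <- which.max(abs(vecs[, cpt]))
        if (vecs[w, cpt] < 0) vecs[, cpt] <- -vecs[, cpt]
    }
    comps <- vecs / sqrt(g@dSum)
    new("DiffusionResult", eigenvalues = vals, vectors = vecs,
        components = comps)
}

## Weighted spectral representation whose row-wise Euclidean distances are
## the diffusion-pseudotime distances: column i is
## (lambda_i / (1 - lambda_i)) * u_i for the non-trivial eigenpairs with
## lambda_i < 1 - eps.  Extra eigenvalues at ~1 (disconnected directions)
## are excluded with a warning.
dptRepresentation <- function(dm, nDcs = 10, eps = 1e-10) {
    lam <- dm@eigenvalues
    nonTrivial <- seq_along(lam)[-1]
    excl <- nonTrivial[lam[nonTrivial] >= 1 - eps]
    if (length(excl))
        warnf("excluding %d component(s) with eigenvalue >= 1 - eps (disconnected or near-invariant direction)",
              length(excl))
    keep <- head(nonTrivial[lam[nonTrivial] < 1 - eps], nDcs)
    if (!length(keep)) stopf("no usable diffusion components")
    w <- lam[keep] / (1 - lam[keep])
    dm@vectors[, keep, drop = FALSE] * rep(w, each = nrow(dm@vectors))
}

#' Diffusion pseudotime distance
#'
#' The random-walk distance accumulated over all walk lengths:
#' \deqn{dpt(x, y)^2 = \sum_{i \ge 1} \left(\frac{\lambda_i}{1 -
#'   \lambda_i}\right)^2 (\psi_i(x) - \psi_i(y))^2,}
#' summing over the non-trivial eigenpairs with \eqn{\lambda_i < 1 -
#' \epsilon} (components at eigenvalue 1 — disconnected directions — are
#' excluded with a warning).  Equals the Euclidean distance between rows
#' of the accumulated transition matrix.
#'
#' @param dm A [DiffusionResult-class].
#' @param x An observation index.
#' @param y One or more observation indices.
#' @param nDcs Number of non-trivial components used (default 10).
#' @param eps Exclusion tolerance for eigenvalues at 1 (default 1e-10).
#' @return Nonnegative distance(s), one per element of `y`.
#' @export
dptDistance <- function(dm, x, y, nDcs = 10, eps = 1e-10) {
    R <- dptRepresentation(dm, nDcs, eps)
    n <- nrow(R)
    if (x < 1 || x > n) stopf("x out of range")
    if (any(y < 1 | y > n)) stopf("y out of range")
    d2 <- rowSums((R[y, , drop = FALSE] -
                   rep(1, length(y)) %o% R[x, ])^2)
    sqrt(pmax(d2, 0))
}

#' Diffusion pseudotime from a root cell
#'
#' Pseudotime of every cell is its diffusion-pseudotime distance to the
#' chosen root, normalized by the maximum so values lie in [0, 1] (the
#' raw distances are kept in `dptToRoot`).
#'
#' @param dm A [DiffusionResult-class].
#' @param root Root observation index.
#' @inheritParams dptDistance
#' @return A [DptResult-class] (segments all zero; see
#'   [detectBranching()]).
#' @export
dptPseudotime <- function(dm, root, nDcs = 10, eps = 1e-10) {
    n <- nrow(dm@vectors)
    if (length(root) != 1 || root < 1 || root > n)
        stopf("root must be a single index in [1, %d]", n)
    d <- dptDistance(dm, root, seq_len(n), nDcs = nDcs, eps = eps)
    mx <- max(d)
    pt <- if (mx > 0) d / mx else d
    new("DptResult", root = as.integer(root), pseudotime = pt,
        segments = integer(n), dptToRoot = d)
}

## Kendall-style split criterion: the branch point shows as correlated
## orderings before the split and anti-correlated after, so the cut index
## maximizes the contrast tau(a[1:i], b[1:i]) - tau(a[(i+1):n], b[(i+1):n]).
## The contrast is precision-weighted (divided by the combined tau standard
## error ~ sqrt(1/i + 1/(n-i))) so short flanks, whose tau estimates are
## noisy, cannot win on sampling noise alone; the reported `score` is the
## raw contrast at the chosen index.  Ties pick the smallest index (the
## cell closest to the ordering tip).
kendallTauSplit <- function(a, b, minSize = 5) {
    n <- length(a)
    if (n < 2 * minSize) return(NULL)
    best <- -Inf; bestI <- NA_integer_; bestContrast <- NA_real_
    for (i in minSize:(n - minSize)) {
        t1 <- suppressWarnings(stats::cor(a[1:i], b[1:i], method = "kendall"))
        t2 <- suppressWarnings(stats::cor(a[(i + 1):n], b[(i + 1):n],
                                          method = "kendall"))
        if (is.na(t1) || is.na(t2)) next
        z <- (t1 - t2) / sqrt(1 / i + 1 / (n - i))
        if (z > best + 1e-12) { best <- z; bestI <- i; bestContrast <- t1 - t2 }
    }
    if (is.na(bestI)) return(NULL)
    list(idx = bestI, score = bestContrast)
}

#' Detect branchings in a trajectory
#'
#' Iteratively splits the cell set into trajectory segments.  Within the
#' segment under consideration: the first tip \eqn{\mu} is the cell
#' farthest (in diffusion pseudotime) from the segment root, the second
#' tip \eqn{\nu} the cell farthest from \eqn{\mu}.  For each of the
#' three tips, cells are ordered by distance from that tip and a branch
#' is cut where the orderings from the other two tips cease to be
#' correlated (running Kendall-tau split).  A cut is accepted only when
#' the tau contrast exceeds `tauThreshold`; on an unbranched segment the
#' split degenerates and the segment is left whole.  Cells claimed by no
#' branch or by several (around the branch point) stay with the trunk.
#' The procedure repeats `nBranchings` times on the largest unresolved
#' segment.  The segment containing the root is labeled 0, the others by
#' decreasing size.
#'
#' @inheritParams dptPseudotime
#' @param nBranchings Number of branching splits to attempt (0 = single
#'   segment).
#' @param tauThreshold Minimum Kendall-tau contrast for a valid cut
#'   (default 0.5).
#' @param minSize Minimum cells on either side of a cut; default 5% of
#'   the segment (at least 5), which keeps small-sample tau noise from
#'   producing spurious early cuts.
#' @return A [DptResult-class] with pseudotime and segments populated.
#' @export
detectBranching <- function(dm, root, nBranchings = 1, nDcs = 10,
                            eps = 1e-10, tauThreshold = 0.5, minSize = NULL) {
    base <- dptPseudotime(dm, root, nDcs = nDcs, eps = eps)
    n <- length(base@pseudotime)
    segs <- integer(n)
    if (nBranchings < 1) return(base)

    R <- suppressWarnings(dptRepresentation(dm, nDcs, eps))
    distWithin <- function(cells, from) {
        sqrt(rowSums((R[cells, , drop = FALSE] -
                      rep(1, length(cells)) %o% R[from, ])^2))
    }
    unresolvable <- integer(0)
    nextId <- 1L
    for (iter in seq_len(nBranchings)) {
        sizes <- table(segs[!(segs %in% unresolvable)])
        if (!length(sizes)) break
        segId <- as.integer(names(sizes)[which.max(sizes)])
        cells <- which(segs == segId)
        minSz <- if (is.null(minSize)) max(5L, ceiling(0.05 * length(cells)))
                 else minSize
        if (length(cells) < 3 * minSz) { unresolvable <- c(unresolvable, segId); next }

        localRoot <- cells[which.min(base@dptToRoot[cells])]
        dRoot <- distWithin(cells, localRoot)
        mu <- cells[which.max(dRoot)]
        dMu <- distWithin(cells, mu)
        nu <- cells[which.max(dMu)]
        dNu <- distWithin(cells, nu)
        tipD <- list(dRoot, dMu, dNu)
        ## a genuine branching needs three mutually distant tips: on an
        ## unbranched segment the second tip collapses onto the root side
        ## and the "arm" between them is an artifact
        pairD <- c(dRoot[match(mu, cells)], dRoot[match(nu, cells)],
                   dMu[match(nu, cells)])
        if (min(pairD) < 0.25 * max(pairD)) {
            unresolvable <- c(unresolvable, segId); next
        }

        branches <- vector("list", 3L)
        for (t in 1:3) {
            others <- setdiff(1:3, t)
            o <- order(tipD[[t]])
            sp <- kendallTauSplit(tipD[[others[1]]][o], tipD[[others[2]]][o],
                                  minSz)
            if (!is.null(sp) && sp$score >= tauThreshold)
                branches[[t]] <- cells[o[seq_len(sp$idx)]]
        }
        valid <- !vapply(branches, is.null, logical(1))
        if (sum(valid[2:3]) == 0) { unresolvable <- c(unresolvable, segId); next }

        ## seed of each branch: cells it claims exclusively; cells claimed
        ## by several rotations or by none (the ambiguous region around the
        ## branch point) follow their nearest uniquely claimed cell in the
        ## dpt embedding
        claims <- integer(n)
        for (t in 1:3) if (valid[t])
            claims[branches[[t]]] <- claims[branches[[t]]] + 1L
        seedLab <- integer(n)                    # 0 = not a seed
        for (t in 1:3) {
            if (!valid[t]) next
            own <- branches[[t]][claims[branches[[t]]] == 1L]
            seedLab[own] <- t
        }
        undecided <- cells[seedLab[cells] == 0L]
        seeds <- cells[seedLab[cells] != 0L]
        if (length(undecided) && length(seeds)) {
            DD <- pairwiseDistances(R)[undecided, seeds, drop = FALSE]
            kk <- min(7L, length(seeds))
            for (ui in seq_along(undecided)) {
                nn <- order(DD[ui, ])[seq_len(kk)]
                votes <- table(seedLab[seeds[nn]])
                seedLab[undecided[ui]] <-
                    as.integer(names(votes)[which.max(votes)])
            }
        }
        ## rotation 1 (segment root side) keeps the parent id; the others
        ## become new segments
        for (t in 2:3) {
            if (!valid[t]) next
            own <- cells[seedLab[cells] == t]
            if (length(own)) {
                segs[own] <- nextId
                nextId <- nextId + 1L
            }
        }
    }
    ## relabel: root's segment -> 0, others by decreasing size
    rootSeg <- segs[root]
    rest <- setdiff(unique(segs), rootSeg)
    if (length(rest))
        rest <- rest[order(-vapply(rest, function(s) sum(segs == s), numeric(1)))]
    segs <- match(segs, c(rootSeg, rest)) - 1L
    new("DptResult", root = base@root, pseudotime = base@pseudotime,
        segments = as.integer(segs), dptToRoot = base@dptToRoot)
}

#' Fruchterman–Reingold force-directed layout
#'
#' Classic force-directed graph drawing on the connectivity weights:
#' with optimal length \eqn{k = \sqrt{area/n}} (unit density, area = n),
#' edges attract with force \eqn{d^2/k} scaled by their weight and all
#' pairs repel with \eqn{k^2/d}; displacement per iteration is capped by
#' a linearly cooling temperature.  For more than 2000 nodes, repulsion
#' is grid-approximated with cutoff radius `3 k`.  Initial positions are
#' seeded, so identical seeds give identical coordinates.
#'
#' @param g A [NeighborGraph-class] with connectivities.
#' @param iterations Number of iterations (default 100).
#' @param seed Seed for the initial positions (default 0).
#' @return A [LayoutResult-class] with finite n-by-2 coordinates.
#' @export
frLayout <- function(g, iterations = 100, seed = 0) {
    stopifnot(methods::is(g, "NeighborGraph"))
    if (is.null(g@conn)) stopf("connectivities missing; run gaussianConnectivities() first")
    n <- g@nObs
    if (n < 1) stopf("empty graph")
    W <- methods::as(Matrix::triu(g@conn), "TsparseMatrix")
    ei <- W@i + 1L; ej <- W@j + 1L; ew <- W@x
    area <- n
    kOpt <- sqrt(area / n)
    set.seed(seed)
    pos <- matrix(stats::runif(2 * n, 0, sqrt(area)), n, 2)
    if (n == 1)
        return(new("LayoutResult", coords = pos,
                   iterations = as.integer(iterations),
                   seed = as.integer(seed)))
    t0 <- 0.1 * sqrt(area)
    cutoff <- 3 * kOpt
    for (it in seq_len(iterations)) {
        temp <- t0 * (1 - (it - 1) / iterations)
        disp <- repulsionForces(pos, kOpt, cutoff, exact = n <= 2000)
        ## attraction along edges, weighted
        dx <- pos[ei, 1] - pos[ej, 1]
        dy <- pos[ei, 2] - pos[ej, 2]
        d <- sqrt(dx^2 + dy^2) + 1e-9
        f <- d * ew / kOpt            # (d^2 / k) / d per unit vector
        fx <- dx * f; fy <- dy * f
        disp[, 1] <- disp[, 1] - vsum(ei, fx, n) + vsum(ej, fx, n)
        disp[, 2] <- disp[, 2] - vsum(ei, fy, n) + vsum(ej, fy, n)
        len <- sqrt(rowSums(disp^2)) + 1e-12
        step <- pmin(len, temp) / len
        pos <- pos + disp * step
    }
    new("LayoutResult", coords = pos, iterations = as.integer(iterations),
        seed = as.integer(seed))
}

vsum <- function(idx, val, n) {
    out <- numeric(n)
    agg <- rowsum(val, idx)
    out[as.integer(rownames(agg))] <- agg[, 1]
    out
}

repulsionForces <- function(pos, kOpt, cutoff, exact) {
    n <- nrow(pos)
    if (exact) {
        dx <- outer(pos[, 1], pos[, 1], "-")
        dy <- outer(pos[, 2], pos[, 2], "-")
        d2 <- dx^2 + dy^2
        diag(d2) <- Inf
        d2[d2 < 1e-12] <- 1e-12
        f <- kOpt^2 / d2              # (k^2 / d) / d per unit vector
        cbind(rowSums(dx * f), rowSums(dy * f))
    } else {
        ## grid approximation: only pairs within adjacent cells of side
        ## `cutoff` interact
        cellx <- floor(pos[, 1] / cutoff)
        celly <- floor(pos[, 2] / cutoff)
        key <- paste(cellx, celly)
        buckets <- split(seq_len(n), key)
        coordOf <- function(k) as.numeric(strsplit(k, " ")[[1]])
        disp <- matrix(0, n, 2)
        for (k in names(buckets)) {
            cc <- coordOf(k)
            members <- buckets[[k]]
            neigh <- unlist(lapply(-1:1, function(ox)
                lapply(-1:1, function(oy)
                    buckets[[paste(cc[1] + ox, cc[2] + oy)]])),
                use.names = FALSE)
            if (is.null(neigh)) next
            dx <- outer(pos[members, 1], pos[neigh, 1], "-")
            dy <- outer(pos[members, 2], pos[neigh, 2], "-")
            d2 <- dx^2 + dy^2
            d2[d2 < 1e-12] <- Inf      # self pairs
            f <- kOpt^2 / d2
            f[d2 > cutoff^2] <- 0
            disp[members, 1] <- disp[members, 1] + rowSums(dx * f)
            disp[members, 2] <- disp[members, 2] + rowSums(dy * f)
        }
        disp
    }
}
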