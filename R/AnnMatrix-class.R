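#' @include AllGenerics.R utils.R
NULL

#' File backing descriptor
#'
#' Internal descriptor of the HDF5 backing of an [AnnMatrix-class]: the
#' file path, the on-disk encoding of the matrix (`"array"` for dense,
#' `"csr"` for compressed sparse row), the matrix dimensions, and — for
#' sparse backing — the cached row pointer so row slices can be read
#' without touching the rest of the file.  Backed matrices are read-only;
#' mutation requires [toMemory()].
#'
#' @slot path Path of the HDF5 container.
#' @slot encoding `"array"` or `"csr"`.
#' @slot dims Integer vector `c(n_obs, n_var)`.
#' @slot indptr Cached CSR row pointer (0-based, length `n_obs + 1`), or
#'   `integer(0)` for dense backing.
#' @aliases FileBacking
#' @exportClass FileBacking
setClass("FileBacking",
    representation(path = "character", encoding = "character",
                   dims = "integer", indptr = "numeric"))

#' AnnMatrix: an annotated observations-by-variables matrix
#'
#' The central data container: a numeric matrix `X` with observations
#' (cells) as rows and variables (genes) as columns, together with axis
#' annotation tables `obs` and `var` (data frames keyed by the axis
#' names), a free-form named list `uns` of unstructured metadata, and an
#' optional HDF5 [FileBacking-class] in which case `X` stays on disk and
#' slices are read on demand.
#'
#' Construct with [AnnMatrix()]; read and write with [readH5AM()] /
#' [writeH5AM()]; subset with `a[i, j]` where `i` and `j` may be logical
#' masks, integer indices, or name vectors.
#'
#' @slot X The data matrix (base matrix or sparse `Matrix`); a 0x0 matrix
#'   when the object is backed.
#' @slot obs Per-observation annotation `data.frame` (row names =
#'   observation names).
#' @slot var Per-variable annotation `data.frame` (row names = variable
#'   names).
#' @slot uns Named list of unstructured annotations.
#' @slot backing A [FileBacking-class], or `NULL` in memory mode.
#' @aliases AnnMatrix-class
#' @exportClass AnnMatrix
setClass("AnnMatrix",
    representation(X = "ANY", obs = "data.frame", var = "data.frame",
                   uns = "list", backing = "ANY"),
    prototype(X = matrix(numeric(0), 0, 0), uns = list(), backing = NULL))

setValidity("AnnMatrix", function(object) {
    msg <- character(0)
    no <- nrow(object@obs)
    nv <- nrow(object@var)
    if (is.null(object@backing)) {
        if (!(is.matrix(object@X) || isSparse(object@X)))
            msg <- c(msg, "X must be a base matrix or a sparse Matrix")
        else {
            if (nrow(object@X) != no)
                msg <- c(msg, sprintf("nrow(X) = %d but %d obs names (obs axis)",
                                      nrow(object@X), no))
            if (ncol(object@X) != nv)
                msg <- c(msg, sprintf("ncol(X) = %d but %d var names (var axis)",
                                      ncol(object@X), nv))
        }
    } else {
        if (!methods::is(object@backing, "FileBacking"))
            msg <- c(msg, "backing must be a FileBacking or NULL")
        else if (!identical(object@backing@dims, c(no, nv)))
            msg <- c(msg, "backing dims disagree with axis lengths")
    }
    if (anyDuplicated(rownames(object@obs)))
        msg <- c(msg, "obs names are not unique")
    if (anyDuplicated(rownames(object@var)))
        msg <- c(msg, "var names are not unique")
    if (length(object@uns) && is.null(names(object@uns)))
        msg <- c(msg, "uns must be a named list")
    if (length(msg)) msg else TRUE
})

#' Create an AnnMatrix
#'
#' @param X Numeric matrix (dense base matrix or sparse `Matrix`),
#'   observations as rows, variables as columns.  Sparse input stays
#'   sparse.
#' @param obsNames,varNames Character vectors naming the rows / columns of
#'   `X`.  Default: taken from `dimnames(X)`, else `"obs1"... ` /
#'   `"var1"...`.  Duplicates are uniquified with `-1`, `-2`, ... suffixes
#'   (with a warning).
#' @param obs,var Optional data frames (or named lists of vectors) of
#'   per-axis annotation columns.
#' @param uns Optional named list of unstructured annotations.
#' @return An [AnnMatrix-class] in memory mode.
#' @examples
#' a <- AnnMatrix(matrix(1:6, 2, 3), obsNames = c("c1", "c2"),
#'                varNames = c("g1", "g2", "g3"))
#' nObs(a); nVar(a)
#' @export
AnnMatrix <- function(X, obsNames = NULL, varNames = NULL,
                      obs = NULL, var = NULL, uns = list()) {
    if (!(is.matrix(X) || isSparse(X))) {
        if (is.numeric(X) && !is.null(dim(X))) X <- as.matrix(X)
        else stopf("X must be a matrix or sparse Matrix")
    }
    if (is.null(obsNames))
        obsNames <- if (!is.null(rownames(X))) rownames(X)
                    else paste0("obs", seq_len(nrow(X)))
    if (is.null(varNames))
        varNames <- if (!is.null(colnames(X))) colnames(X)
                    else paste0("var", seq_len(ncol(X)))
    obsNames <- as.character(obsNames)
    varNames <- as.character(varNames)
    if (length(obsNames) != nrow(X))
        stopf("obs axis: %d names for %d rows of X", length(obsNames), nrow(X))
    if (length(varNames) != ncol(X))
        stopf("var axis: %d names for %d columns of X", length(varNames), ncol(X))
    obsNames <- uniquifyNames(obsNames, "obs")
    varNames <- uniquifyNames(varNames, "var")

    obs <- makeAxisTable(obs, obsNames, "obs")
    var <- makeAxisTable(var, varNames, "var")
    dimnames(X) <- NULL
    if (length(uns) && is.null(names(uns)))
        stopf("uns must be a named list")
    new("AnnMatrix", X = X, obs = obs, var = var, uns = uns, backing = NULL)
}

makeAxisTable <- function(tab, idx, axis) {
    n <- length(idx)
    if (is.null(tab)) {
        out <- data.frame(row.names = idx)
    } else {
        if (!is.data.frame(tab)) tab <- as.data.frame(tab, stringsAsFactors = FALSE)
        if (nrow(tab) != n)
            stopf("%s table has %d rows, axis has length %d (%s axis)",
                  axis, nrow(tab), n, axis)
        out <- tab
        rownames(out) <- idx
    }
    out
}

## ---- accessors ------------------------------------------------------------

#' @rdname nObs
#' @export
setMethod("nObs", "AnnMatrix", function(x) nrow(x@obs))

#' @rdname nObs
#' @export
setMethod("nVar", "AnnMatrix", function(x) nrow(x@var))

#' @describeIn AnnMatrix `dim(a)` is `c(nObs, nVar)`.
#' @param x An `AnnMatrix`.
#' @export
setMethod("dim", "AnnMatrix", function(x) c(nObs(x), nVar(x)))

#' @rdname obsNames
#' @export
setMethod("obsNames", "AnnMatrix", function(x) rownames(x@obs))

#' @rdname obsNames
#' @export
setMethod("varNames", "AnnMatrix", function(x) rownames(x@var))

#' @rdname obsTable
#' @export
setMethod("obsTable", "AnnMatrix", function(x) x@obs)

#' @rdname obsTable
#' @export
setMethod("obsTable<-", "AnnMatrix", function(x, value) {
    x@obs <- makeAxisTable(value, obsNames(x), "obs")
    validObject(x)
    x
})

#' @rdname obsTable
#' @export
setMethod("varTable", "AnnMatrix", function(x) x@var)

#' @rdname obsTable
#' @export
setMethod("varTable<-", "AnnMatrix", function(x, value) {
    x@var <- makeAxisTable(value, varNames(x), "var")
    validObject(x)
    x
})

#' @rdname uns
#' @export
setMethod("uns", "AnnMatrix", function(x) x@uns)

#' @rdname uns
#' @export
setMethod("uns<-", "AnnMatrix", function(x, value) {
    if (length(value) && is.null(names(value)))
        stopf("uns must be a named list")
    x@uns <- value
    x
})

#' @rdname isBacked
#' @export
setMethod("isBacked", "AnnMatrix", function(x) !is.null(x@backing))

#' @rdname xData
#' @export
setMethod("xData", "AnnMatrix", function(x) {
    if (isBacked(x)) backedRead(x@backing, NULL, NULL) else x@X
})

#' @rdname xData
#' @export
setMethod("xData<-", "AnnMatrix", function(x, value) {
    if (isBacked(x))
        stopf("backed AnnMatrix is read-only; call toMemory() first")
    if (!identical(dim(value), dim(x)))
        stopf("replacement X must be %d x %d", nObs(x), nVar(x))
    dimnames(value) <- NULL
    x@X <- value
    x
})

#' @rdname isBacked
#' @export
setMethod("toMemory", "AnnMatrix", function(x) {
    if (!isBacked(x)) return(x)
    X <- backedRead(x@backing, NULL, NULL)
    new("AnnMatrix", X = X, obs = x@obs, var = x@var, uns = x@uns,
        backing = NULL)
})

## ---- slicing --------------------------------------------------------------

#' @describeIn AnnMatrix Subset observations and/or variables.  Selectors
#'   may be logical masks, 1-based integer vectors (repeats and reordering
#'   allowed), or name vectors.  Works identically in memory and backed
#'   mode; a backed slice reads only the needed blocks from disk and
#'   returns an in-memory object.
#' @param i,j Observation / variable selectors.
#' @param drop Ignored (kept for generic compatibility; never drops).
#' @param ... Ignored.
#' @export
setMethod("[", "AnnMatrix", function(x, i, j, ..., drop = FALSE) {
    oi <- if (missing(i)) NULL else i
    vj <- if (missing(j)) NULL else j
    oi <- resolveSelector(oi, obsNames(x), "obs")
    vj <- resolveSelector(vj, varNames(x), "var")
    X <- if (isBacked(x)) backedRead(x@backing, oi, vj)
         else x@X[oi, vj, drop = FALSE]
    newObs <- x@obs[oi, , drop = FALSE]
    newVar <- x@var[vj, , drop = FALSE]
    rownames(newObs) <- uniquifyNames(rownames(x@obs)[oi], "obs")
    rownames(newVar) <- uniquifyNames(rownames(x@var)[vj], "var")
    new("AnnMatrix", X = X, obs = newObs, var = newVar, uns = x@uns,
        backing = NULL)
})

## ---- show -----------------------------------------------------------------

setMethod("show", "AnnMatrix", function(object) {
    kind <- if (isBacked(object)) {
        sprintf("backed (%s, %s)", object@backing@encoding,
                object@backing@path)
    } else if (isSparse(object@X)) {
        sprintf("sparse, %d stored values", length(object@X@x))
    } else "dense"
    cat(sprintf("AnnMatrix: %d obs x %d var (%s)\n",
                nObs(object), nVar(object), kind))
    if (ncol(object@obs))
        cat("  obs columns:", paste(colnames(object@obs), collapse = ", "), "\n")
    if (ncol(object@var))
        cat("  var columns:", paste(colnames(object@var), collapse = ", "), "\n")
    if (length(object@uns))
        cat("  uns keys:", paste(names(object@uns), collapse = ", "), "\n")
    invisible(NULL)
})
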