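#' @include scamp-package.R
NULL

#' Number of observations / variables
#'
#' Axis sizes of an [AnnMatrix-class]: observations are samples (cells),
#' variables are features (genes).
#'
#' @param x An `AnnMatrix`.
#' @return An integer scalar.
#' @export
setGeneric("nObs", function(x) standardGeneric("nObs"))

#' @rdname nObs
#' @export
setGeneric("nVar", function(x) standardGeneric("nVar"))

#' Axis names
#'
#' Observation and variable names of an [AnnMatrix-class].
#'
#' @param x An `AnnMatrix`.
#' @return A character vector.
#' @export
setGeneric("obsNames", function(x) standardGeneric("obsNames"))

#' @rdname obsNames
#' @export
setGeneric("varNames", function(x) standardGeneric("varNames"))

#' Axis annotation tables
#'
#' Per-observation and per-variable annotation tables (data frames whose
#' row names are the axis names).
#'
#' @param x An `AnnMatrix`.
#' @param value A `data.frame` with one row per axis element.
#' @return A `data.frame`.
#' @export
setGeneric("obsTable", function(x) standardGeneric("obsTable"))

#' @rdname obsTable
#' @export
setGeneric("obsTable<-", function(x, value) standardGeneric("obsTable<-"))

#' @rdname obsTable
#' @export
setGeneric("varTable", function(x) standardGeneric("varTable"))

#' @rdname obsTable
#' @export
setGeneric("varTable<-", function(x, value) standardGeneric("varTable<-"))

#' Unstructured annotations
#'
#' The string-keyed map of unstructured metadata attached to an
#' [AnnMatrix-class] (named list; values may be scalars, vectors, matrices,
#' sparse matrices, or nested named lists).
#'
#' @param x An `AnnMatrix`.
#' @param value A named list.
#' @return A named list.
#' @export
setGeneric("uns", function(x) standardGeneric("uns"))

#' @rdname uns
#' @export
setGeneric("uns<-", function(x, value) standardGeneric("uns<-"))

#' Data matrix access
#'
#' The observations-by-variables data matrix.  For a file-backed
#' `AnnMatrix` this reads the matrix (or a slice of it) from disk; in
#' memory mode it returns the resident matrix.
#'
#' @param x An `AnnMatrix`.
#' @param value A matrix or sparse `Matrix` with matching dimensions.
#' @return A base matrix or a `Matrix` sparse matrix.
#' @export
setGeneric("xData", function(x) standardGeneric("xData"))

#' @rdname xData
#' @export
setGeneric("xData<-", function(x, value) standardGeneric("xData<-"))

#' Backing state
#'
#' Whether an [AnnMatrix-class] is backed by an HDF5 file (`isBacked`),
#' and conversion of a backed object to memory mode (`toMemory`).
#'
#' @param x An `AnnMatrix`.
#' @return `isBacked`: a logical scalar. `toMemory`: an in-memory
#'   `AnnMatrix`.
#' @export
setGeneric("isBacked", function(x) standardGeneric("isBacked"))

#' @rdname isBacked
#' @export
setGeneric("toMemory", function(x) standardGeneric("toMemory"))

#' Neighbor-graph component access
#'
#' Accessors for the pieces of a [NeighborGraph-class]: the sparse kNN
#' distance matrix, the symmetric connectivity weights, the per-node kernel
#' widths, and the row-stochastic transition operator.
#'
#' @param x A `NeighborGraph`.
#' @return A sparse `Matrix` (or numeric vector for `kernelWidths`).
#' @export
setGeneric("knnDistances", function(x) standardGeneric("knnDistances"))

#' @rdname knnDistances
#' @export
setGeneric("connectivities", function(x) standardGeneric("connectivities"))

#' @rdname knnDistances
#' @export
setGeneric("kernelWidths", function(x) standardGeneric("kernelWidths"))

#' @rdname knnDistances
#' @export
setGeneric("transitions", function(x) standardGeneric("transitions"))
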