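#' @include io-h5am.R
NULL

#' Export an AnnMatrix to a loom file
#'
#' Writes the loom convention: the main dataset `matrix` holds variables
#' (genes) as rows and observations (cells) as columns; per-variable
#' annotations go to `row_attrs` (names under `var_names`) and
#' per-observation annotations to `col_attrs` (names under `obs_names`).
#' Only flat annotation columns can be represented; nested `uns` values
#' have no loom slot and are skipped with a warning.
#'
#' @param a An [AnnMatrix-class].
#' @param path Output path; an existing file is replaced.
#' @return `path`, invisibly.
#' @seealso [importLoom()]
#' @export
exportLoom <- function(a, path) {
    stopifnot(methods::is(a, "AnnMatrix"))
    if (isBacked(a)) a <- toMemory(a)
    if (file.exists(path)) file.remove(path)
    rhdf5::h5createFile(path)
    on.exit(h5closeAll(), add = TRUE)

    ## An R matrix of dim (n_obs, n_var) serializes to an HDF5 dataset of
    ## shape (n_var, n_obs) in C order, which is exactly the loom layout.
    X <- a@X
    if (isSparse(X)) X <- as.matrix(X)
    rhdf5::h5write(X, path, "matrix")

    rhdf5::h5createGroup(path, "row_attrs")
    rhdf5::h5write(varNames(a), path, "row_attrs/var_names")
    for (cn in colnames(a@var))
        writeLoomAttr(a@var[[cn]], path, paste0("row_attrs/", cn))
    rhdf5::h5createGroup(path, "col_attrs")
    rhdf5::h5write(obsNames(a), path, "col_attrs/obs_names")
    for (cn in colnames(a@obs))
        writeLoomAttr(a@obs[[cn]], path, paste0("col_attrs/", cn))
    if (length(a@uns))
        warnf("loom has no slot for unstructured annotations; skipping uns keys: %s",
              paste(names(a@uns), collapse = ", "))
    invisible(path)
}

writeLoomAttr <- function(col, path, tgt) {
    if (is.factor(col)) col <- as.character(col)
    if (is.logical(col)) col <- as.integer(col)
    rhdf5::h5write(col, path, tgt)
}

#' Import a loom file
#'
#' Reads a loom file written by [exportLoom()] (or following the same
#' core layout), transposing back to the observations-by-variables
#' orientation.
#'
#' @param path Loom file path.
#' @return An [AnnMatrix-class] in memory mode.
#' @export
importLoom <- function(path) {
    if (!file.exists(path)) stopf("no such file: %s", path)
    on.exit(h5closeAll(), add = TRUE)
    ls <- h5listing(path)
    if (!h5exists(ls, "/matrix"))
        stopf("loom format error: missing dataset 'matrix'")
    X <- rhdf5::h5read(path, "matrix")   # back to (n_obs, n_var) in R
    storage.mode(X) <- "double"
    readAttrs <- function(group, special) {
        out <- list(names = NULL, cols = list())
        if (!h5exists(ls, group)) return(out)
        kids <- ls[ls$group == group & ls$otype == "H5I_DATASET", , drop = FALSE]
        for (k in seq_len(nrow(kids))) {
            val <- rhdf5::h5read(path, kids$full[k])
            if (is.array(val) && length(dim(val)) == 1L) val <- as.vector(val)
            if (kids$name[k] == special) out$names <- as.character(val)
            else out$cols[[kids$name[k]]] <- val
        }
        out
    }
    ra <- readAttrs("/row_attrs", "var_names")
    ca <- readAttrs("/col_attrs", "obs_names")
    AnnMatrix(X,
              obsNames = ca$names %||% paste0("obs", seq_len(nrow(X))),
              varNames = ra$names %||% paste0("var", seq_len(ncol(X))),
              obs = if (length(ca$cols)) ca$cols else NULL,
              var = if (length(ra$cols)) ra$cols else NULL)
}
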