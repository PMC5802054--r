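#' @include AnnMatrix-class.R
NULL

## Container layout (all under one HDF5 file):
##   /            attrs: n_obs, n_var
##   /X           dense 2-D dataset (attr encoding = "array"), or group with
##                data / indices / indptr datasets (attr encoding = "csr",
##                attr shape = c(n_obs, n_var)); CSR indices are 0-based
##   /obs, /var   groups: "_index" dataset plus one dataset per column;
##                factor columns as subgroup {codes, categories} with
##                attr encoding = "categorical"; logical columns as integer
##                datasets with attr encoding = "bool"
##   /uns         group mirroring the nested named list; sparse values as
##                csr subgroups, nested lists as subgroups

H5AM_ENCODINGS <- c("array", "csr")

h5closeAll <- function() rhdf5::h5closeAll()

h5setAttr <- function(path, objname, name, value) {
    fid <- rhdf5::H5Fopen(path)
    on.exit(rhdf5::H5Fclose(fid), add = TRUE)
    oid <- rhdf5::H5Oopen(fid, objname)
    on.exit(rhdf5::H5Oclose(oid), add = TRUE, after = FALSE)
    rhdf5::h5writeAttribute(value, oid, name)
    invisible(NULL)
}

h5getAttrs <- function(path, objname) {
    rhdf5::h5readAttributes(path, objname)
}

h5exists <- function(ls, name) name %in% ls$full

h5listing <- function(path) {
    ls <- rhdf5::h5ls(path)
    ls$full <- ifelse(ls$group == "/", paste0("/", ls$name),
                      paste(ls$group, ls$name, sep = "/"))
    ls
}

writeSparseCsr <- function(X, path, name) {
    Xr <- methods::as(methods::as(X, "generalMatrix"), "RsparseMatrix")
    rhdf5::h5createGroup(path, name)
    rhdf5::h5write(Xr@x, path, paste0(name, "/data"))
    rhdf5::h5write(as.integer(Xr@j), path, paste0(name, "/indices"))
    rhdf5::h5write(as.numeric(Xr@p), path, paste0(name, "/indptr"))
    h5setAttr(path, name, "encoding", "csr")
    h5setAttr(path, name, "shape", as.numeric(dim(X)))
}

readSparseCsr <- function(path, name) {
    at <- h5getAttrs(path, name)
    shape <- as.numeric(at$shape)
    x <- as.numeric(rhdf5::h5read(path, paste0(name, "/data")))
    j <- as.integer(rhdf5::h5read(path, paste0(name, "/indices")))
    p <- as.numeric(rhdf5::h5read(path, paste0(name, "/indptr")))
    i <- rep.int(seq_len(shape[1]), diff(p))
    Matrix::sparseMatrix(i = i, j = j + 1L, x = x,
                         dims = shape, repr = "C")
}

writeAxisTable <- function(tab, path, name) {
    rhdf5::h5createGroup(path, name)
    rhdf5::h5write(rownames(tab), path, paste0(name, "/_index"))
    for (cn in colnames(tab)) {
        col <- tab[[cn]]
        tgt <- paste0(name, "/", cn)
        if (is.factor(col)) {
            rhdf5::h5createGroup(path, tgt)
            rhdf5::h5write(as.integer(col) - 1L, path, paste0(tgt, "/codes"))
            rhdf5::h5write(levels(col), path, paste0(tgt, "/categories"))
            h5setAttr(path, tgt, "encoding", "categorical")
        } else if (is.logical(col)) {
            rhdf5::h5write(as.integer(col), path, tgt)
            h5setAttr(path, tgt, "encoding", "bool")
        } else if (is.numeric(col) || is.character(col)) {
            rhdf5::h5write(col, path, tgt)
        } else {
            stopf("cannot store %s column '%s' of class %s in the container",
                  name, cn, class(col)[1])
        }
    }
}

readAxisTable <- function(path, name, ls) {
    idxName <- paste0(name, "/_index")
    if (!h5exists(ls, idxName))
        stopf("container format error: missing dataset '%s'", idxName)
    idx <- as.character(rhdf5::h5read(path, idxName))
    children <- ls[ls$group == name & ls$name != "_index", , drop = FALSE]
    tab <- data.frame(row.names = idx)
    for (k in seq_len(nrow(children))) {
        cn <- children$name[k]
        full <- children$full[k]
        if (children$otype[k] == "H5I_GROUP") {
            at <- h5getAttrs(path, full)
            enc <- as.character(at$encoding %||% "")
            if (!identical(enc, "categorical"))
                stopf("container format error: unknown encoding '%s' at %s",
                      enc, full)
            codes <- as.integer(rhdf5::h5read(path, paste0(full, "/codes")))
            cats <- as.character(rhdf5::h5read(path, paste0(full, "/categories")))
            tab[[cn]] <- factor(cats[codes + 1L], levels = cats)
        } else {
            at <- h5getAttrs(path, full)
            val <- rhdf5::h5read(path, full)
            if (identical(as.character(at$encoding %||% ""), "bool"))
                val <- as.logical(val)
            if (is.array(val) && length(dim(val)) == 1L) val <- as.vector(val)
            tab[[cn]] <- val
        }
    }
    tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a

writeUnsValue <- function(value, path, name, key = name) {
    if (isSparse(value)) {
        writeSparseCsr(value, path, name)
    } else if (is.list(value)) {
        if (length(value) && is.null(names(value)))
            stopf("uns entry '%s': nested lists must be named", key)
        rhdf5::h5createGroup(path, name)
        h5setAttr(path, name, "encoding", "mapping")
        for (k in names(value))
            writeUnsValue(value[[k]], path, paste0(name, "/", k), k)
    } else if (is.logical(value)) {
        rhdf5::h5write(as.integer(value), path, name)
        h5setAttr(path, name, "encoding", "bool")
    } else if (is.numeric(value) || is.character(value)) {
        rhdf5::h5write(value, path, name)
    } else {
        stopf("uns entry '%s': cannot store class %s in the container",
              key, class(value)[1])
    }
}

readUnsGroup <- function(path, name, ls) {
    children <- ls[ls$group == name, , drop = FALSE]
    out <- list()
    for (k in seq_len(nrow(children))) {
        cn <- children$name[k]
        full <- children$full[k]
        if (children$otype[k] == "H5I_GROUP") {
            at <- h5getAttrs(path, full)
            enc <- as.character(at$encoding %||% "mapping")
            if (identical(enc, "csr")) {
                out[[cn]] <- readSparseCsr(path, full)
            } else if (identical(enc, "mapping")) {
                out[[cn]] <- readUnsGroup(path, full, ls)
            } else {
                stopf("container format error: unknown encoding '%s' at %s",
                      enc, full)
            }
        } else {
            at <- h5getAttrs(path, full)
            val <- rhdf5::h5read(path, full)
            if (identical(as.character(at$encoding %||% ""), "bool"))
                val <- as.logical(val)
            if (is.array(val) && length(dim(val)) == 1L) val <- as.vector(val)
            out[[cn]] <- val
        }
    }
    out
}

#' Write an AnnMatrix to its HDF5 container
#'
#' Serializes the full object — `X` (dense as a 2-D dataset, sparse in a
#' compressed row-major layout), both axis tables including categorical
#' columns, and the nested `uns` map — to a single HDF5 file.  A
#' write-then-read round trip in memory mode reproduces the object
#' exactly (bit-equal floats).
#'
#' @param a An in-memory [AnnMatrix-class] (convert backed objects with
#'   [toMemory()] first).
#' @param path Output file path; an existing file is replaced.
#' @return `path`, invisibly.
#' @seealso [readH5AM()]
#' @export
writeH5AM <- function(a, path) {
    stopifnot(methods::is(a, "AnnMatrix"))
    if (isBacked(a)) a <- toMemory(a)
    if (file.exists(path)) file.remove(path)
    rhdf5::h5createFile(path)
    on.exit(h5closeAll(), add = TRUE)

    if (isSparse(a@X)) {
        writeSparseCsr(a@X, path, "X")
    } else {
        rhdf5::h5write(a@X, path, "X")
        h5setAttr(path, "X", "encoding", "array")
    }
    writeAxisTable(a@obs, path, "obs")
    writeAxisTable(a@var, path, "var")
    rhdf5::h5createGroup(path, "uns")
    h5setAttr(path, "uns", "encoding", "mapping")
    for (k in names(a@uns))
        writeUnsValue(a@uns[[k]], path, paste0("uns/", k), k)
    h5setAttr(path, "/", "n_obs", as.numeric(nObs(a)))
    h5setAttr(path, "/", "n_var", as.numeric(nVar(a)))
    invisible(path)
}

#' Read an AnnMatrix from its HDF5 container
#'
#' In memory mode the whole object is loaded.  With `backed = TRUE` the
#' axis tables and `uns` are loaded but `X` stays in the file; slices of
#' the returned object read only the blocks they need, and element values
#' are identical to memory mode.  Backed objects are read-only for `X`.
#'
#' @param path Path of a container written by [writeH5AM()].
#' @param backed Keep `X` on disk? (default `FALSE`).
#' @return An [AnnMatrix-class].
#' @export
readH5AM <- function(path, backed = FALSE) {
    if (!file.exists(path)) stopf("no such file: %s", path)
    on.exit(h5closeAll(), add = TRUE)
    ls <- h5listing(path)
    for (req in c("/X", "/obs", "/var"))
        if (!h5exists(ls, req))
            stopf("container format error: missing dataset '%s'", req)
    obs <- readAxisTable(path, "/obs", ls)
    var <- readAxisTable(path, "/var", ls)
    unsv <- if (h5exists(ls, "/uns")) readUnsGroup(path, "/uns", ls) else list()

    xIsGroup <- ls$otype[ls$full == "/X"][1] == "H5I_GROUP"
    enc <- as.character(h5getAttrs(path, "X")$encoding %||%
                        if (xIsGroup) "csr" else "array")
    if (!enc %in% H5AM_ENCODINGS)
        stopf("container format error: unknown encoding '%s' for X", enc)

    if (backed) {
        indptr <- if (enc == "csr")
            as.numeric(rhdf5::h5read(path, "X/indptr")) else numeric(0)
        dims <- if (enc == "csr")
            as.integer(h5getAttrs(path, "X")$shape)
        else {
            d <- ls[ls$full == "/X", "dim"]
            as.integer(rev(strsplit(d, " x ")[[1]]))
        }
        bk <- new("FileBacking", path = path, encoding = enc,
                  dims = c(nrow(obs), nrow(var)), indptr = indptr)
        return(new("AnnMatrix", X = matrix(numeric(0), 0, 0), obs = obs,
                   var = var, uns = unsv, backing = bk))
    }
    X <- if (enc == "csr") readSparseCsr(path, "X")
         else {
             m <- rhdf5::h5read(path, "X")
             storage.mode(m) <- "double"
             m
         }
    new("AnnMatrix", X = X, obs = obs, var = var, uns = unsv, backing = NULL)
}

## Read rows/cols of a backed X.  oi/vj are 1-based index vectors or NULL
## for "all"; repeats and reordering are honored.  Only the needed blocks
## are read: dense via hyperslab selection on unique sorted indices, CSR
## via contiguous runs of the row pointer.
backedRead <- function(bk, oi, vj) {
    on.exit(h5closeAll(), add = TRUE)
    nO <- bk@dims[1]; nV <- bk@dims[2]
    if (is.null(oi)) oi <- seq_len(nO)
    if (is.null(vj)) vj <- seq_len(nV)
    if (bk@encoding == "array") {
        ui <- sort(unique(oi)); uj <- sort(unique(vj))
        m <- rhdf5::h5read(bk@path, "X", index = list(ui, uj))
        storage.mode(m) <- "double"
        m <- m[match(oi, ui), match(vj, uj), drop = FALSE]
        dimnames(m) <- NULL
        return(m)
    }
    ## CSR
    ptr <- bk@indptr
    ui <- sort(unique(oi))
    runs <- split(ui, cumsum(c(1L, diff(ui) != 1L)))
    xs <- list(); js <- list(); lens <- integer(length(ui))
    pos <- 1L
    for (r in runs) {
        from <- ptr[r[1]] + 1
        to <- ptr[r[length(r)] + 1]
        if (to >= from) {
            sel <- list(seq.int(from, to))
            xs[[length(xs) + 1L]] <- as.numeric(
                rhdf5::h5read(bk@path, "X/data", index = sel))
            js[[length(js) + 1L]] <- as.integer(
                rhdf5::h5read(bk@path, "X/indices", index = sel))
        }
        lens[pos:(pos + length(r) - 1L)] <- as.integer(diff(ptr[c(r, r[length(r)] + 1L)]))
        pos <- pos + length(r)
    }
    x <- unlist(xs, use.names = FALSE)
    j <- unlist(js, use.names = FALSE)
    i <- rep.int(seq_along(ui), lens)
    M <- Matrix::sparseMatrix(i = i, j = (j %||% integer(0)) + 1L,
                              x = x %||% numeric(0),
                              dims = c(length(ui), nV), repr = "C")
    M[match(oi, ui), vj, drop = FALSE]
}
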