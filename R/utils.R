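#' @include scamp-package.R
NULL

# Uniquify names by appending "-1", "-2", ... to repeats; warns once.
uniquifyNames <- function(x, axis = "axis") {
    if (!anyDuplicated(x)) return(x)
    warning(sprintf("non-unique %s names; uniquifying with '-<k>' suffixes", axis),
            call. = FALSE)
    counts <- new.env(parent = emptyenv())
    out <- character(length(x))
    for (i in seq_along(x)) {
        nm <- x[i]
        k <- if (is.null(counts[[nm]])) 0L else counts[[nm]]
        counts[[nm]] <- k + 1L
        out[i] <- if (k == 0L) nm else {
            # keep appending until the suffixed name is itself unused
            cand <- paste0(nm, "-", k)
            while (!is.null(counts[[cand]])) {
                k <- k + 1L
                counts[[nm]] <- k + 1L
                cand <- paste0(nm, "-", k)
            }
            counts[[cand]] <- 1L
            cand
        }
    }
    out
}

isSparse <- function(x) methods::is(x, "sparseMatrix")

colMeansAny <- function(x) {
    if (isSparse(x)) Matrix::colMeans(x) else colMeans(x)
}

rowSumsAny <- function(x) {
    if (isSparse(x)) Matrix::rowSums(x) else rowSums(x)
}

colSums2Any <- function(x) {
    if (isSparse(x)) Matrix::colSums(x^2) else colSums(x^2)
}

# Per-gene mean and sample variance without densifying.
colMeanVar <- function(x) {
    n <- nrow(x)
    mu <- colMeansAny(x)
    s2 <- if (n < 2) rep(0, ncol(x)) else (colSums2Any(x) - n * mu^2) / (n - 1)
    s2[s2 < 0] <- 0
    list(mean = mu, var = s2)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Resolve an axis selector (logical mask / integer indices / names / NULL)
# to positive integer indices along an axis with the given names.
resolveSelector <- function(sel, names, axis = "obs") {
    n <- length(names)
    if (is.null(sel)) return(seq_len(n))
    if (is.logical(sel)) {
        if (length(sel) != n)
            stopf("logical %s selector has length %d, axis has length %d",
                  axis, length(sel), n)
        return(which(sel))
    }
    if (is.numeric(sel)) {
        sel <- as.integer(sel)
        if (any(sel < 1L | sel > n))
            stopf("integer %s selector out of range [1, %d]", axis, n)
        return(sel)
    }
    if (is.character(sel)) {
        idx <- match(sel, names)
        if (anyNA(idx))
            stopf("unknown %s name(s): %s", axis,
                  paste(sel[is.na(idx)], collapse = ", "))
        return(idx)
    }
    stopf("unsupported %s selector of class %s", axis, class(sel)[1])
}
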