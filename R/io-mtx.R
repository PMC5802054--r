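#' @include AnnMatrix-class.R
NULL

#' Import a 10x-style MatrixMarket directory
#'
#' Reads the classic triplet layout: `matrix.mtx` (MatrixMarket
#' coordinate format, genes as rows and cells as columns), `genes.tsv`
#' (gene id and symbol columns), and `barcodes.tsv`.  The matrix is
#' transposed so cells become observations; variable names are the gene
#' symbols (uniquified if duplicated, with a warning) and the gene ids
#' are kept in the `gene_id` var column.
#'
#' @param dirPath Directory containing the three files.
#' @return A sparse [AnnMatrix-class].
#' @export
read10xMtx <- function(dirPath) {
    if (!dir.exists(dirPath)) stopf("no such directory: %s", dirPath)
    mtx <- file.path(dirPath, "matrix.mtx")
    genes <- file.path(dirPath, "genes.tsv")
    barcodes <- file.path(dirPath, "barcodes.tsv")
    for (f in c(mtx, genes, barcodes))
        if (!file.exists(f)) stopf("missing sidecar file: %s", f)

    M <- withCallingHandlers(
        Matrix::readMM(mtx),
        warning = function(w) {
            stopf("matrix.mtx format error: %s", conditionMessage(w))
        })
    M <- methods::as(methods::as(Matrix::t(M), "CsparseMatrix"), "dMatrix")

    gtab <- read.delim(genes, header = FALSE, stringsAsFactors = FALSE)
    if (nrow(gtab) != ncol(M))
        stopf("genes.tsv has %d rows but matrix has %d genes",
              nrow(gtab), ncol(M))
    bc <- read.delim(barcodes, header = FALSE, stringsAsFactors = FALSE)[[1]]
    if (length(bc) != nrow(M))
        stopf("barcodes.tsv has %d rows but matrix has %d cells",
              length(bc), nrow(M))

    symbols <- if (ncol(gtab) >= 2) gtab[[2]] else gtab[[1]]
    AnnMatrix(M, obsNames = bc, varNames = symbols,
              var = data.frame(gene_id = gtab[[1]],
                               stringsAsFactors = FALSE))
}
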