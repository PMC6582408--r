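#' Read an expression matrix from disk
#'
#' Two dialects are supported. `dense`: a UTF-8 TSV/CSV with a header row of
#' cell ids and gene ids in the first column. `mtx`: a MatrixMarket
#' coordinate file accompanied by `genes.txt` and `cells.txt` sidecars (one
#' identifier per line) in the same directory; zeros absent from the triplet
#' file materialize as 0.
#'
#' @param path file path (for `mtx`, the `.mtx` file).
#' @param format `"auto"` (by extension), `"dense"` or `"mtx"`.
#' @param sep field separator for dense files; guessed from the extension
#'   (`.csv` is comma, anything else tab) when `NULL`.
#' @param genes_file,cells_file sidecar paths for `mtx` input; default
#'   `genes.txt` / `cells.txt` next to the matrix file.
#' @param transpose set `TRUE` if the dense file is cells x genes.
#' @return validated genes x cells expression matrix.
#' @export
read_expression <- function(path, format = c("auto", "dense", "mtx"), sep = NULL,
                            genes_file = NULL, cells_file = NULL,
                            transpose = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.mtx(\\.gz)?$", path)) "mtx" else "dense"
  if (format == "mtx") {
    mat <- as.matrix(Matrix::readMM(path))
    if (is.null(genes_file)) genes_file <- file.path(dirname(path), "genes.txt")
    if (is.null(cells_file)) cells_file <- file.path(dirname(path), "cells.txt")
    if (!file.exists(genes_file)) stop("missing row-name sidecar: ", genes_file)
    if (!file.exists(cells_file)) stop("missing column-name sidecar: ", cells_file)
    gene_ids <- readLines(genes_file)
    cell_ids <- readLines(cells_file)
    if (length(gene_ids) != nrow(mat))
      stop("genes.txt has ", length(gene_ids), " ids but matrix has ",
           nrow(mat), " rows")
    if (length(cell_ids) != ncol(mat))
      stop("cells.txt has ", length(cell_ids), " ids but matrix has ",
           ncol(mat), " columns")
    dimnames(mat) <- list(gene_ids, cell_ids)
  } else {
    if (is.null(sep)) sep <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
    df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                            check.names = FALSE, quote = "",
                            comment.char = "", stringsAsFactors = FALSE)
    if (ncol(df) == 0) stop("parse error in ", path, ": no data columns (line 1)")
    bad <- which(!vapply(df, is.numeric, logical(1)))
    if (length(bad))
      stop("parse error in ", path, ": non-numeric column '",
           colnames(df)[bad[1]], "'")
    mat <- as.matrix(df)
  }
  if (transpose) mat <- t(mat)
  storage.mode(mat) <- "double"
  validate_gem(mat)
  mat
}

#' Write an expression (or degree) matrix to disk
#'
#' `dense` writes the TSV/CSV dialect read by [read_expression()]; `mtx`
#' writes MatrixMarket coordinate format plus `genes.txt` / `cells.txt`
#' sidecars.
#'
#' @param gem validated matrix (GEM or NDM).
#' @param path output path.
#' @param format `"dense"` or `"mtx"`.
#' @param sep field separator for dense output (default by extension).
#' @return `path`, invisibly.
#' @export
write_expression <- function(gem, path, format = c("dense", "mtx"), sep = NULL) {
  format <- match.arg(format)
  validate_gem(gem)
  if (format == "mtx") {
    Matrix::writeMM(methods::as(Matrix::Matrix(gem, sparse = TRUE), "CsparseMatrix"), path)
    writeLines(rownames(gem), file.path(dirname(path), "genes.txt"))
    writeLines(colnames(gem), file.path(dirname(path), "cells.txt"))
  } else {
    if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(c("gene_id", colnames(gem)), collapse = sep), con)
    utils::write.table(gem, con, sep = sep, quote = FALSE,
                       col.names = FALSE, row.names = TRUE)
  }
  invisible(path)
}

#' Read per-cell labels
#'
#' Labels (cell types, time stages, cluster assignments) are stored as a
#' two-column TSV `cell_id<TAB>label` with no header, and represented in R as
#' a character vector named by cell id.
#'
#' @param path label file path.
#' @return named character vector of labels.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = FALSE, sep = "\t", quote = "",
                          comment.char = "", stringsAsFactors = FALSE,
                          col.names = c("cell_id", "label"))
  if (anyDuplicated(df$cell_id)) stop("duplicate cell ids in label file")
  stats::setNames(as.character(df$label), df$cell_id)
}

#' @rdname read_labels
#' @param labels named vector of labels (names are cell ids).
#' @export
write_labels <- function(labels, path) {
  if (is.null(names(labels))) stop("labels must be named by cell id")
  utils::write.table(data.frame(names(labels), as.character(labels)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Align a named label vector with a matrix's cells; errors on mismatch.
align_labels <- function(labels, cell_ids) {
  if (is.null(names(labels))) {
    if (length(labels) != length(cell_ids))
      stop("unnamed labels must have one entry per cell")
    return(stats::setNames(as.character(labels), cell_ids))
  }
  if (!setequal(names(labels), cell_ids))
    stop("label cell ids do not match the matrix cell ids")
  stats::setNames(as.character(labels[cell_ids]), cell_ids)
}
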