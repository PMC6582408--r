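#' Validate a gene expression matrix
#'
#' A gene expression matrix (GEM) in this package is a plain numeric matrix
#' with genes as rows and cells as columns, gene identifiers as row names and
#' cell identifiers as column names. All values must be finite and
#' non-negative; identifiers must be present and unique. The representation is
#' deliberately the base-R matrix so that the network degree matrix derived
#' from it is a drop-in replacement for the GEM in any downstream method.
#'
#' @param gem numeric matrix, genes x cells, with dimnames.
#' @return `gem`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_gem <- function(gem) {
  if (!is.matrix(gem) || !is.numeric(gem))
    stop("expression matrix must be a numeric matrix (genes x cells)")
  if (is.null(rownames(gem)) || is.null(colnames(gem)))
    stop("expression matrix must carry gene ids (rownames) and cell ids (colnames)")
  if (anyDuplicated(rownames(gem)))
    stop("duplicate gene ids in expression matrix")
  if (anyDuplicated(colnames(gem)))
    stop("duplicate cell ids in expression matrix")
  if (any(!is.finite(gem)))
    stop("expression matrix contains non-finite values")
  if (any(gem < 0))
    stop("expression matrix contains negative values")
  invisible(gem)
}

#' Construct a validated expression matrix
#'
#' @param values numeric matrix of non-negative expression values.
#' @param gene_ids,cell_ids optional identifier vectors; defaults to existing
#'   dimnames, or `gene1..geneM` / `cell1..cellN`.
#' @return validated genes x cells numeric matrix.
#' @export
as_gem <- function(values, gene_ids = NULL, cell_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.null(gene_ids)) rownames(values) <- gene_ids
  if (!is.null(cell_ids)) colnames(values) <- cell_ids
  if (is.null(rownames(values))) rownames(values) <- paste0("gene", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- paste0("cell", seq_len(ncol(values)))
  validate_gem(values)
  values
}

#' Drop rarely expressed genes
#'
#' Removes genes expressed (nonzero) in fewer than `min_cells` cells. The
#' default of 10 keeps genes expressed in at least 10 cells, the standard
#' preprocessing for this method; a gene expressed in exactly `min_cells`
#' cells is retained.
#'
#' @param gem validated expression matrix.
#' @param min_cells minimum number of cells with nonzero expression.
#' @return expression matrix restricted to the retained genes.
#' @export
filter_genes <- function(gem, min_cells = 10) {
  validate_gem(gem)
  if (length(min_cells) != 1 || is.na(min_cells) || min_cells < 1)
    stop("min_cells must be a positive integer")
  keep <- rowSums(gem > 0) >= min_cells
  if (!any(keep))
    stop("no genes expressed in >= ", min_cells,
         " cells; lower min_cells or check the input")
  gem[keep, , drop = FALSE]
}

#' Log-transform an expression matrix
#'
#' Applies the natural-log `log(1 + x)` transform entrywise, the usual
#' variance-stabilizing step for expression values. Zeros map to zeros and
#' within-gene rank order is preserved, so the neighborhood statistic is
#' unaffected in the absence of ties; the transform matters only for methods
#' run directly on the GEM.
#'
#' @param gem validated expression matrix.
#' @return transformed expression matrix.
#' @export
log1p_transform <- function(gem) {
  validate_gem(gem)
  out <- log1p(gem)
  dimnames(out) <- dimnames(gem)
  out
}
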