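#' Network degree matrix from cell networks
#'
#' The network degree matrix (NDM) has the same genes x cells shape as the
#' expression matrix; entry (x, k) is the number of edges incident to gene x
#' in the network of cell k. It carries the network information of the cell
#' into a container any expression-based method can consume.
#'
#' @param networks list of `csn_network` objects, one per cell, sharing one
#'   gene set (as produced by [build_all_networks()] with `sink =
#'   "edge_lists"`).
#' @return genes x cells numeric matrix of raw degrees, with attribute
#'   `normalized = FALSE`.
#' @seealso [normalize_ndm()], [build_all_networks()] whose `degree_only`
#'   sink produces the same matrix without materializing the networks.
#' @export
degree_matrix <- function(networks) {
  if (!length(networks)) stop("no networks supplied")
  ids <- unname(vapply(networks, function(nw) nw$cell_id, character(1)))
  if (anyDuplicated(ids)) stop("duplicate cell_id in network stream")
  genes <- networks[[1]]$gene_ids
  m <- length(genes)
  for (nw in networks)
    if (!identical(nw$gene_ids, genes)) stop("networks disagree on the gene set")
  ndm <- vapply(networks, function(nw)
    tabulate(c(nw$edges), nbins = m), numeric(m))
  dimnames(ndm) <- list(genes, ids)
  structure(ndm, normalized = FALSE)
}

#' Equalize the total degree across cells
#'
#' Rescales each cell's degree column so every cell has the same total number
#' of network degrees; the common target is the mean raw column sum, so the
#' matrix keeps its overall scale and within-cell degree ratios are
#' untouched. Equalization makes cells from sparsely and densely connected
#' populations comparable and improves downstream robustness. All-zero
#' columns (cells with an empty network) are left at zero with a warning.
#'
#' @param ndm raw degree matrix from [degree_matrix()] or the `degree_only`
#'   sink.
#' @return degree matrix with equal column sums and attribute
#'   `normalized = TRUE`.
#' @export
normalize_ndm <- function(ndm) {
  if (isTRUE(attr(ndm, "normalized"))) return(ndm)
  cs <- colSums(ndm)
  if (all(cs == 0))
    stop("all cell networks are empty; consider a larger alpha or box_size")
  if (any(cs == 0))
    warning(sum(cs == 0), " cell(s) have empty networks; left at zero degree")
  target <- mean(cs)
  scale <- ifelse(cs > 0, target / cs, 0)
  out <- sweep(ndm, 2, scale, `*`)
  dimnames(out) <- dimnames(ndm)
  structure(out, normalized = TRUE)
}
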