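#' Construct the association network of a single cell
#'
#' Tests every unordered gene pair for local dependence at the focal cell and
#' returns the resulting undirected boolean network. In
#' `zero_mode = "drop_zero_edges"` (the default, appropriate when zeros may be
#' technical dropouts) any pair in which the focal cell expresses either gene
#' at exactly zero is set to no-edge without consulting the statistic; in
#' `"trust_zeros"` (zeros known to be biological) the statistic alone
#' decides. Construction is unsupervised: no cell labels are used. Gene pairs
#' whose tie-expanded box covers all cells (e.g. a constant gene) carry no
#' association evidence and contribute no edge; one warning is emitted for
#' such genes.
#'
#' @param gem validated expression matrix (preprocessed as desired).
#' @param k focal cell index or cell id.
#' @param box_size neighborhood size as a fraction of cells, default 0.1.
#' @param alpha one-sided significance level for the edge test, default 0.01.
#' @param zero_mode zero-handling policy, see Details.
#' @return a `csn_network`: list with `cell_id`, `gene_ids`, `edges` (two
#'   -column integer matrix of gene index pairs, i < j) and `rho_hat` (the
#'   statistic of each edge).
#' @export
build_cell_network <- function(gem, k, box_size = 0.1, alpha = 0.01,
                               zero_mode = c("drop_zero_edges", "trust_zeros")) {
  zero_mode <- match.arg(zero_mode)
  validate_gem(gem)
  m <- nrow(gem); n <- ncol(gem)
  if (n < 2) stop("at least 2 cells are required")
  if (is.character(k)) k <- match(k, colnames(gem))
  if (is.na(k) || k < 1 || k > n) stop("cell index out of range")

  boxes <- matrix(FALSE, n, m)
  for (g in seq_len(m)) boxes[neighborhood(gem[g, ], k, box_size), g] <- TRUE
  nx <- colSums(boxes)
  full <- nx >= n
  if (any(full))
    warning("box covers all cells for gene(s) ",
            paste(rownames(gem)[full], collapse = ", "),
            "; no edges assigned there")

  pairs <- which(upper.tri(diag(m)), arr.ind = TRUE)   # (row < col)
  nxy <- vapply(seq_len(nrow(pairs)), function(p)
    sum(boxes[, pairs[p, 1]] & boxes[, pairs[p, 2]]), numeric(1))
  rh <- rho_hat_vec(n, nx[pairs[, 1]], nx[pairs[, 2]], nxy)
  edge <- edge_decision(rh, alpha)
  if (zero_mode == "drop_zero_edges")
    edge <- edge & gem[pairs[, 1], k] > 0 & gem[pairs[, 2], k] > 0
  structure(list(cell_id = colnames(gem)[k], gene_ids = rownames(gem),
                 edges = unname(pairs[edge, , drop = FALSE]),
                 rho_hat = rh[edge]),
            class = "csn_network")
}

#' @export
print.csn_network <- function(x, ...) {
  cat("cell-specific network for cell '", x$cell_id, "': ",
      length(x$gene_ids), " genes, ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Construct the networks of all cells
#'
#' Iterates once over gene pairs, testing every (pair, cell) combination, and
#' emits results through one of three sinks: `degree_only` accumulates the
#' network degree matrix without storing any network (constant memory in the
#' number of pairs), `edge_lists` returns one [build_cell_network()]-style
#' object per cell, and `stat_tensor` returns the full pairs x cells matrix
#' of standardized statistics (refused above `max_stats` entries, since it
#' materializes everything). Results agree across sinks on the same input.
#'
#' @inheritParams build_cell_network
#' @param sink output mode, see Details.
#' @param pairs optional restriction: a two-column matrix of gene indices or
#'   gene ids; default all `m(m-1)/2` unordered pairs.
#' @param max_stats entry cap for the `stat_tensor` sink.
#' @return according to `sink`: a degree matrix (genes x cells, see
#'   [degree_matrix()]), a list of `csn_network`, or a `csn_stats` matrix
#'   (pairs x cells, rownames `geneA|geneB`) carrying the gene pair index as
#'   attribute `pairs`. The `stat_tensor` sink stores the raw statistic; the
#'   zero-handling policy is applied only when edges are derived from it.
#' @export
build_all_networks <- function(gem, box_size = 0.1, alpha = 0.01,
                               zero_mode = c("drop_zero_edges", "trust_zeros"),
                               sink = c("degree_only", "edge_lists", "stat_tensor"),
                               pairs = NULL, max_stats = 2e7) {
  zero_mode <- match.arg(zero_mode)
  sink <- match.arg(sink)
  validate_gem(gem)
  m <- nrow(gem); n <- ncol(gem)
  if (n < 2) stop("at least 2 cells are required")
  if (m < 2) stop("at least 2 genes are required")
  pairs <- resolve_pairs(pairs, gem)
  np <- nrow(pairs)
  if (sink == "stat_tensor" && np * n > max_stats)
    stop("stat_tensor would hold ", np, " pairs x ", n, " cells = ",
         format(np * n, big.mark = ","), " statistics (cap ",
         format(max_stats, big.mark = ","),
         "); use degree_only or restrict pairs")

  genes_used <- sort(unique(c(pairs)))
  mem <- vector("list", m)
  for (g in genes_used) mem[[g]] <- neighborhood_matrix(gem[g, ], box_size)
  nx <- matrix(0, n, m)
  for (g in genes_used) nx[, g] <- Matrix::colSums(mem[[g]])
  full <- genes_used[vapply(genes_used, function(g) any(nx[, g] >= n), logical(1))]
  if (length(full))
    warning("box covers all cells for gene(s) ",
            paste(rownames(gem)[full], collapse = ", "),
            "; no edges assigned there")

  ndm <- if (sink == "degree_only")
    matrix(0, m, n, dimnames = dimnames(gem))
  stat <- if (sink == "stat_tensor")
    matrix(NA_real_, np, n,
           dimnames = list(paste(rownames(gem)[pairs[, 1]],
                                 rownames(gem)[pairs[, 2]], sep = "|"),
                           colnames(gem)))
  if (sink == "edge_lists") {
    edge_cells <- vector("list", np)
    edge_stats <- vector("list", np)
  }
  zcut <- stats::qnorm(1 - alpha)
  for (p in seq_len(np)) {
    x <- pairs[p, 1]; y <- pairs[p, 2]
    nxy <- Matrix::colSums(mem[[x]] * mem[[y]])
    rh <- rho_hat_vec(n, nx[, x], nx[, y], nxy)
    if (sink == "stat_tensor") { stat[p, ] <- rh; next }
    e <- rh > zcut
    if (zero_mode == "drop_zero_edges") e <- e & gem[x, ] > 0 & gem[y, ] > 0
    if (sink == "degree_only") {
      ndm[x, ] <- ndm[x, ] + e
      ndm[y, ] <- ndm[y, ] + e
    } else {
      edge_cells[[p]] <- which(e)
      edge_stats[[p]] <- rh[e]
    }
  }
  if (sink == "degree_only")
    return(structure(ndm, normalized = FALSE))
  if (sink == "stat_tensor")
    return(structure(stat, pairs = pairs, box_size = box_size, alpha = alpha,
                     class = c("csn_stats", "matrix")))
  nets <- lapply(seq_len(n), function(k) {
    hit <- which(vapply(edge_cells, function(ec) any(ec == k), logical(1)))
    structure(list(cell_id = colnames(gem)[k], gene_ids = rownames(gem),
                   edges = unname(pairs[hit, , drop = FALSE]),
                   rho_hat = vapply(hit, function(p)
                     edge_stats[[p]][match(k, edge_cells[[p]])], numeric(1))),
              class = "csn_network")
  })
  names(nets) <- colnames(gem)
  nets
}

# Normalize a pair specification to a 2-column integer matrix with col1 < col2.
resolve_pairs <- function(pairs, gem) {
  m <- nrow(gem)
  if (is.null(pairs)) {
    pr <- which(upper.tri(diag(m)), arr.ind = TRUE)
    return(unname(cbind(pr[, 1], pr[, 2])))
  }
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2) stop("pairs must have two columns")
  if (is.character(pairs)) {
    idx <- matrix(match(pairs, rownames(gem)), ncol = 2)
    if (any(is.na(idx))) stop("unknown gene id in pairs")
    pairs <- idx
  }
  pairs <- cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
  if (any(pairs[, 1] == pairs[, 2])) stop("self-pairs are not tested")
  if (any(pairs < 1 | pairs > m)) stop("gene index out of range in pairs")
  unname(pairs)
}

#' Derive edges or degrees from a statistic tensor
#'
#' Applies the one-sided edge test (and, in `drop_zero_edges` mode, the
#' zero rule, which needs the originating expression matrix) to a
#' `stat_tensor` result, reproducing exactly what the other sinks emit.
#'
#' @param stats `csn_stats` matrix from [build_all_networks()].
#' @param gem the expression matrix the statistics were computed from
#'   (required for `drop_zero_edges`).
#' @inheritParams build_cell_network
#' @return logical pairs x cells edge matrix (`edges_from_stats`) or a
#'   genes x cells degree matrix (`degrees_from_stats`).
#' @export
edges_from_stats <- function(stats, gem = NULL, alpha = attr(stats, "alpha"),
                             zero_mode = c("drop_zero_edges", "trust_zeros")) {
  zero_mode <- match.arg(zero_mode)
  pairs <- attr(stats, "pairs")
  e <- unclass(stats) > stats::qnorm(1 - alpha)
  if (zero_mode == "drop_zero_edges") {
    if (is.null(gem)) stop("gem is required to apply the zero rule")
    e <- e & gem[pairs[, 1], , drop = FALSE] > 0 &
      gem[pairs[, 2], , drop = FALSE] > 0
  }
  e
}

#' @rdname edges_from_stats
#' @param gene_ids gene identifiers of the originating matrix (defaults to
#'   those of `gem`).
#' @export
degrees_from_stats <- function(stats, gem = NULL, alpha = attr(stats, "alpha"),
                               zero_mode = c("drop_zero_edges", "trust_zeros"),
                               gene_ids = rownames(gem)) {
  e <- edges_from_stats(stats, gem, alpha, zero_mode)
  pairs <- attr(stats, "pairs")
  if (is.null(gene_ids)) gene_ids <- as.character(seq_len(max(pairs)))
  ndm <- matrix(0, length(gene_ids), ncol(e),
                dimnames = list(gene_ids, colnames(stats)))
  for (p in seq_len(nrow(pairs))) {
    ndm[pairs[p, 1], ] <- ndm[pairs[p, 1], ] + e[p, ]
    ndm[pairs[p, 2], ] <- ndm[pairs[p, 2], ] + e[p, ]
  }
  structure(ndm, normalized = FALSE)
}

#' Write cell networks as a long-format edge-list TSV
#'
#' One row per (cell, edge): `cell_id`, `gene_a`, `gene_b`, `rho_hat`
#' (6 significant digits). A `.gz` path is compressed transparently.
#'
#' @param networks list of `csn_network` objects.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_edge_lists <- function(networks, path) {
  rows <- lapply(networks, function(nw) {
    if (nrow(nw$edges) == 0) return(NULL)
    data.frame(cell_id = nw$cell_id,
               gene_a = nw$gene_ids[nw$edges[, 1]],
               gene_b = nw$gene_ids[nw$edges[, 2]],
               rho_hat = signif(nw$rho_hat, 6))
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(cell_id = character(), gene_a = character(),
                      gene_b = character(), rho_hat = numeric())
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
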