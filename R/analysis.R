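# Two-sample Wilcoxon rank-sum with a defined answer for degenerate input:
# a fully constant pooled sample carries no evidence, p = 1.
rank_test <- function(a, b) {
  if (length(unique(c(a, b))) < 2)
    return(list(p = 1, effect = 0))
  p <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
  list(p = p, effect = stats::median(a) - stats::median(b))
}

#' Differential edges between cell groups
#'
#' For every gene pair and every group-versus-rest contrast, compares the
#' per-cell standardized association statistic between the group's cells and
#' all other cells with a two-sided Wilcoxon rank-sum test, then adjusts all
#' p-values jointly by Benjamini-Hochberg. A pair whose statistic is larger
#' in one cell type marks an association specific to that type (a "marker
#' edge"). Groups with fewer than 3 cells are skipped with a warning.
#'
#' @param stats pairs x cells statistic matrix from [build_all_networks()]
#'   (`sink = "stat_tensor"`).
#' @param labels cell group labels, named by cell id (or unnamed, one per
#'   column of `stats`).
#' @param pairs optional character vector of pair ids (`"geneA|geneB"`
#'   rownames of `stats`) restricting the tests.
#' @param min_cells_per_edge if positive, pairs with an above-threshold
#'   statistic in fewer than this many cells overall are excluded first.
#' @return data.frame (`unit_id`, `group_a`, `group_b`, `effect` =
#'   difference of group medians, `p_value`, `q_value`,
#'   `tested_on = "edge_statistic"`) sorted by `q_value`.
#' @export
differential_edges <- function(stats, labels, pairs = NULL,
                               min_cells_per_edge = 0) {
  labels <- align_labels(labels, colnames(stats))
  rows <- if (is.null(pairs)) rownames(stats) else {
    missing <- setdiff(pairs, rownames(stats))
    if (length(missing)) stop("pairs not in stats: ", paste(missing, collapse = ", "))
    pairs
  }
  mat <- unclass(stats)[rows, , drop = FALSE]
  if (min_cells_per_edge > 0) {
    zcut <- stats::qnorm(1 - attr(stats, "alpha"))
    mat <- mat[rowSums(mat > zcut) >= min_cells_per_edge, , drop = FALSE]
  }
  groups <- sort(unique(labels))
  if (length(groups) < 2) stop("at least 2 groups are required")
  sizes <- table(labels)
  small <- names(sizes)[sizes < 3]
  if (length(small)) {
    warning("skipping group(s) with < 3 cells: ", paste(small, collapse = ", "))
    groups <- setdiff(groups, small)
  }
  res <- do.call(rbind, lapply(groups, function(g) {
    sel <- labels == g
    out <- apply(mat, 1, function(v) rank_test(v[sel], v[!sel]))
    data.frame(unit_id = rownames(mat), group_a = g, group_b = "rest",
               effect = vapply(out, `[[`, numeric(1), "effect"),
               p_value = vapply(out, `[[`, numeric(1), "p"),
               tested_on = "edge_statistic", row.names = NULL)
  }))
  res$q_value <- stats::p.adjust(res$p_value, "BH")
  res[order(res$q_value, res$p_value, res$unit_id),
      c("unit_id", "group_a", "group_b", "effect", "p_value", "q_value",
        "tested_on")]
}

#' Hub genes by network degree
#'
#' Ranks genes by mean degree within each cell group (or globally without
#' labels) and returns the top of each ranking; these are the genes most
#' connected in the cells of that group, candidate key regulators. Ties are
#' broken alphabetically by gene id.
#'
#' @param ndm degree matrix (normalization recommended, see
#'   [normalize_ndm()]).
#' @param labels optional group labels named by cell id.
#' @param top_k list length per group, default 10.
#' @return named list of character vectors of gene ids, one per group (a
#'   single `"all"` entry without labels).
#' @export
hub_genes <- function(ndm, labels = NULL, top_k = 10) {
  if (top_k < 1 || top_k > nrow(ndm)) stop("top_k must be in 1..m")
  groups <- if (is.null(labels)) list(all = colnames(ndm)) else {
    labels <- align_labels(labels, colnames(ndm))
    split(colnames(ndm), labels)
  }
  lapply(groups, function(cells) {
    mu <- rowMeans(ndm[, cells, drop = FALSE])
    ord <- order(-mu, rownames(ndm))
    rownames(ndm)[ord][seq_len(top_k)]
  })
}

#' 'Dark' genes: differential in degree but not in expression
#'
#' For every gene and every group-versus-rest contrast, runs two Wilcoxon
#' rank-sum tests: one on the expression values, one on the network degrees,
#' each family adjusted by Benjamini-Hochberg across all genes and
#' contrasts. A gene is dark for a contrast when the degree difference is
#' significant (`q < alpha_deg`) while the expression difference is not
#' (`q >= alpha_expr`): the gene changes its network role without changing
#' its expression level, invisible to differential-expression analysis.
#'
#' @param gem expression matrix.
#' @param ndm degree matrix aligned with `gem` (same gene and cell ids).
#' @param labels group labels named by cell id; at least two groups.
#' @param alpha_expr,alpha_deg significance levels, default 0.05 each.
#' @return data.frame with one row per (gene, contrast): effect sizes,
#'   p- and q-values of both tests, and logical `dark`.
#' @export
dark_genes <- function(gem, ndm, labels, alpha_expr = 0.05, alpha_deg = 0.05) {
  if (!identical(dimnames(gem), dimnames(ndm)))
    stop("gem and ndm must share gene and cell ids in the same order")
  labels <- align_labels(labels, colnames(gem))
  groups <- sort(unique(labels))
  if (length(groups) < 2) {
    warning("fewer than 2 groups; no contrasts to test")
    return(data.frame(gene = character(), group = character(),
                      effect_expr = numeric(), p_expr = numeric(),
                      q_expr = numeric(), effect_deg = numeric(),
                      p_deg = numeric(), q_deg = numeric(), dark = logical()))
  }
  res <- do.call(rbind, lapply(groups, function(g) {
    sel <- labels == g
    te <- apply(gem, 1, function(v) rank_test(v[sel], v[!sel]))
    td <- apply(ndm, 1, function(v) rank_test(v[sel], v[!sel]))
    data.frame(gene = rownames(gem), group = g,
               effect_expr = vapply(te, `[[`, numeric(1), "effect"),
               p_expr = vapply(te, `[[`, numeric(1), "p"),
               effect_deg = vapply(td, `[[`, numeric(1), "effect"),
               p_deg = vapply(td, `[[`, numeric(1), "p"), row.names = NULL)
  }))
  res$q_expr <- stats::p.adjust(res$p_expr, "BH")
  res$q_deg <- stats::p.adjust(res$p_deg, "BH")
  res$dark <- res$q_deg < alpha_deg & res$q_expr >= alpha_expr
  res[order(res$q_deg, res$gene),
      c("gene", "group", "effect_expr", "p_expr", "q_expr",
        "effect_deg", "p_deg", "q_deg", "dark")]
}

#' Network rewiring along ordered stages
#'
#' Summarizes how a gene panel's association structure moves along a time
#' course or other ordinal staging: per stage, the mean within-panel degree
#' of each gene and the mean standardized statistic of each pair, plus each
#' gene's peak stage. Degrees here are counted within the panel from the
#' statistic alone (no zero rule), so the summary depends only on `stats`.
#'
#' @param stats pairs x cells statistic matrix for the panel
#'   ([build_all_networks()] with `pairs`).
#' @param stage_labels ordinal stage per cell, named by cell id. Factor
#'   levels (or sorted unique values) define the stage order.
#' @param alpha edge threshold used for the degree summaries.
#' @return list with `gene_stage` (gene x stage mean degree, long format),
#'   `pair_stage` (pair x stage mean statistic, long format) and `peaks`
#'   (data.frame gene, peak stage).
#' @export
rewiring_summary <- function(stats, stage_labels, alpha = attr(stats, "alpha")) {
  stage_labels <- if (is.factor(stage_labels))
    stats::setNames(as.character(stage_labels), names(stage_labels))
  else stage_labels
  stage_labels <- align_labels(stage_labels, colnames(stats))
  stages <- sort(unique(stage_labels))
  stages <- stages[vapply(stages, function(s) sum(stage_labels == s) > 0, logical(1))]
  pairs <- attr(stats, "pairs")
  genes <- sort(unique(c(rn <- do.call(rbind, strsplit(rownames(stats), "|", fixed = TRUE)))))
  e <- unclass(stats) > stats::qnorm(1 - alpha)
  deg <- matrix(0, length(genes), ncol(stats), dimnames = list(genes, colnames(stats)))
  for (p in seq_len(nrow(e))) {
    deg[rn[p, 1], ] <- deg[rn[p, 1], ] + e[p, ]
    deg[rn[p, 2], ] <- deg[rn[p, 2], ] + e[p, ]
  }
  gene_stage <- do.call(rbind, lapply(stages, function(s)
    data.frame(gene = genes, stage = s,
               mean_degree = rowMeans(deg[, stage_labels == s, drop = FALSE]),
               row.names = NULL)))
  pair_stage <- do.call(rbind, lapply(stages, function(s)
    data.frame(pair = rownames(stats), stage = s,
               mean_rho_hat = rowMeans(unclass(stats)[, stage_labels == s,
                                                      drop = FALSE]),
               row.names = NULL)))
  peaks <- data.frame(gene = genes, peak_stage = vapply(genes, function(g) {
    v <- gene_stage$mean_degree[gene_stage$gene == g]
    stages[which.max(v)]
  }, character(1)), row.names = NULL)
  list(gene_stage = gene_stage, pair_stage = pair_stage, peaks = peaks)
}
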