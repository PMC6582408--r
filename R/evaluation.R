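#' Clustering agreement scores
#'
#' Compares a predicted partition of cells against a reference partition
#' with four standard indexes. ARI is the chance-corrected pair-counting
#' Rand index (1 iff the partitions are identical up to relabeling). F1 is
#' the pairwise variant: precision and recall of co-clustered cell pairs.
#' Purity is the weighted fraction of each predicted cluster taken up by its
#' majority reference class. Entropy is the mean reference-label entropy
#' within predicted clusters (base 2, weighted by cluster size; 0 for pure
#' clusters).
#'
#' @param predicted,truth label vectors, named by cell id (or unnamed and
#'   positionally aligned); must cover the same cells.
#' @return list with elements `ari`, `f1`, `purity`, `entropy`.
#' @export
clustering_scores <- function(predicted, truth) {
  if (!is.null(names(predicted)) && !is.null(names(truth))) {
    if (!setequal(names(predicted), names(truth)))
      stop("predicted and truth cover different cell sets")
    truth <- truth[names(predicted)]
  } else if (length(predicted) != length(truth)) {
    stop("predicted and truth must have the same length")
  }
  n <- length(predicted)
  if (n < 2) stop("at least 2 cells are required")
  tab <- table(predicted, truth)
  # pair counts
  tp <- sum(choose(tab, 2))
  pred_pairs <- sum(choose(rowSums(tab), 2))
  true_pairs <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  expected <- pred_pairs * true_pairs / total
  max_idx <- (pred_pairs + true_pairs) / 2
  ari <- if (max_idx == expected) 1 else (tp - expected) / (max_idx - expected)
  precision <- if (pred_pairs > 0) tp / pred_pairs else 1
  recall <- if (true_pairs > 0) tp / true_pairs else 1
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  purity <- sum(apply(tab, 1, max)) / n
  hrow <- apply(tab, 1, function(r) {
    p <- r[r > 0] / sum(r)
    -sum(p * log2(p))
  })
  entropy <- sum(rowSums(tab) / n * hrow)
  list(ari = ari, f1 = f1, purity = purity, entropy = entropy)
}

#' Pseudo-trajectory ordering accuracy
#'
#' Scores an inferred cell ordering (e.g. pseudotime values) against known
#' ordinal stages: over all ordered cell pairs (i, j) with stage(i) strictly
#' later than stage(j), a pair counts as T when the ordering value of i is
#' strictly larger than that of j, and as F otherwise (ties count as F).
#' Accuracy is T / (T + F); it is invariant under strictly monotone
#' transforms of the values and 0.5 in expectation for a random ordering.
#'
#' @param order_values numeric score per cell (larger = later), named by
#'   cell id or positionally aligned with `stages`.
#' @param stages ordinal stage per cell: numeric, ordered factor, or
#'   character (sorted order taken as stage order).
#' @return list with integer counts `T`, `F` and `accuracy`.
#' @export
trajectory_accuracy <- function(order_values, stages) {
  if (!is.null(names(order_values)) && !is.null(names(stages))) {
    if (!setequal(names(order_values), names(stages)))
      stop("order_values and stages cover different cell sets")
    stages <- stages[names(order_values)]
  } else if (length(order_values) != length(stages)) {
    stop("order_values and stages must have the same length")
  }
  st <- if (is.factor(stages)) as.integer(stages)
        else as.integer(factor(stages, levels = sort(unique(stages))))
  if (length(unique(st)) < 2)
    stop("at least 2 distinct stages are required (no comparable pairs)")
  levs <- sort(unique(st))
  t_cnt <- f_cnt <- 0
  for (a in seq_along(levs)[-1]) for (b in seq_len(a - 1)) {
    vi <- order_values[st == levs[a]]   # later stage
    vj <- order_values[st == levs[b]]   # earlier stage
    cmp <- outer(vi, vj, `>`)
    t_cnt <- t_cnt + sum(cmp)
    f_cnt <- f_cnt + sum(!cmp)
  }
  list(T = t_cnt, F = f_cnt, accuracy = t_cnt / (t_cnt + f_cnt))
}

#' Cluster cells of a GEM or NDM with a fixed protocol
#'
#' A small harness so the expression matrix and the degree matrix can be
#' clustered with identical method and parameters and then compared with
#' [clustering_scores()]. Cells (columns) are the observations.
#'
#' @param mat genes x cells matrix (GEM or NDM, any preprocessing applied
#'   beforehand).
#' @param k number of clusters.
#' @param method `"kmeans"` (`stats::kmeans`, `nstart` restarts),
#'   `"hclust"` (Ward.D2 on Euclidean distance) or `"kmedoids"`
#'   (`cluster::pam`).
#' @param nstart random restarts for k-means.
#' @param seed optional RNG seed applied just before the stochastic step.
#' @return named integer vector of cluster assignments (names = cell ids).
#' @export
cluster_cells <- function(mat, k, method = c("kmeans", "hclust", "kmedoids"),
                          nstart = 25, seed = NULL) {
  method <- match.arg(method)
  obs <- t(mat)
  if (!is.null(seed)) set.seed(seed)
  cl <- switch(method,
    kmeans = stats::kmeans(obs, centers = k, nstart = nstart)$cluster,
    hclust = stats::cutree(stats::hclust(stats::dist(obs), "ward.D2"), k),
    kmedoids = {
      if (!requireNamespace("cluster", quietly = TRUE))
        stop("the 'cluster' package is required for kmedoids")
      cluster::pam(obs, k, cluster.only = TRUE)
    })
  stats::setNames(as.integer(cl), colnames(mat))
}
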