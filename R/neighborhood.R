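#' Neighborhood of a cell in one gene's expression profile
#'
#' The neighborhood ("box") of cell `k` for one gene is a contiguous window
#' in the sorted order of that gene's values, of target size
#' `h = round(box_size * n)`, centered on the rank of cell `k` and shifted
#' inward at the extremes of the distribution so that the target size is
#' preserved. The window is then expanded to include every cell whose value
#' ties with a window boundary value, so the box is well defined and
#' invariant to the input permutation even with heavily tied data (for
#' example the zero spike of single-cell counts). The focal cell's rank is
#' taken as the middle of its tie run, so placement depends on the data only
#' through the values; with an even target size the window takes
#' `ceiling((h-1)/2)` ranks below that rank and `floor((h-1)/2)` above it.
#'
#' The occupancy actually used by the association statistic is the
#' post-expansion count, not the target.
#'
#' @param values numeric vector, one gene's expression across the n cells.
#' @param k focal cell index in `1..n`.
#' @param box_size fraction of cells targeted by the box, in (0, 1].
#' @return integer vector of member cell indices (unordered set, contains `k`).
#' @examples
#' neighborhood(c(5, 5, 5, 5), 1, 0.5)   # all tied: full inclusion
#' length(neighborhood(seq_len(100), 50, 0.1))
#' @export
neighborhood <- function(values, k, box_size = 0.1) {
  n <- length(values)
  if (n < 2) stop("at least 2 cells are required (statistic undefined for n < 2)")
  if (box_size <= 0 || box_size > 1) stop("box_size must be in (0, 1]")
  if (k < 1 || k > n) stop("cell index out of range")
  w <- neighborhood_windows(values, box_size)
  which(values >= w$sv[w$a[k]] & values <= w$sv[w$b[k]])
}

# Rank-window bookkeeping for one gene, all cells at once.
# Returns sorted values sv and, per focal cell k, the sorted-order index range
# [a[k], b[k]] of its tie-expanded window. Runs O(n log n).
neighborhood_windows <- function(values, box_size) {
  n <- length(values)
  h <- max(1L, min(n, as.integer(round(box_size * n))))
  ord <- order(values, seq_along(values))   # stable: ties keep input order
  sv <- values[ord]
  run <- cumsum(c(TRUE, sv[-1] != sv[-n]))               # tie-run labels
  first <- match(run, run)                               # run start indexes
  last <- rev(n + 1L - match(rev(run), rev(run)))        # run end indexes
  stable <- integer(n)
  stable[ord] <- seq_len(n)
  # focal rank = middle of the cell's tie run, so the window depends on the
  # data only through the values (permutation-invariant placement)
  pos <- first[stable] + (last[stable] - first[stable]) %/% 2L
  lo <- pos - as.integer(ceiling((h - 1) / 2))
  hi <- pos + as.integer(floor((h - 1) / 2))
  s <- pmax(0L, 1L - lo); lo <- lo + s; hi <- hi + s     # shift up at low end
  s <- pmax(0L, hi - n); hi <- hi - s; lo <- pmax(1L, lo - s)  # down at high end
  list(sv = sv, ord = ord, a = first[lo], b = last[hi])
}

# Sparse n x n box-membership matrix for one gene: entry (j, k) = 1 when cell
# j lies in the neighborhood of focal cell k. Column sums are the box
# occupancies n_x^(k).
neighborhood_matrix <- function(values, box_size) {
  n <- length(values)
  if (n < 2) stop("at least 2 cells are required (statistic undefined for n < 2)")
  w <- neighborhood_windows(values, box_size)
  counts <- w$b - w$a + 1L
  i <- unlist(lapply(seq_len(n), function(k) w$ord[w$a[k]:w$b[k]]),
              use.names = FALSE)
  Matrix::sparseMatrix(i = i, j = rep.int(seq_len(n), counts), x = 1,
                       dims = c(n, n))
}
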