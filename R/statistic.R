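#' Neighborhood box-counting association statistic for one cell
#'
#' Given the occupancies of the three neighborhood boxes around a focal cell
#' (marginal boxes of genes x and y, and their intersection), the statistic
#' is the local difference between the joint frequency and the product of the
#' marginal frequencies:
#' \deqn{\rho = n_{xy}/n - (n_x/n)(n_y/n)}
#' Under independence of the two genes the statistic has mean 0 and standard
#' deviation
#' \deqn{\sigma = \sqrt{n_x n_y (n-n_x)(n-n_y) / (n^4 (n-1))}}
#' and the standardized form
#' \deqn{\hat\rho = \sqrt{n-1}\,(n\,n_{xy} - n_x n_y) /
#'   \sqrt{n_x n_y (n-n_x)(n-n_y)}}
#' is approximately standard normal, which gives the per-cell edge test.
#'
#' All arguments are vectorized; `rho` is always in `[-1, 1]` and the
#' statistic is symmetric in `n_x` and `n_y`.
#'
#' @param n total number of cells.
#' @param n_x,n_y marginal box occupancies, each strictly between 0 and `n`.
#' @param n_xy intersection box occupancy, `0 <= n_xy <= min(n_x, n_y)`.
#' @return data.frame with columns `rho`, `mu` (null mean, 0), `sigma` (null
#'   standard deviation) and `rho_hat` (standardized statistic).
#' @examples
#' pair_cell_statistic(500, 50, 50, 10)
#' @export
pair_cell_statistic <- function(n, n_x, n_y, n_xy) {
  if (any(n < 2)) stop("statistic undefined for n < 2")
  if (any(n_xy < 0) || any(n_xy > pmin(n_x, n_y)))
    stop("n_xy must lie in [0, min(n_x, n_y)]")
  if (any(n_x <= 0 | n_x >= n) || any(n_y <= 0 | n_y >= n))
    stop("degenerate box: n_x and n_y must be strictly between 0 and n ",
         "(sigma = 0 otherwise)")
  rho <- n_xy / n - (n_x / n) * (n_y / n)
  sigma <- sqrt(n_x * n_y * (n - n_x) * (n - n_y) / (n^4 * (n - 1)))
  data.frame(rho = rho, mu = 0, sigma = sigma, rho_hat = rho / sigma)
}

# Vectorized standardized statistic tolerating degenerate boxes, used by the
# network builders: a box covering all n cells (constant gene after tie
# expansion) carries no association evidence, so rho_hat := 0 there.
rho_hat_vec <- function(n, n_x, n_y, n_xy) {
  den <- n_x * n_y * (n - n_x) * (n - n_y)
  out <- numeric(length(n_xy))
  ok <- den > 0
  out[ok] <- sqrt(n - 1) * (n * n_xy[ok] - n_x[ok] * n_y[ok]) / sqrt(den[ok])
  out
}

#' Per-cell edge decision
#'
#' One-sided test of gene independence in a single cell: an edge is declared
#' when the standardized statistic exceeds the upper-`alpha` quantile of the
#' standard normal (positive local dependence only). The default
#' `alpha = 0.01` corresponds to the threshold 2.3263.
#'
#' @param rho_hat standardized statistic (vectorized).
#' @param alpha one-sided significance level in (0, 1).
#' @return logical vector: `TRUE` where an edge is declared.
#' @export
edge_decision <- function(rho_hat, alpha = 0.01) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  rho_hat > stats::qnorm(1 - alpha)
}
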