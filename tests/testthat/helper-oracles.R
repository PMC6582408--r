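# Independent brute-force oracles used to pin down the optimized code paths.

# Naive neighborhood: find the focal cell's rank by scanning, place the
# contiguous target window, shift it inward at the ends, then scan all cells
# against the boundary values. No sorting tricks shared with the package
# implementation beyond the rule itself.
naive_neighborhood <- function(values, k, box_size) {
  n <- length(values)
  h <- max(1, min(n, round(box_size * n)))
  # focal rank = middle of the focal value's tie run, found by counting
  below <- sum(values < values[k])
  ties <- sum(values == values[k])
  rank_k <- below + 1 + (ties - 1) %/% 2
  lo <- rank_k - ceiling((h - 1) / 2)
  hi <- rank_k + floor((h - 1) / 2)
  if (lo < 1) { hi <- hi + (1 - lo); lo <- 1 }
  if (hi > n) { lo <- max(1, lo - (hi - n)); hi <- n }
  sv <- sort(values)
  which(values >= sv[lo] & values <= sv[hi])
}

# Pair-counting adjusted Rand index: classify every unordered cell pair as
# together/apart in each partition and apply the 2x2 mismatch closed form.
brute_ari <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) n11 <- n11 + 1
    else if (!sa && !sb) n00 <- n00 + 1
    else if (sa) n10 <- n10 + 1
    else n01 <- n01 + 1
  }
  den <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (den == 0) return(1)
  2 * (n11 * n00 - n10 * n01) / den
}

# Random small expression vector with ties and zeros injected.
random_tied_values <- function(n) {
  v <- round(stats::rexp(n), sample(0:1, 1))
  v[stats::runif(n) < 0.3] <- 0
  v
}

# Small random GEM for structural tests.
random_gem <- function(m, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vals <- matrix(stats::rlnorm(m * n), m, n)
  vals[stats::runif(m * n) < 0.2] <- 0
  as_gem(vals, paste0("g", seq_len(m)), paste0("c", seq_len(n)))
}

# Null-calibration simulation shared by the distributional acceptance checks:
# independent uniform pairs at n cells, statistics from the package's own
# stat-tensor sink. Returns a pairs x cells matrix of rho_hat.
simulate_null_stats <- function(n_pairs, n, seed) {
  out <- matrix(NA_real_, n_pairs, n)
  for (i in seq_len(n_pairs)) {
    pr <- generate_pair("independent", n = n, marginal = "uniform",
                        seed = seed + i)
    gem <- as_gem(pr$values)
    out[i, ] <- build_all_networks(gem, sink = "stat_tensor")[1, ]
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
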