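# Deterministic sorted reference sample from a zero-inflated log-normal:
# the (i - 0.5)/n quantile grid, with the lowest zero_prop fraction at 0.
# Mimics the right-skewed, spike-at-zero marginals of scRNA-seq counts.
zero_inflated_lognormal_quantiles <- function(n, zero_prop = 0.3,
                                              meanlog = 0, sdlog = 1) {
  q <- (seq_len(n) - 0.5) / n
  out <- numeric(n)
  pos <- q > zero_prop
  out[pos] <- stats::qlnorm((q[pos] - zero_prop) / (1 - zero_prop), meanlog, sdlog)
  out
}

#' Simulate one gene pair under a dependency scenario
#'
#' Generates a 2 x n expression pair together with per-cell ground-truth
#' dependency flags. `independent`: both genes i.i.d. from the marginal.
#' `partial_*`: a random subset of `floor(dependent_fraction * n)` cells
#' follows `y = g(x) + noise` while the rest stay independent.
#' `full_*`: every cell is dependent. The linear `g` is the identity; the
#' nonlinear `g` is a unimodal quadratic or circular-arc profile, both of
#' which defeat global correlation but are caught by the local statistic.
#' Values are clamped at zero so the pair is a valid expression input.
#'
#' @param kind scenario kind, see Details.
#' @param n number of cells (at least 50 for stable boxes at the default
#'   box size).
#' @param dependent_fraction fraction of dependent cells; forced to 0 for
#'   `independent` and 1 for `full_*`, default 0.5 for `partial_*`.
#' @param noise_sd noise standard deviation on the dependent cells, as a
#'   fraction of `sd(x)`.
#' @param marginal marginal family for the independent draws: `"uniform"`
#'   on (0, 1), `"normal"` (mean 5, sd 1, clamped), or `"lognormal"`.
#' @param nonlinear_g nonlinear profile, `"quadratic"` or `"arc"`.
#' @param seed optional RNG seed; identical spec + seed reproduce bit-identical
#'   output.
#' @return list with `values` (2 x n matrix, rows `x`, `y`), `dependent`
#'   (logical per cell) and `kind`.
#' @export
generate_pair <- function(kind = c("independent", "partial_linear",
                                   "partial_nonlinear", "full_linear",
                                   "full_nonlinear"),
                          n = 500, dependent_fraction = NULL, noise_sd = 0.1,
                          marginal = c("uniform", "normal", "lognormal"),
                          nonlinear_g = c("quadratic", "arc"), seed = NULL) {
  kind <- match.arg(kind)
  marginal <- match.arg(marginal)
  nonlinear_g <- match.arg(nonlinear_g)
  if (n < 2) stop("n must be at least 2")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (is.null(dependent_fraction))
    dependent_fraction <- switch(kind, independent = 0,
                                 full_linear = 1, full_nonlinear = 1, 0.5)
  if (dependent_fraction < 0 || dependent_fraction > 1)
    stop("dependent_fraction must be in [0, 1]")
  if (kind == "independent" && dependent_fraction != 0)
    stop("independent scenario requires dependent_fraction = 0")
  if (kind %in% c("full_linear", "full_nonlinear") && dependent_fraction != 1)
    stop("full_* scenarios require dependent_fraction = 1")
  if (!is.null(seed)) set.seed(seed)
  rmarg <- switch(marginal,
    uniform = function(k) stats::runif(k),
    normal = function(k) pmax(0, stats::rnorm(k, mean = 5)),
    lognormal = function(k) stats::rlnorm(k))
  x <- rmarg(n)
  y <- rmarg(n)
  nd <- floor(dependent_fraction * n)
  dep <- rep(FALSE, n)
  if (nd > 0) {
    dep[sample.int(n, nd)] <- TRUE
    xd <- x[dep]
    g <- if (kind %in% c("partial_linear", "full_linear")) xd
    else if (nonlinear_g == "quadratic") {
      c0 <- stats::median(x)
      s <- max((x - c0)^2)
      (xd - c0)^2 / ifelse(s > 0, s, 1) * max(x)
    } else {
      c0 <- stats::median(x)
      r <- max(abs(x - c0)) * 1.001
      sqrt(r^2 - (xd - c0)^2)
    }
    y[dep] <- pmax(0, g + stats::rnorm(nd, sd = noise_sd * stats::sd(x)))
  }
  values <- rbind(x = x, y = y)
  colnames(values) <- paste0("cell", seq_len(n))
  list(values = values, dependent = dep, kind = kind)
}

#' Simulate a multi-cell-type population with association structure
#'
#' Generates a genes x cells matrix of `n_types` cell types whose types
#' differ in gene-gene *association* structure: each type owns a module of
#' genes driven by a shared latent program (within-module correlation
#' `module_cor` on the latent scale), while all other genes are independent.
#' With `marginal_matched = TRUE` every gene's values within each type are
#' rank-remapped onto one common zero-inflated log-normal reference, so each
#' gene's marginal distribution is identical across types (exactly so for
#' equal type sizes) and only the dependence structure distinguishes the
#' types -- the construction behind 'dark' genes, which differ between
#' groups in network degree but not in expression. With `marginal_matched =
#' FALSE` the module genes of each type are additionally shifted up in their
#' own type (`expr_shift` on the log scale), making them conventionally
#' differentially expressed as well.
#'
#' @param n_types number of cell types.
#' @param cells_per_type cells per type; scalar or length-`n_types` vector.
#' @param m total number of genes.
#' @param module_size genes per type module when `modules` is not given.
#' @param modules optional list (length `n_types`) of gene index vectors.
#' @param module_cor within-module latent correlation in [0, 1); the default
#'   0.99 emulates a tightly co-regulated program.
#' @param marginal_matched match every gene's marginal across types, see
#'   Details.
#' @param zero_prop zero-inflation fraction of the reference marginal.
#' @param meanlog,sdlog log-normal parameters of the reference marginal.
#' @param expr_shift meanlog shift of own-type module genes when
#'   `marginal_matched = FALSE`.
#' @param dropout_rate independent technical zero-masking applied to the
#'   final matrix.
#' @param seed optional RNG seed; identical spec + seed reproduce
#'   bit-identical output.
#' @return list with `gem` (validated expression matrix), `labels` (type
#'   per cell, named), `modules` (list of gene-id vectors per type) and
#'   `params`.
#' @export
generate_population <- function(n_types = 3, cells_per_type = 100, m = 30,
                                module_size = 10, modules = NULL,
                                module_cor = 0.99, marginal_matched = TRUE,
                                zero_prop = 0.3, meanlog = 0, sdlog = 1,
                                expr_shift = 1, dropout_rate = 0, seed = NULL) {
  if (length(cells_per_type) == 1) cells_per_type <- rep(cells_per_type, n_types)
  if (length(cells_per_type) != n_types) stop("cells_per_type length mismatch")
  if (module_cor < 0 || module_cor >= 1) stop("module_cor must be in [0, 1)")
  if (dropout_rate < 0 || dropout_rate > 1) stop("dropout_rate must be in [0, 1]")
  if (is.null(modules)) {
    if (n_types * module_size > m)
      stop("n_types * module_size exceeds the number of genes")
    modules <- split(seq_len(n_types * module_size),
                     rep(seq_len(n_types), each = module_size))
  }
  if (length(modules) != n_types) stop("one module per type is required")
  if (any(unlist(modules) > m)) stop("module gene index exceeds m")
  if (!is.null(seed)) set.seed(seed)
  gene_ids <- sprintf("gene%02d", seq_len(m))
  n <- sum(cells_per_type)
  cell_ids <- sprintf("cell%04d", seq_len(n))
  type_ids <- paste0("type", seq_len(n_types))
  labels <- stats::setNames(rep(type_ids, cells_per_type), cell_ids)
  gem <- matrix(0, m, n, dimnames = list(gene_ids, cell_ids))
  for (t in seq_len(n_types)) {
    cols <- which(labels == type_ids[t])
    nt <- length(cols)
    ref <- zero_inflated_lognormal_quantiles(nt, zero_prop, meanlog, sdlog)
    ref_hi <- zero_inflated_lognormal_quantiles(nt, zero_prop,
                                                meanlog + expr_shift, sdlog)
    z <- stats::rnorm(nt)
    raw <- matrix(stats::rnorm(m * nt), m, nt)
    mg <- modules[[t]]
    raw[mg, ] <- sqrt(module_cor) * matrix(z, length(mg), nt, byrow = TRUE) +
      sqrt(1 - module_cor) * raw[mg, ]
    for (g in seq_len(m)) {
      tgt <- if (!marginal_matched && g %in% mg) ref_hi else ref
      gem[g, cols] <- tgt[rank(raw[g, ], ties.method = "first")]
    }
  }
  if (dropout_rate > 0)
    gem[stats::runif(length(gem)) < dropout_rate] <- 0
  validate_gem(gem)
  list(gem = gem, labels = labels,
       modules = lapply(modules, function(idx) gene_ids[idx]),
       params = list(n_types = n_types, cells_per_type = cells_per_type,
                     m = m, module_cor = module_cor,
                     marginal_matched = marginal_matched,
                     zero_prop = zero_prop, meanlog = meanlog, sdlog = sdlog,
                     expr_shift = expr_shift, dropout_rate = dropout_rate,
                     seed = seed))
}
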