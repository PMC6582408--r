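test_that("perfect dependence yields an edge; independence rarely does", {
  set.seed(21)
  x <- runif(500)
  gem <- as_gem(rbind(x, x), c("gx", "gy"), paste0("c", 1:500))
  nw <- build_cell_network(gem, 250)
  expect_equal(nrow(nw$edges), 1)  # the only pair is called
  # independent pair: edges across cells are rare (near the test level)
  pr <- generate_pair("independent", n = 500, marginal = "uniform", seed = 5)
  st <- build_all_networks(as_gem(pr$values), sink = "stat_tensor")
  expect_lt(mean(edge_decision(st[1, ])), 0.1)
})

test_that("zero expression suppresses incident edges in drop_zero_edges mode", {
  set.seed(8)
  x <- runif(100); x[7] <- 0
  gem <- as_gem(rbind(a = x, b = x + 1e-6, c = runif(100)))
  nw_drop <- build_cell_network(gem, 7, zero_mode = "drop_zero_edges")
  # gene 1 is zero in cell 7: nothing may touch it
  expect_false(any(nw_drop$edges == 1))
  nw_trust <- build_cell_network(gem, 7, zero_mode = "trust_zeros")
  expect_true(any(nw_trust$edges == 1))  # statistic alone decides
})

test_that("an all-zero matrix produces empty networks with a warning", {
  gem <- as_gem(matrix(0, 3, 4))
  nets <- suppressWarnings(build_all_networks(gem, sink = "edge_lists"))
  expect_length(nets, 4)
  for (nw in nets) expect_equal(nrow(nw$edges), 0)
  expect_warning(build_all_networks(gem, sink = "degree_only"),
                 "covers all cells")
})

test_that("all sink modes agree on the same input", {
  gem <- random_gem(6, 80, seed = 31)
  nd_direct <- build_all_networks(gem, sink = "degree_only")
  nets <- build_all_networks(gem, sink = "edge_lists")
  expect_equal(unclass(nd_direct), unclass(degree_matrix(nets)),
               ignore_attr = TRUE)
  st <- build_all_networks(gem, sink = "stat_tensor")
  expect_equal(unclass(nd_direct),
               unclass(degrees_from_stats(st, gem, zero_mode = "drop_zero_edges")),
               ignore_attr = TRUE)
  # and per-cell networks match the single-cell builder
  nw5 <- build_cell_network(gem, 5)
  expect_equal(nets[[5]]$edges, nw5$edges)
  expect_equal(nets[[5]]$rho_hat, nw5$rho_hat)
})

test_that("networks are undirected with no self-edges and a symmetric statistic", {
  gem <- random_gem(5, 60, seed = 13)
  nets <- build_all_networks(gem, sink = "edge_lists")
  for (nw in nets) {
    if (nrow(nw$edges) == 0) next
    expect_true(all(nw$edges[, 1] < nw$edges[, 2]))
    expect_false(any(duplicated(nw$edges)))
  }
  # statistic symmetric under gene swap
  st <- build_all_networks(gem, sink = "stat_tensor")
  gem_swapped <- gem[c(2, 1, 3:5), ]
  st2 <- build_all_networks(gem_swapped, sink = "stat_tensor")
  expect_equal(st["g1|g2", ], st2["g2|g1", ])
})

test_that("a looser alpha can only add edges", {
  gem <- random_gem(6, 100, seed = 17)
  nd_strict <- build_all_networks(gem, alpha = 0.01)
  nd_loose <- build_all_networks(gem, alpha = 0.5)
  expect_true(all(nd_loose >= nd_strict))
  expect_gt(sum(nd_loose), sum(nd_strict))
})

test_that("outlier cells far outside the joint support get no edge", {
  set.seed(9)
  x <- c(runif(199, 1, 2), 100)
  y <- c(x[1:199] + rnorm(199, sd = 0.01), 0.0001)
  gem <- as_gem(rbind(gx = x, gy = y))
  st <- build_all_networks(gem, sink = "stat_tensor")
  expect_false(edge_decision(st[1, 200]))       # the outlier
  expect_gt(mean(edge_decision(st[1, 1:199])), 0.8)  # the dependent bulk
})

test_that("the stat tensor refuses to materialize beyond its cap", {
  gem <- random_gem(10, 50, seed = 3)
  expect_error(build_all_networks(gem, sink = "stat_tensor", max_stats = 100),
               "cap")
  sub <- build_all_networks(gem, sink = "stat_tensor",
                            pairs = cbind(1, 2), max_stats = 100)
  expect_equal(dim(sub), c(1L, 50L))
})

test_that("restricting pairs reproduces the corresponding full-run rows", {
  gem <- random_gem(5, 60, seed = 23)
  st_all <- build_all_networks(gem, sink = "stat_tensor")
  st_sub <- build_all_networks(gem, sink = "stat_tensor",
                               pairs = rbind(c("g2", "g4"), c("g1", "g5")))
  expect_equal(st_sub["g2|g4", ], st_all["g2|g4", ])
  expect_equal(st_sub["g1|g5", ], st_all["g1|g5", ])
  expect_error(resolve_pairs <- build_all_networks(gem, pairs = cbind(2, 2)),
               "self-pairs")
})

test_that("edge lists serialize to the long TSV dialect", {
  gem <- random_gem(5, 60, seed = 41)
  nets <- build_all_networks(gem, sink = "edge_lists")
  p <- file.path(withr::local_tempdir(), "edges.tsv")
  write_edge_lists(nets, p)
  df <- read.delim(p)
  expect_named(df, c("cell_id", "gene_a", "gene_b", "rho_hat"))
  expect_equal(nrow(df), sum(vapply(nets, function(nw) nrow(nw$edges), 1L)))
})
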