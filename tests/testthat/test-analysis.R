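make_stats <- function(mat, pairs = NULL, alpha = 0.01) {
  structure(mat, pairs = pairs, alpha = alpha,
            class = c("csn_stats", "matrix"))
}

test_that("a group-specific association surfaces as the top marker edge", {
  set.seed(101)
  n_a <- 30; n_r <- 60
  labels <- setNames(rep(c("A", "B", "C"), each = 30),
                     paste0("c", 1:(n_a + n_r)))
  mat <- matrix(rnorm(8 * 90), 8, 90,
                dimnames = list(paste0("g", 1:8, "|g", 2:9),
                                names(labels)))
  mat[3, labels == "A"] <- rnorm(n_a, mean = 4)  # planted marker edge in A
  res <- differential_edges(make_stats(mat), labels)
  top <- res[1, ]
  expect_equal(top$unit_id, rownames(mat)[3])
  expect_equal(top$group_a, "A")
  expect_gt(top$effect, 2)
  expect_lt(top$q_value, 0.01)
  # q-values respect the BH contract
  expect_true(all(res$q_value >= res$p_value - 1e-12))
  expect_true(all(diff(res$q_value) >= -1e-12))
})

test_that("null and degenerate edge contrasts behave as specified", {
  set.seed(55)
  labels <- setNames(rep(c("A", "B"), each = 20), paste0("c", 1:40))
  mat <- matrix(rnorm(5 * 40), 5, 40,
                dimnames = list(paste0("p", 1:5), names(labels)))
  res <- differential_edges(make_stats(mat), labels)
  expect_gt(min(res$q_value), 0.05)  # no extreme discovery under the null
  # constant statistic in both groups: p = 1
  mat[2, ] <- 1.5
  res2 <- differential_edges(make_stats(mat), labels)
  expect_equal(res2$p_value[res2$unit_id == "p2"], c(1, 1))
  # too-small groups are skipped with a warning
  labels2 <- setNames(c(rep("A", 38), "B", "B"), names(labels))
  expect_warning(res3 <- differential_edges(make_stats(mat), labels2), "< 3")
  expect_error(differential_edges(make_stats(mat),
                                  setNames(rep("A", 40), names(labels))),
               "2 groups")
})

test_that("hub genes rank by mean degree with deterministic ties", {
  ndm <- structure(matrix(c(5, 3, 1), 3, 1,
                          dimnames = list(c("g1", "g2", "g3"), "c1")),
                   normalized = FALSE)
  expect_equal(hub_genes(ndm, top_k = 2)$all, c("g1", "g2"))
  expect_setequal(hub_genes(ndm, top_k = 3)$all, rownames(ndm))
  # two groups with disjoint high-degree modules give disjoint top lists
  nd2 <- matrix(0, 6, 40, dimnames = list(paste0("g", 1:6), paste0("c", 1:40)))
  labels <- setNames(rep(c("A", "B"), each = 20), colnames(nd2))
  nd2[1:3, labels == "A"] <- 5
  nd2[4:6, labels == "B"] <- 5
  hubs <- hub_genes(nd2, labels, top_k = 3)
  expect_setequal(hubs$A, c("g1", "g2", "g3"))
  expect_setequal(hubs$B, c("g4", "g5", "g6"))
  # alphabetical tie-break
  tied <- matrix(1, 3, 2, dimnames = list(c("b", "a", "c"), c("c1", "c2")))
  expect_equal(hub_genes(tied, top_k = 3)$all, c("a", "b", "c"))
  expect_error(hub_genes(ndm, top_k = 9), "top_k")
})

test_that("dark genes require degree change without expression change", {
  set.seed(77)
  n <- 80
  labels <- setNames(rep(c("A", "B"), each = 40), paste0("c", 1:n))
  ids <- c("dark", "both", "null")
  gem <- matrix(rlnorm(3 * n), 3, n, dimnames = list(ids, names(labels)))
  gem["both", labels == "A"] <- gem["both", labels == "A"] * 8
  ndm <- matrix(rpois(3 * n, 5), 3, n, dimnames = dimnames(gem))
  ndm["dark", labels == "A"] <- rpois(40, 30)
  ndm["both", labels == "A"] <- rpois(40, 30)
  res <- dark_genes(gem, structure(ndm, normalized = FALSE), labels)
  dark_a <- res[res$group == "A", ]
  expect_true(dark_a$dark[dark_a$gene == "dark"])
  expect_false(dark_a$dark[dark_a$gene == "both"])   # differential in both
  expect_false(dark_a$dark[dark_a$gene == "null"])
  expect_error(dark_genes(gem, structure(ndm[, rev(colnames(ndm))],
                                         normalized = FALSE), labels),
               "share")
  expect_warning(r0 <- dark_genes(gem, structure(ndm, normalized = FALSE),
                                  setNames(rep("A", n), colnames(gem))),
                 "2 groups")
  expect_equal(nrow(r0), 0)
})

test_that("rewiring summaries localize the active stage of a panel", {
  set.seed(31)
  n <- 90
  stages <- setNames(rep(c("00h", "12h", "24h"), each = 30), paste0("c", 1:n))
  mat <- matrix(rnorm(3 * n, mean = 0), 3, n,
                dimnames = list(c("gA|gB", "gA|gC", "gB|gC"), names(stages)))
  mat[, stages == "12h"] <- rnorm(3 * 30, mean = 5)  # dependence only mid-course
  rs <- rewiring_summary(make_stats(mat), stages)
  expect_true(all(rs$peaks$peak_stage == "12h"))
  ga <- rs$gene_stage[rs$gene_stage$gene == "gA", ]
  expect_equal(ga$stage[which.max(ga$mean_degree)], "12h")
  expect_equal(dim(rs$pair_stage), c(9L, 3L))
  # constant association: flat profile
  flat <- make_stats(matrix(5, 1, n, dimnames = list("gA|gB", names(stages))))
  rsf <- rewiring_summary(flat, stages)
  expect_equal(var(rsf$gene_stage$mean_degree), 0)
  # single stage: aggregates equal global means
  one <- rewiring_summary(make_stats(mat),
                          setNames(rep("s1", n), names(stages)))
  expect_equal(one$pair_stage$mean_rho_hat, unname(rowMeans(mat)))
})

test_that("analyses are invariant to cell permutation with permuted labels", {
  gem <- random_gem(6, 60, seed = 99)
  labels <- setNames(rep(c("A", "B"), each = 30), colnames(gem))
  ndm <- build_all_networks(gem)
  perm <- sample(60)
  res1 <- dark_genes(gem, ndm, labels)
  res2 <- dark_genes(gem[, perm], ndm[, perm], labels[perm])
  expect_equal(res1, res2)
})
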