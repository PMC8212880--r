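test_that("closest distance reproduces the path-graph worked examples", {
  g <- path5()
  expect_equal(closest_distance(g, "N1", "N5"), 4)          # plain BFS hops
  expect_equal(closest_distance(g, c("N1", "N2"), c("N4", "N5")), 2.5)
  # shared members contribute zero
  expect_equal(closest_distance(g, c("N1", "N2"), c("N2", "N5")), 0.5)
  expect_equal(closest_distance(g, c("N1"), c("N1", "N3")), 0)
  expect_error(closest_distance(g, c("Q1", "Q2"), "N1"),
               class = "graftnet_data_error")
})

test_that("closest distance vanishes exactly on contained sets", {
  g <- synth_interactome(60, 2, seed = 5)
  nodes <- igraph::V(g)$name
  withr::with_seed(23, {
    for (i in 1:20) {
      a <- sample(nodes, 6); b <- sample(nodes, 6)
      d <- closest_distance(g, a, b)
      # mean of per-node minima: zero forces every a-node into b
      if (d == 0) expect_true(all(a %in% b))
      if (length(setdiff(a, b)) == 0) expect_equal(d, 0)
      if (length(intersect(a, b)) == 0) expect_gt(d, 0)
    }
  })
})

test_that("closest distance is directional; the symmetrized form is symmetric", {
  # star + pendant chain: mean-min distances differ by direction
  g <- igraph::make_graph(~ H - A, H - B, H - C, C - D, D - E)
  a <- c("A", "B"); b <- c("E", "H")
  d_ab <- closest_distance(g, a, b)
  d_ba <- closest_distance(g, b, a)
  expect_false(isTRUE(all.equal(d_ab, d_ba)))
  rec_f <- proximity_significance(g, a, b, n_rand = 5, seed = 1,
                                  min_bin_size = 1)
  rec_r <- proximity_significance(g, b, a, n_rand = 5, seed = 1,
                                  min_bin_size = 1)
  expect_equal(rec_f$d_obs, mean(c(d_ab, d_ba)))
  expect_equal(rec_f$d_obs, rec_r$d_obs)
})

test_that("separation score reproduces its worked examples", {
  g <- path5()
  expect_equal(separation_score(g, c("N1", "N2"), c("N4", "N5")), 1.5)
  expect_equal(separation_score(g, c("N1", "N3"), c("N1", "N3")), 0)
  # two cliques joined by one edge separate positively
  cl <- igraph::make_graph(~ A - B, B - C, A - C, D - E, E - F, D - F, C - D)
  expect_gt(separation_score(cl, c("A", "B", "C"), c("D", "E", "F")), 0)
  expect_error(separation_score(g, "N1", c("N4", "N5")),
               class = "graftnet_parameter_error")
})

test_that("degree bins partition the nodes with the stated limits", {
  g <- synth_interactome(80, 2, seed = 3)
  bins <- build_degree_bins(g, min_bin_size = 10)
  expect_setequal(unlist(bins$bins), igraph::V(g)$name)
  expect_equal(sum(lengths(bins$bins)), igraph::vcount(g))
  expect_true(all(lengths(bins$bins) >= 10))
  # all nodes the same degree -> one bin
  ring <- igraph::make_ring(12)
  igraph::V(ring)$name <- paste0("R", 1:12)
  expect_length(build_degree_bins(ring, 3)$bins, 1)
  # min_bin_size 1: bins collapse to exact degree classes, so null
  # sampling within a unique degree class returns nodes of that degree only
  star <- igraph::make_graph(~ X - L1, X - L2, L2 - L3)
  b1 <- build_degree_bins(star, 1)
  degs <- igraph::degree(star)
  for (bin in b1$bins) expect_length(unique(degs[bin]), 1)
  expect_length(b1$bins, length(unique(degs)))
  expect_error(build_degree_bins(ring, 13),
               class = "graftnet_parameter_error")
})

test_that("the null sampler preserves the degree-bin multiset exactly", {
  g <- synth_interactome(100, 2, seed = 7)
  bins <- build_degree_bins(g, 5)
  nodes <- igraph::V(g)$name
  withr::with_seed(29, {
    for (i in 1:20) {
      ref <- sample(nodes, 12)
      drawn <- graftnet:::sample_degree_matched(bins, ref)
      expect_equal(sort(table(bins$bin_of[drawn])),
                   sort(table(bins$bin_of[ref])))
      expect_equal(anyDuplicated(drawn), 0L)
    }
  })
})

test_that("proximity significance is deterministic with bounded empirical p", {
  g <- synth_interactome(100, 2, seed = 2)
  nodes <- igraph::V(g)$name
  a <- nodes[1:8]; b <- nodes[51:58]
  rec <- proximity_significance(g, a, b, n_rand = 99, seed = 10)
  rec2 <- proximity_significance(g, a, b, n_rand = 99, seed = 10)
  expect_identical(rec, rec2)
  expect_gt(rec$p_emp, 0)
  expect_lte(rec$p_emp, 1)
  # pseudocount formula: d_obs of a subset pair (distance 0) beats every
  # null draw that is positive
  rec0 <- proximity_significance(g, a, a, n_rand = 100, seed = 4)
  expect_equal(rec0$d_obs, 0)
  expect_gte(rec0$p_emp, 1 / 101)
})

test_that("proximity matrix covers all unordered pairs with family-wise BH", {
  g <- synth_interactome(120, 2, seed = 8)
  nodes <- igraph::V(g)$name
  withr::with_seed(31, {
    modules <- lapply(1:5, function(i) sample(nodes, 8))
    names(modules) <- paste0("M", 1:5)
  })
  out <- proximity_matrix(g, modules, n_rand = 20, seed = 1)
  expect_equal(nrow(out), 10)  # C(5,2)
  ok <- !is.na(out$p_emp)
  expect_equal(out$q[ok], bh_adjust(out$p_emp[ok]))
  expect_equal(out$blank, out$p_emp > 0.05)
  # single pair: q equals p (BH base case)
  one <- proximity_matrix(g, modules[1:2], n_rand = 20, seed = 1)
  expect_equal(one$q, one$p_emp)
})
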