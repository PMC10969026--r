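path3 <- adjacency(matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3))
triangle <- adjacency(matrix(1, 3, 3) - diag(3))

test_that("thresholding applies the inclusive >= rule off the diagonal", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.10
  w[1, 3] <- w[3, 1] <- 0.22
  w[2, 3] <- w[3, 2] <- 0.30
  diag(w) <- 1 # diagonal must be ignored
  adj <- threshold_adjacency(w, 0.22)
  expect_equal(sum(adj$a) / 2, 2)
  expect_equal(adj$a[1, 3], 1)
  expect_equal(adj$a[2, 3], 1)
  expect_equal(adj$a[1, 2], 0)
  expect_equal(diag(adj$a), rep(0, 3), ignore_attr = TRUE)
  expect_equal(sum(threshold_adjacency(w, 0)$a) / 2, 3)
  expect_equal(sum(threshold_adjacency(w, 0.31)$a), 0)
})

test_that("the default threshold grid has 51 values", {
  g <- threshold_grid()
  expect_length(g, 51)
  expect_equal(g[1], 0)
  expect_equal(g[51], 0.5)
  expect_equal(threshold_grid(0, 0, 0.01), 0)
  expect_equal(threshold_grid(0, 0.1, 0.05), c(0, 0.05, 0.1))
  expect_error(threshold_grid(0.2, 0.1, 0.01), "bound")
  expect_error(threshold_grid(0, 0.5, 0), "step")
})

test_that("node strength sums off-diagonal weights", {
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.5
  w[1, 3] <- w[3, 1] <- 0.2
  w[2, 3] <- w[3, 2] <- 0.1
  expect_equal(unname(node_strength(w)), c(0.7, 0.6, 0.3))
  expect_equal(unname(node_strength(matrix(0, 3, 3))), rep(0, 3))
  u <- matrix(0.4, 5, 5)
  expect_equal(unname(node_strength(u)), rep(4 * 0.4, 5))
})

test_that("degrees, path length, clustering and efficiency on canonical graphs", {
  full <- make_canonical_graph("complete", 68)
  expect_equal(unname(degrees(full)$degree), rep(67, 68))
  expect_equal(degrees(full)$average, 67)
  expect_equal(characteristic_path_length(full)$L, 1)
  expect_equal(clustering_coefficients(full)$global, 1)
  expect_equal(global_efficiency(full), 1)
  expect_equal(count_connected_nodes(full), 68)

  expect_equal(unname(degrees(path3)$degree), c(1, 2, 1))
  expect_equal(degrees(path3)$average, 4 / 3)
  expect_equal(characteristic_path_length(path3)$L, 4 / 3)
  expect_equal(global_efficiency(path3), 5 / 6)

  expect_equal(clustering_coefficients(triangle)$global, 1)
  star <- make_canonical_graph("star", 4)
  expect_equal(clustering_coefficients(star)$global, 0)

  empty <- adjacency(matrix(0, 4, 4))
  expect_equal(count_connected_nodes(empty), 0)
  expect_equal(global_efficiency(empty), 0)
  expect_error(characteristic_path_length(empty), "edgeless")
})

test_that("disconnected graphs report unreachable pairs", {
  a <- matrix(0, 4, 4)
  a[1, 2] <- a[2, 1] <- 1
  a[3, 4] <- a[4, 3] <- 1
  adj <- adjacency(a)
  pl <- characteristic_path_length(adj)
  expect_equal(pl$L, 1)
  expect_equal(pl$unreachable_pairs, 8)
  expect_equal(global_efficiency(adj), 4 / 12)
  one_edge <- matrix(0, 5, 5); one_edge[1, 2] <- one_edge[2, 1] <- 1
  expect_equal(count_connected_nodes(adjacency(one_edge)), 2)
})

test_that("metrics match the brute-force oracle on random graphs", {
  set.seed(23)
  for (k in 1:40) {
    n <- sample(4:12, 1)
    a <- random_adjacency(n, p_edge = runif(1, 0.2, 0.8))
    if (sum(a) == 0) next
    adj <- adjacency(a)
    want <- oracle_metrics(a)
    expect_equal(degrees(adj)$average, want$D, tolerance = 1e-12)
    pl <- characteristic_path_length(adj)
    expect_equal(pl$L, want$L, tolerance = 1e-12)
    expect_equal(pl$unreachable_pairs, want$unreachable)
    expect_equal(clustering_coefficients(adj)$global, want$CC,
                 tolerance = 1e-12)
    expect_equal(global_efficiency(adj), want$E, tolerance = 1e-12)
  }
})

test_that("metrics are invariant under node relabeling", {
  set.seed(24)
  a <- random_adjacency(9, 0.4)
  perm <- sample(9)
  adj <- adjacency(a)
  padj <- adjacency(a[perm, perm])
  expect_equal(degrees(padj)$average, degrees(adj)$average)
  expect_equal(characteristic_path_length(padj)$L,
               characteristic_path_length(adj)$L)
  expect_equal(clustering_coefficients(padj)$global,
               clustering_coefficients(adj)$global)
  expect_equal(global_efficiency(padj), global_efficiency(adj))
  expect_equal(sort(unname(clustering_coefficients(padj)$per_node)),
               sort(unname(clustering_coefficients(adj)$per_node)))
})

test_that("edge count, degree, efficiency and node count fall with threshold", {
  set.seed(25)
  w <- matrix(runif(20 * 20, 0, 0.5), 20, 20)
  w <- (w + t(w)) / 2; diag(w) <- 0
  tab <- threshold_metrics(w)
  expect_equal(nrow(tab), 51)
  expect_true(all(diff(tab$n_edges) <= 0))
  expect_true(all(diff(tab$D) <= 0))
  expect_true(all(diff(tab$E) <= 0))
  expect_true(all(diff(tab$n_connected) <= 0))
})

test_that("random references reproduce known ensembles", {
  full <- make_canonical_graph("complete", 10)
  rnd <- random_reference(full, n_realizations = 5, seed = 1)
  expect_equal(rnd$cc_random, 1)
  expect_equal(rnd$l_random, 1)
  lattice <- make_canonical_graph("ring_lattice", 68, k = 6)
  rl <- random_reference(lattice, n_realizations = 10, seed = 2)
  cc_real <- clustering_coefficients(lattice)$global
  expect_gt(cc_real / rl$cc_random, 2)
  expect_error(random_reference(full, n_realizations = 0), "n_realizations")
  expect_error(random_reference(adjacency(matrix(0, 3, 3)), 5), "edge")
})

test_that("random references are seed-reproducible", {
  ws <- make_canonical_graph("watts_strogatz", 30, k = 4, p = 0.2, seed = 3)
  a <- random_reference(ws, n_realizations = 8, seed = 11)
  b <- random_reference(ws, n_realizations = 8, seed = 11)
  expect_identical(a, b)
})

test_that("small-world index is 1 on the complete graph and exceeds 1 on WS", {
  full <- make_canonical_graph("complete", 12)
  sw <- small_world_index(full, n_realizations = 3, seed = 1)
  expect_equal(sw$sigma, 1)
  expect_equal(sw$gamma, 1)
  expect_equal(sw$lambda, 1)
  ws <- make_canonical_graph("watts_strogatz", 68, k = 6, p = 0.1, seed = 4)
  sws <- small_world_index(ws, n_realizations = 10, seed = 5)
  expect_gt(sws$sigma, 1)
  expect_equal(sws$sigma, sws$gamma / sws$lambda, tolerance = 1e-12)
})

test_that("graph_metrics collects consistent fields", {
  gm <- graph_metrics(path3, weights = matrix(c(0, 2, 0, 2, 0, 1, 0, 1, 0),
                                              3, 3))
  expect_equal(gm$average_degree, 4 / 3)
  expect_equal(unname(gm$strength), c(2, 3, 1))
  expect_equal(gm$n_connected_nodes, 3)
  expect_equal(gm$efficiency, 5 / 6)
})
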