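test_that("binarization uses a strict signed threshold and kills the diagonal", {
  vals <- matrix(c(1, 0.31, 0.29, -0.9,
                   0.31, 1, 0.30, 0.5,
                   0.29, 0.30, 1, 0.6,
                   -0.9, 0.5, 0.6, 1), 4, 4)
  fc <- edge_matrix(vals, "pearson_r", roi_labels = letters[1:4])
  adj <- binarize(fc, 0.3)
  expect_equal(adj["a", "b"], 1L)   # 0.31 > 0.3
  expect_equal(adj["a", "c"], 0L)   # 0.29
  expect_equal(adj["b", "c"], 0L)   # exactly 0.30: strict
  expect_equal(adj["a", "d"], 0L)   # -0.9: no absolute value
  expect_equal(diag(unclass(adj)), rep(0L, 4), ignore_attr = TRUE)
})

test_that("edge sets are nested across increasing thresholds", {
  fc <- rand_fc(8, 30, seed = 18)
  a1 <- binarize(fc, 0.1); a2 <- binarize(fc, 0.3); a3 <- binarize(fc, 0.5)
  expect_true(all(a2 <= a1))
  expect_true(all(a3 <= a2))
})

test_that("degree, clustering and path length match closed forms", {
  k4 <- complete_adj(4)
  expect_equal(unname(node_degrees(k4)), rep(3L, 4))
  expect_equal(mean_degree(k4), 3)
  expect_equal(clustering_coefficients(k4)$mean, 1)
  expect_equal(characteristic_path_length(k4)$L, 1)

  star <- adj_from_edges(4, list(c(1, 2), c(1, 3), c(1, 4)))
  expect_equal(unname(node_degrees(star)), c(3L, 1L, 1L, 1L))
  expect_equal(mean_degree(star), 1.5)
  expect_equal(clustering_coefficients(star)$mean, 0)
  expect_equal(characteristic_path_length(star)$L, 1.5)

  p3 <- adj_from_edges(3, list(c(1, 2), c(2, 3)))
  expect_equal(characteristic_path_length(p3)$L, 4 / 3)

  tri_pendant <- adj_from_edges(4, list(c(1, 2), c(2, 3), c(1, 3), c(3, 4)))
  cc <- clustering_coefficients(tri_pendant)
  expect_equal(unname(cc$coefficients), c(1, 1, 1 / 3, 0))
  expect_equal(cc$mean, 7 / 12)

  ring <- adj_from_edges(6, lapply(1:6, function(i) c(i, i %% 6 + 1)))
  expect_equal(clustering_coefficients(ring)$mean, 0)

  expect_equal(mean_degree(matrix(0L, 3, 3)), 0)
  expect_error(characteristic_path_length(matrix(0L, 3, 3)), "no edges")
})

test_that("disconnected pairs are excluded from L and reported as a fraction", {
  two_comps <- adj_from_edges(4, list(c(1, 2), c(3, 4)))
  pl <- characteristic_path_length(two_comps)
  expect_equal(pl$L, 1)                       # only within-component pairs
  expect_equal(pl$frac_disconnected_pairs, 8 / 12)
  eff <- characteristic_path_length(two_comps, method = "efficiency")
  expect_equal(eff$L, 1 / (4 / 12))           # 4 ordered pairs at distance 1
})

test_that("all metrics agree with igraph on random graphs", {
  skip_if_not_installed("igraph")
  for (seed in 1:100) {
    adj <- er_adj(30, runif(1, 0.1, 0.5), seed = 300 + seed)
    if (sum(adj) == 0) next
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    expect_equal(unname(node_degrees(adj)), unname(igraph::degree(g)))
    ours_c <- clustering_coefficients(adj)$coefficients
    ref_c <- igraph::transitivity(g, type = "local", isolates = "zero")
    ref_c[is.nan(ref_c)] <- 0
    expect_equal(unname(ours_c), unname(ref_c), tolerance = 1e-10)
    expect_equal(characteristic_path_length(adj)$L,
                 igraph::mean_distance(g, directed = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("the threshold sweep covers the grid with monotone mean degree", {
  fc <- rand_fc(12, 40, seed = 19)
  sweep_tab <- threshold_sweep(fc, subject_id = "s")
  expect_equal(nrow(sweep_tab), 41L)
  expect_true(all(diff(sweep_tab$mean_degree) <= 0))
  # a threshold below the global minimum r gives the complete graph
  lo <- min(fc[upper.tri(fc)]) - 0.01
  rec <- graph_metrics(fc, lo)
  expect_equal(rec$char_path_length, 1)
  expect_equal(rec$mean_degree, 11)
})

test_that("the degree-tail diagnostic separates power laws from regular graphs", {
  skip_if_not_installed("igraph")
  # degree sequence with exactly power-law survival S(d) = 1/d at d = 1..16
  degs <- rep(c(1L, 2L, 4L, 8L, 16L), times = c(48L, 24L, 12L, 6L, 6L))
  set.seed(21)
  g <- igraph::sample_degseq(degs, method = "fast.heur.simple")
  sf <- as.matrix(igraph::as_adjacency_matrix(g))
  r2_sf <- degree_distribution_diagnostic(sf)
  expect_gt(r2_sf, 0.95)
  # dense ER graph: binomial (peaked) degrees, poor log-log linearity
  r2_dense <- degree_distribution_diagnostic(er_adj(60, 0.5, seed = 20))
  expect_gt(r2_sf, r2_dense)
  # regular graph: all degrees equal, diagnostic undefined
  ring <- adj_from_edges(12, lapply(1:12, function(i) c(i, i %% 12 + 1)))
  expect_true(is.na(degree_distribution_diagnostic(ring)))
})
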