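test_that("clustering matches closed forms and the triangle-counting oracle", {
  expect_equal(clustering_coefficients(complete_graph(5))$nodal, rep(1, 5))
  expect_equal(clustering_coefficients(star_graph(4))$nodal, rep(0, 5))
  set.seed(101)
  for (i in 1:20) {
    a <- rand_adj(7, runif(1, 0.2, 0.8))
    expect_equal(clustering_coefficients(a)$nodal, bf_clustering(a), tolerance = 1e-12)
  }
})

test_that("global efficiency matches pair enumeration and is monotone in edges", {
  expect_equal(global_efficiency(complete_graph(6)), 1)
  expect_equal(global_efficiency(path_graph(3)), (1 + 1 + 0.5) / 3, tolerance = 1e-12)
  expect_equal(global_efficiency(matrix(0L, 4, 4)), 0)
  set.seed(103)
  a <- rand_adj(8, 0.2)
  e0 <- global_efficiency(a)
  missing <- which(a == 0 & upper.tri(a), arr.ind = TRUE)
  for (r in seq_len(min(5, nrow(missing)))) {
    a2 <- a
    a2[missing[r, 1], missing[r, 2]] <- a2[missing[r, 2], missing[r, 1]] <- 1L
    expect_gte(global_efficiency(a2), e0)
  }
})

test_that("characteristic path length uses the largest component", {
  expect_equal(characteristic_path_length(complete_graph(5)), 1)
  expect_equal(characteristic_path_length(path_graph(3)), 4 / 3, tolerance = 1e-12)
  expect_equal(characteristic_path_length(ring_graph(5)), 1.5, tolerance = 1e-12)
  # triangle plus isolated edge: L computed within the triangle
  a <- matrix(0L, 5, 5)
  a[1, 2] <- a[2, 3] <- a[1, 3] <- a[4, 5] <- 1L
  a <- pmax(a, t(a))
  expect_equal(characteristic_path_length(a), 1)
  expect_error(characteristic_path_length(matrix(0L, 3, 3)), "fewer than 2")
})

test_that("modularity optimizer recovers exact optima on small structured graphs", {
  two_tri <- matrix(0L, 6, 6)
  for (e in list(c(1,2), c(2,3), c(1,3), c(4,5), c(5,6), c(4,6)))
    two_tri[e[1], e[2]] <- two_tri[e[2], e[1]] <- 1L
  mp <- modularity_partition(two_tri, seed = 1)
  expect_equal(mp$Q, 0.5, tolerance = 1e-12)
  expect_equal(length(unique(mp$partition)), 2)
  expect_true(all(mp$partition[1:3] == mp$partition[1]))
  # complete graph has no community structure: optimal Q = 0
  expect_equal(modularity_partition(complete_graph(6), seed = 1)$Q, 0,
               tolerance = 1e-12)
  expect_error(modularity_partition(matrix(0L, 4, 4)), "edgeless")
  # deterministic given seed
  set.seed(107)
  a <- rand_adj(12, 0.3)
  expect_identical(modularity_partition(a, seed = 5), modularity_partition(a, seed = 5))
})

test_that("degree-preserving null preserves the degree sequence", {
  set.seed(109)
  for (i in 1:10) {
    a <- rand_adj(10, 0.4)
    if (sum(a) / 2 < 2) next
    gn <- degree_preserving_null(a, seed = i)
    expect_equal(sort(igraph::degree(gn)), sort(rowSums(a)))
  }
  # complete graph admits no swap and is returned unchanged with a warning
  expect_warning(gn <- degree_preserving_null(complete_graph(5), seed = 1),
                 "unchanged")
  expect_equal(sort(igraph::degree(gn)), rep(4, 5))
})

test_that("small-worldness separates lattice-like from random topology", {
  # ring lattice (2 neighbors per side) with a couple of shortcuts
  n <- 20
  a <- matrix(0L, n, n)
  for (i in seq_len(n)) for (s in 1:2) {
    j <- ((i + s - 1) %% n) + 1
    a[i, j] <- a[j, i] <- 1L
  }
  a[1, 10] <- a[10, 1] <- 1L
  a[5, 15] <- a[15, 5] <- 1L
  sig <- small_worldness(a, null_model_config(n_nulls = 50, seed = 2))
  expect_gt(sig, 1)
  # a random graph is (statistically) its own null
  set.seed(113)
  g <- igraph::sample_gnm(30, 120)
  sig0 <- small_worldness(g, null_model_config(n_nulls = 50, seed = 3))
  expect_gt(sig0, 0.8)
  expect_lt(sig0, 1.25)
  # isomorphism invariance
  perm <- sample(n)
  expect_equal(small_worldness(a[perm, perm], null_model_config(50, seed = 2)),
               sig, tolerance = 0.15)
})

test_that("centralities match closed forms on canonical graphs", {
  # path: middle node carries the single geodesic
  expect_equal(betweenness_centrality(path_graph(3)), c(0, 1, 0))
  expect_equal(betweenness_centrality(complete_graph(5)), rep(0, 5))
  # star: center/leaf eigenvector ratio is sqrt(3) for 3 leaves
  ev <- eigenvector_centrality(star_graph(3))
  expect_equal(ev[1] / ev[2], sqrt(3), tolerance = 1e-9)
  expect_equal(sum(ev^2), 1, tolerance = 1e-12)
  # regular connected graph: uniform eigenvector
  expect_equal(eigenvector_centrality(ring_graph(6)), rep(1 / sqrt(6), 6),
               tolerance = 1e-9)
  expect_equal(closeness_centrality(complete_graph(4)), rep(1, 4))
  expect_equal(closeness_centrality(path_graph(3)), c(2 / 3, 1, 2 / 3),
               tolerance = 1e-12)
  # two disjoint edges: within-component convention gives all ones
  a <- matrix(0L, 4, 4)
  a[1, 2] <- a[2, 1] <- a[3, 4] <- a[4, 3] <- 1L
  expect_equal(closeness_centrality(a), rep(1, 4))
  expect_equal(largest_component_fraction(a), 0.5)
  tri_iso <- matrix(0L, 6, 6)
  tri_iso[1, 2] <- tri_iso[2, 3] <- tri_iso[1, 3] <- 1L
  tri_iso <- pmax(tri_iso, t(tri_iso))
  expect_equal(largest_component_fraction(tri_iso), 0.5)
})

test_that("every metric is invariant under node relabeling", {
  set.seed(127)
  a <- rand_adj(9, 0.4)
  perm <- sample(9)
  ap <- a[perm, perm]
  expect_equal(sort(clustering_coefficients(ap)$nodal),
               sort(clustering_coefficients(a)$nodal), tolerance = 1e-12)
  expect_equal(global_efficiency(ap), global_efficiency(a), tolerance = 1e-12)
  expect_equal(characteristic_path_length(ap), characteristic_path_length(a),
               tolerance = 1e-12)
  expect_equal(sort(betweenness_centrality(ap)), sort(betweenness_centrality(a)),
               tolerance = 1e-9)
  expect_equal(sort(eigenvector_centrality(ap)), sort(eigenvector_centrality(a)),
               tolerance = 1e-9)
  expect_equal(sort(closeness_centrality(ap)), sort(closeness_centrality(a)),
               tolerance = 1e-12)
  expect_equal(largest_component_fraction(ap), largest_component_fraction(a))
})

test_that("metrics and centrality tables assemble per subject and density", {
  set.seed(131)
  z <- matrix(rnorm(2 * 16), nrow = 2, dimnames = list(c("A", "B"), NULL))
  nets <- build_all_networks(z, grid = density_grid(0.2, 0.3, 0.05))
  mt <- metrics_table(nets, null_config = null_model_config(5, seed = 1), seed = 1)
  expect_equal(nrow(mt), 2 * 3)
  expect_true(all(c("clustering", "efficiency", "modularity_Q", "path_length",
                    "small_worldness", "lcc_fraction") %in% names(mt)))
  expect_true(all(mt$clustering >= 0 & mt$clustering <= 1))
  expect_true(all(mt$efficiency >= 0 & mt$efficiency <= 1))
  ct <- centrality_table(nets)
  expect_equal(nrow(ct), 2 * 16)
  expect_true(all(ct$betweenness >= 0))
})
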