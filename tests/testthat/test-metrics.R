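# Graph-theory measures against hand values and brute-force oracles.

test_that("star and path graphs give hand-computed nodal values", {
  star <- net_from_edges(6, lapply(2:6, function(i) c(1, i)))
  nm <- nodal_metrics(star)
  expect_equal(nm$degree, c(5, 1, 1, 1, 1, 1))
  expect_equal(nm$betweenness, c(10, 0, 0, 0, 0, 0))  # C(5,2) leaf pairs
  expect_equal(global_metrics(star)$assortativity, -1)

  p3 <- net_from_edges(3, list(c(1, 2), c(2, 3)))
  expect_equal(nodal_metrics(p3)$betweenness, c(0, 1, 0))
  gm <- global_metrics(p3)
  expect_equal(gm$Lp, 4 / 3)
  expect_equal(gm$Eg, 5 / 6)
})

test_that("complete graph K6 attains the metric ceilings", {
  k6 <- net_from_edges(6, combn(6, 2, simplify = FALSE))
  gm <- global_metrics(k6)
  expect_equal(gm$Cp, 1)
  expect_equal(gm$Lp, 1)
  expect_equal(gm$Eg, 1)
  expect_equal(gm$Eloc, 1)
})

test_that("two disjoint triangles have modularity one half", {
  tri2 <- net_from_edges(6, list(c(1, 2), c(2, 3), c(1, 3),
                                 c(4, 5), c(5, 6), c(4, 6)))
  expect_equal(global_metrics(tri2)$modularity, 0.5)
})

test_that("edgeless graphs are flagged", {
  empty <- binary_network(matrix(FALSE, 5, 5), 0.1)
  gm <- global_metrics(empty)
  expect_equal(gm$Cp, 0)
  expect_equal(gm$Eg, 0)
  expect_true(is.na(gm$Lp))
})

test_that("metrics match brute-force oracles on random graphs", {
  for (s in 1:50) {
    n <- sample(4:10, 1)
    net <- random_net(n, runif(1, 0.3, 0.8), seed = 3000 + s)
    gm <- global_metrics(net, modularity_restarts = 0)
    nm <- nodal_metrics(net)
    oracle <- brute_global(net$adjacency)
    expect_equal(nm$degree, oracle$degree, tolerance = 1e-12)
    expect_equal(gm$Cp, oracle$Cp, tolerance = 1e-12)
    expect_equal(gm$Eg, oracle$Eg, tolerance = 1e-12)
    if (is.finite(oracle$Lp))
      expect_equal(gm$Lp, oracle$Lp, tolerance = 1e-12)
    expect_equal(nm$betweenness, brute_betweenness(net$adjacency),
                 tolerance = 1e-12)
  }
})

test_that("mean degree equals 2E/R and metrics are relabeling-invariant", {
  net <- random_net(12, 0.3, seed = 77)
  nm <- nodal_metrics(net)
  expect_equal(mean(nm$degree), sum(net$adjacency) / 12)
  perm <- with_test_seed(78, sample(12))
  netp <- binary_network(net$adjacency[perm, perm], net$sparsity)
  gm <- global_metrics(net, modularity_restarts = 0)
  gmp <- global_metrics(netp, modularity_restarts = 0)
  for (m in c("Cp", "Lp", "Eg", "Eloc", "assortativity"))
    expect_equal(gm[[m]], gmp[[m]], tolerance = 1e-12)
  expect_equal(sort(nodal_metrics(netp)$betweenness),
               sort(nm$betweenness), tolerance = 1e-12)
})

test_that("nested edge sets order Eg and Lp, and Eg >= 1/Lp", {
  W <- with_test_seed(79, {
    w <- matrix(runif(400), 20, 20); w[lower.tri(w, TRUE)] <- 0; w + t(w)
  })
  diag(W) <- 1
  S <- structure(list(subject_id = "s", values = W, region_ids = 1:20),
                 class = "similarity_matrix")
  n1 <- binarize_at_sparsity(S, 0.25)
  n2 <- binarize_at_sparsity(S, 0.45)
  g1 <- global_metrics(n1, modularity_restarts = 0)
  g2 <- global_metrics(n2, modularity_restarts = 0)
  expect_lte(g1$Eg, g2$Eg)
  expect_gte(g1$Lp, g2$Lp)
  for (g in list(g1, g2)) if (g$n_disconnected_pairs == 0)
    expect_gte(g$Eg, 1 / g$Lp)
})

test_that("degree-preserving rewiring keeps the degree sequence", {
  net <- random_net(30, 0.2, seed = 80)
  r1 <- rewire_preserving_degree(net, seed = 5)
  expect_equal(sort(rowSums(r1$adjacency)), sort(rowSums(net$adjacency)))
  expect_false(any(diag(r1$adjacency)))
  # determinism and seed sensitivity
  r2 <- rewire_preserving_degree(net, seed = 5)
  r3 <- rewire_preserving_degree(net, seed = 6)
  expect_identical(r1$adjacency, r2$adjacency)
  expect_false(identical(r1$adjacency, r3$adjacency))
  # too few edges: unchanged with a warning
  tiny <- net_from_edges(3, list(c(1, 2)))
  expect_warning(rt <- rewire_preserving_degree(tiny, seed = 1), "no legal swap")
  expect_identical(rt$adjacency, tiny$adjacency)
})

test_that("rewiring destroys lattice clustering", {
  lattice <- ws_net(60, 4, 0, seed = 81)   # ring lattice, high clustering
  cp0 <- global_metrics(lattice, modularity_restarts = 0)$Cp
  null_cp <- vapply(1:20, function(i)
    global_metrics(rewire_preserving_degree(lattice, seed = 900 + i),
                   modularity_restarts = 0)$Cp, numeric(1))
  expect_lt(mean(null_cp), cp0 / 2)
})

test_that("a rewiring-invariant graph normalises to exactly one", {
  k6 <- net_from_edges(6, combn(6, 2, simplify = FALSE))
  sw <- small_worldness(k6, n_null = 5, seed = 3)
  expect_equal(sw$gamma, 1)
  expect_equal(sw$lambda, 1)
  expect_equal(sw$sigma, 1)
})

test_that("metric curves integrate over the sparsity grid", {
  mk_rec <- function(s, eg) structure(list(sparsity = s, Cp = 0.5, Lp = 2,
                                           Eg = eg, Eloc = 0.6,
                                           assortativity = 0, modularity = 0.3),
                                      class = "graph_metrics_record")
  recs <- lapply(seq(0.1, 0.3, by = 0.05), mk_rec, eg = 0.7)
  curves <- metric_curves(recs)
  eg_curve <- curves[[which(vapply(curves, `[[`, "", "metric") == "Eg")]]
  expect_equal(eg_curve$auc, 0.7 * 0.2)          # constant v times width
  expect_equal(metric_curves(recs[1])[[1]]$auc, 0) # single point
  expect_error(metric_curves(rev(recs)), "increasing")
  # Eg is non-decreasing in sparsity for nested binarized networks
  W <- with_test_seed(82, {
    w <- matrix(runif(225), 15, 15); w[lower.tri(w, TRUE)] <- 0; w + t(w)
  })
  diag(W) <- 1
  S <- structure(list(subject_id = "s", values = W, region_ids = 1:15),
                 class = "similarity_matrix")
  nets <- sparsity_series(S, 0.1, 0.5, 0.1)
  egs <- vapply(nets, function(n)
    global_metrics(n, modularity_restarts = 0)$Eg, numeric(1))
  expect_true(all(diff(egs) >= 0))
})
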