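net_from_A <- function(A, nodes = paste0("n", seq_len(nrow(A)))) {
  # A[i, j] = weight of edge i -> j; package stores row = target
  info_network(t(A), nodes = nodes, zone_map = NULL)
}

test_that("path, efficiency, clustering and betweenness match exhaustive oracles", {
  for (seed in 1:30) {
    n <- sample(3:5, 1)
    A <- random_digraph(n, p = 0.6, seed = seed)
    if (all(A == 0)) next
    net <- net_from_A(A)
    oracle_D <- bf_distances(A)
    D <- gcnet:::distance_matrix(net)
    expect_equal(unname(D), oracle_D, tolerance = 1e-12)
    if (any(is.finite(oracle_D[row(oracle_D) != col(oracle_D)]))) {
      pm <- path_metrics(net)
      expect_equal(pm$lambda, bf_lambda(A), tolerance = 1e-12)
    }
    expect_equal(global_efficiency(net, by_zone = FALSE)$global,
      bf_efficiency(A), tolerance = 1e-12)
    expect_equal(unname(clustering_coef(net)), bf_clustering(A),
      tolerance = 1e-12)
    bc <- betweenness_centrality(net)
    oracle_bc <- bf_betweenness(A)
    expect_equal(unname(bc$vbc), oracle_bc$vbc, tolerance = 1e-12)
    for (r in seq_len(nrow(bc$ebc))) {
      i <- match(bc$ebc$source[r], net$nodes)
      j <- match(bc$ebc$target[r], net$nodes)
      expect_equal(bc$ebc$ebc[r], oracle_bc$ebc[i, j], tolerance = 1e-12)
    }
  }
})

test_that("closed-form metrics hold on canonical small graphs", {
  # complete digraph, unit weights
  A <- matrix(1, 4, 4)
  diag(A) <- 0
  net <- net_from_A(A)
  pm <- path_metrics(net)
  expect_equal(pm$lambda, 1)
  expect_equal(pm$diameter, 1)
  expect_true(all(pm$eccentricity == 1))
  expect_equal(global_efficiency(net, by_zone = FALSE)$global, 1)
  expect_true(all(betweenness_centrality(net)$vbc == 0))
  # directed 3-cycle
  A3 <- matrix(0, 3, 3)
  A3[1, 2] <- A3[2, 3] <- A3[3, 1] <- 1
  net3 <- net_from_A(A3)
  pm3 <- path_metrics(net3)
  expect_equal(pm3$lambda, 1.5)
  expect_equal(pm3$diameter, 2)
  expect_equal(global_efficiency(net3, by_zone = FALSE)$global, 0.75)
  # single edge of weight 0.5 has length 2
  A1 <- matrix(0, 2, 2)
  A1[1, 2] <- 0.5
  expect_equal(gcnet:::distance_matrix(net_from_A(A1))[1, 2], 2)
  # path A -> B -> C: B carries the only through-path
  Ap <- matrix(0, 3, 3)
  Ap[1, 2] <- Ap[2, 3] <- 1
  bc <- betweenness_centrality(net_from_A(Ap))
  expect_equal(unname(bc$vbc), c(0, 1, 0))
  # directed triangle with all 6 edges: clustering 1 everywhere
  expect_true(all(abs(clustering_coef(net_from_A(matrix(1, 3, 3) - diag(3))) - 1) < 1e-12))
  # hub -> leaves star: hub clustering 0
  As <- matrix(0, 4, 4)
  As[1, 2:4] <- 1
  expect_equal(unname(clustering_coef(net_from_A(As))[1]), 0)
})

test_that("a bridge edge between two strongly connected clusters maximises EBC", {
  A <- matrix(0, 6, 6)
  for (i in 1:3) for (j in 1:3) if (i != j) A[i, j] <- 1
  for (i in 4:6) for (j in 4:6) if (i != j) A[i, j] <- 1
  A[3, 4] <- 1 # the bridge
  bc <- betweenness_centrality(net_from_A(A))
  bridge <- bc$ebc$ebc[bc$ebc$source == "n3" & bc$ebc$target == "n4"]
  expect_equal(bridge, max(bc$ebc$ebc))
})

test_that("scaling all weights rescales distances and preserves rankings", {
  A <- random_digraph(5, p = 0.6, seed = 99)
  net1 <- net_from_A(A)
  netc <- net_from_A(3 * A)
  D1 <- gcnet:::distance_matrix(net1)
  Dc <- gcnet:::distance_matrix(netc)
  expect_equal(Dc, D1 / 3, tolerance = 1e-12)
  expect_equal(path_metrics(netc)$lambda, path_metrics(net1)$lambda / 3,
    tolerance = 1e-12)
  b1 <- betweenness_centrality(net1)
  bc <- betweenness_centrality(netc)
  expect_equal(order(b1$vbc), order(bc$vbc))
  expect_equal(clustering_coef(net1), clustering_coef(netc), tolerance = 1e-12)
})

test_that("diameter equals max eccentricity and subgraphs lose efficiency", {
  A <- random_digraph(5, p = 0.7, seed = 3)
  net <- net_from_A(A)
  pm <- path_metrics(net)
  expect_equal(pm$diameter, max(pm$eccentricity, na.rm = TRUE))
  Asub <- A
  Asub[which(Asub > 0)[1:3]] <- 0
  if (any(Asub > 0)) {
    expect_lte(bf_efficiency(Asub), bf_efficiency(A) + 1e-12)
    expect_lte(global_efficiency(net_from_A(Asub), by_zone = FALSE)$global,
      global_efficiency(net, by_zone = FALSE)$global + 1e-12)
  }
})

test_that("zone efficiency averages the right source -> target blocks", {
  mont <- make_montage(4) # F1, C1, P1, O1: four distinct zones
  A <- matrix(0, 4, 4)
  A[3, 1] <- 1 # P1 -> F1
  A[4, 3] <- 0.5 # O1 -> P1
  net <- info_network(t(A), nodes = mont$label)
  eff <- global_efficiency(net)
  expect_equal(eff$zones["parietal", "frontal"], 1)
  expect_equal(eff$zones["occipital", "parietal"], 0.5)
  expect_equal(eff$zones["occipital", "frontal"], 1 / 3) # path length 2 + 1
  expect_equal(eff$zones["frontal", "occipital"], 0)
})

test_that("assortativity reflects hub structure and degenerate cases", {
  # hub-and-spoke: hub out-degree high feeding degree-1 leaves
  A <- matrix(0, 5, 5)
  A[1, 2:5] <- 1
  A[2, 3] <- 1 # one extra edge so degrees vary on both sides
  r <- assortativity_degree_dir(net_from_A(A))
  expect_true(r >= -1 && r <= 1)
  expect_lt(r, 0)
  # degree-regular ring: zero variance, undefined
  ring <- matrix(0, 4, 4)
  ring[cbind(1:4, c(2, 3, 4, 1))] <- 1
  res <- assortativity_degree_dir(net_from_A(ring))
  expect_true(is.na(res))
  expect_match(attr(res, "note"), "degenerate")
  expect_error(assortativity_degree_dir(net_from_A(matrix(0, 3, 3))), "2 edges")
})

test_that("attack resilience decays efficiency monotonically towards zero", {
  A <- random_digraph(6, p = 0.7, seed = 5)
  curve <- attack_resilience(net_from_A(A), steps = 5)
  expect_equal(nrow(curve), 5)
  expect_true(all(diff(curve$efficiency) <= 1e-12))
})

test_that("degree-preserving surrogates keep both degree sequences exactly", {
  A <- random_digraph(8, p = 0.4, seed = 21)
  net <- net_from_A(A)
  ne <- null_ensemble(net, n_surrogates = 15, seed = 4)
  out0 <- rowSums(A > 0)
  in0 <- colSums(A > 0)
  for (m in ne$surrogates) {
    As <- t(m)
    expect_equal(unname(rowSums(As > 0)), unname(out0))
    expect_equal(unname(colSums(As > 0)), unname(in0))
    expect_equal(sort(As[As > 0]), sort(A[A > 0])) # same weight multiset
  }
  ne2 <- null_ensemble(net, n_surrogates = 15, seed = 4)
  expect_identical(ne$surrogates, ne2$surrogates)
  expect_identical(ne$z, ne2$z)
  expect_error(null_ensemble(net_from_A(matrix(0, 3, 3))), "sparse")
})

test_that("a graph drawn from the null family has near-zero clustering z-score", {
  set.seed(17)
  ok <- replicate(10, {
    A <- random_digraph(10, p = 0.35, seed = sample.int(1e6, 1))
    net <- net_from_A(A)
    ne <- null_ensemble(net, n_surrogates = 30, seed = sample.int(1e6, 1))
    abs(ne$z["clustering"]) < 3
  })
  expect_gte(mean(ok), 0.8)
})

test_that("build_network applies mask, source and normalisation correctly", {
  delta <- matrix(c(0, 0.1, 0.5, 0), 2, 2,
    dimnames = list(c("F1", "C1"), c("F1", "C1")))
  cm <- connectivity_matrix(delta)
  # all-false mask -> empty network
  net0 <- build_network(cm)
  expect_true(net0$empty)
  expect_error(path_metrics(net0), "disconnected")
  expect_equal(global_efficiency(net0, by_zone = FALSE)$global, 0)
  # all-true mask -> weights equal delta off-diagonal
  cm$sig_mask <- matrix(TRUE, 2, 2)
  net1 <- build_network(cm)
  expect_equal(net1$weights, cm$delta)
  netn <- build_network(cm, normalise = TRUE)
  expect_equal(max(netn$weights), 1)
  nett <- build_network(cm, weight_source = "te")
  expect_equal(nett$weights, cm$te)
})

test_that("network features assemble tidily with optional null z-scores", {
  A <- random_digraph(6, p = 0.6, seed = 2)
  net <- net_from_A(A)
  nf <- network_features(net, null = null_ensemble(net, n_surrogates = 10, seed = 1))
  expect_s3_class(nf, "network_features")
  expect_true(all(c("lambda", "diameter", "efficiency", "clustering",
    "assortativity") %in% nf$scalars$feature))
  expect_true(any(is.finite(nf$scalars$null_z)))
  td <- tidy(nf)
  expect_true(all(c("feature", "node", "value") %in% names(td)))
  g <- glance(nf)
  expect_equal(g$lambda, path_metrics(net)$lambda)
})
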