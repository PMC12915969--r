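test_that("edge inclusion follows the strict absolute-threshold rule", {
  rho <- matrix(0.5, 17, 17); diag(rho) <- 1
  full <- build_network(rho, 0.20)
  expect_equal(sum(full$adjacency) / 2, 136)

  rho2 <- matrix(0.19, 17, 17); diag(rho2) <- 1
  expect_equal(sum(build_network(rho2, 0.20)$adjacency), 0)

  # boundary: |rho| exactly at the threshold is excluded
  rho3 <- matrix(c(1, 0.2, 0.2, 1), 2)
  expect_equal(sum(build_network(rho3, 0.20)$adjacency), 0)
  # negative correlations count through their magnitude
  rho4 <- matrix(c(1, -0.3, -0.3, 1), 2)
  expect_equal(sum(build_network(rho4, 0.20)$adjacency), 2)

  bad <- rho; bad[1, 2] <- 0.9
  expect_error(build_network(bad), "symmetric")
})

test_that("star-graph centralities match their closed forms", {
  adj <- matrix(0L, 5, 5)
  adj[1, 2:5] <- 1L; adj[2:5, 1] <- 1L
  dimnames(adj) <- list(paste0("v", 1:5), paste0("v", 1:5))
  cen <- node_centralities(net_from_adjacency(adj))
  expect_equal(cen$degree, c(4L, 1L, 1L, 1L, 1L))
  expect_equal(cen$closeness[1], 1)
  expect_equal(cen$betweenness[1], 1)
  expect_equal(cen$closeness[2], 4 / 7)
  expect_equal(cen$clustering, rep(0, 5))
})

test_that("a 17-node hub with one node at distance 2 has closeness 16/17", {
  # hub adjacent to 15 nodes; the 17th attaches to a leaf
  adj <- matrix(0L, 17, 17)
  adj[1, 2:16] <- 1L; adj[2:16, 1] <- 1L
  adj[16, 17] <- 1L; adj[17, 16] <- 1L
  dimnames(adj) <- list(paste0("v", 1:17), paste0("v", 1:17))
  cen <- node_centralities(net_from_adjacency(adj))
  expect_equal(cen$degree[1], 15L)
  expect_equal(cen$closeness[1], 16 / 17, tolerance = 1e-12)
})

test_that("centralities equal the brute-force oracle on small random graphs", {
  set.seed(50)
  for (rep in 1:12) {
    n <- sample(4:8, 1)
    adj <- random_adjacency(n, p = runif(1, 0.25, 0.7))
    cen <- node_centralities(net_from_adjacency(adj))
    expect_equal(cen$degree, as.integer(rowSums(adj)))
    expect_equal(cen$closeness, closeness_oracle(adj), tolerance = 1e-12)
    expect_equal(cen$betweenness, betweenness_oracle(adj), tolerance = 1e-12)
    expect_equal(cen$clustering, clustering_oracle(adj), tolerance = 1e-12)
  }
})

test_that("global metrics match enumeration on canonical graphs", {
  # path graph P4
  p4 <- matrix(0L, 4, 4)
  p4[cbind(1:3, 2:4)] <- 1L; p4 <- p4 + t(p4)
  dimnames(p4) <- list(paste0("v", 1:4), paste0("v", 1:4))
  gm <- global_metrics(net_from_adjacency(p4))
  expect_equal(gm$density, 0.5)
  expect_equal(gm$diameter, 3L)
  expect_equal(gm$average_path_length, 10 / 6, tolerance = 1e-12)

  # complete K17
  k17 <- matrix(1L, 17, 17); diag(k17) <- 0L
  dimnames(k17) <- list(paste0("v", 1:17), paste0("v", 1:17))
  gmk <- global_metrics(net_from_adjacency(k17))
  expect_equal(gmk$density, 1)
  expect_equal(gmk$diameter, 1L)
  expect_equal(gmk$average_path_length, 1)
  expect_equal(gmk$average_clustering, 1)
  expect_equal(gmk$degree_variance, 0)
  expect_equal(gmk$fraction_nodes_clustering_gt_0_90, 1)
})

test_that("global metrics agree with oracles on random graphs and relabeling", {
  set.seed(51)
  adj <- random_adjacency(7, 0.5)
  gm <- global_metrics(net_from_adjacency(adj))
  expect_equal(gm$average_clustering, mean(clustering_oracle(adj)), tolerance = 1e-12)
  expect_equal(gm$degree_variance,
               mean((rowSums(adj) - mean(rowSums(adj)))^2), tolerance = 1e-12)
  # permutation of node labels leaves every global metric unchanged
  p <- sample(7)
  gm2 <- global_metrics(net_from_adjacency(adj[p, p]))
  for (f in c("density", "diameter", "average_path_length",
              "average_clustering", "degree_variance")) {
    expect_equal(gm2[[f]], gm[[f]], tolerance = 1e-12)
  }
})

test_that("disconnected graphs fall back to the largest component with warning", {
  adj <- matrix(0L, 6, 6)
  adj[1, 2] <- adj[2, 1] <- 1L
  adj[3, 4] <- adj[4, 3] <- 1L; adj[4, 5] <- adj[5, 4] <- 1L
  dimnames(adj) <- list(paste0("v", 1:6), paste0("v", 1:6))
  expect_warning(gm <- global_metrics(net_from_adjacency(adj)), "disconnected")
  expect_equal(gm$diameter, 2L)
  expect_message(cen <- node_centralities(net_from_adjacency(adj)), "disconnected")
  expect_equal(cen$closeness[6], 0)  # isolated node
  expect_true(all(cen$closeness >= 0 & cen$closeness <= 1))
})

test_that("the CS coefficient behaves as a stability measure", {
  # a nested-neighborhood (threshold) graph: degree ranking survives any
  # small node removal, so the CS coefficient is essentially 1
  n <- 17
  adj <- matrix(0L, n, n)
  for (i in 1:8) for (j in (i + 1):(n - i + 1)) {
    if (j <= n) { adj[i, j] <- 1L; adj[j, i] <- 1L }
  }
  diag(adj) <- 0L
  dimnames(adj) <- list(paste0("v", 1:n), paste0("v", 1:n))
  net <- net_from_adjacency(adj)
  cs <- cs_coefficient(net, drop_fraction = 0.10, n_iter = 400, seed = 3)
  expect_gte(cs$cs_coefficient, 0.99)
  expect_equal(cs$mode, "node_drop")

  # exhaustive oracle: mean correlation over all C(17,2) possible drop pairs
  d0 <- rowSums(adj)
  exact <- mean(apply(combn(n, 2), 2, function(dr) {
    keep <- setdiff(seq_len(n), dr)
    cor(d0[keep], rowSums(adj[keep, keep]))
  }))
  expect_equal(cs$cs_coefficient, exact, tolerance = 0.005)

  # dropping almost nothing drives the CS coefficient to 1
  cs_small <- cs_coefficient(net, drop_fraction = 0.001, n_iter = 200, seed = 4)
  expect_gte(cs_small$cs_coefficient, cs$cs_coefficient - 1e-9)
  expect_gte(cs_small$cs_coefficient, 0.995)

  # a regular graph has constant degrees: correlation undefined
  ring <- matrix(0L, 6, 6)
  ring[cbind(1:6, c(2:6, 1))] <- 1L; ring <- ring + t(ring)
  dimnames(ring) <- list(paste0("v", 1:6), paste0("v", 1:6))
  expect_error(cs_coefficient(net_from_adjacency(ring)), "degenerate")
})

test_that("case-dropping stability re-estimates the network per subsample", {
  pp <- study_scale_pipeline(1)
  cs <- cs_coefficient(pp$net, residuals = pp$residuals, drop_fraction = 0.10,
                       n_iter = 40, mode = "case_drop", seed = 6)
  expect_gte(cs$cs_coefficient, 0.90)
  expect_equal(cs$mode, "case_drop")
  expect_error(cs_coefficient(pp$net, mode = "case_drop"), "residuals")
})

test_that("raising the threshold never increases any degree", {
  pp <- study_scale_pipeline(1)
  taus <- c(0.10, 0.15, 0.20, 0.25, 0.30, 0.40)
  degs <- sapply(taus, function(t) rowSums(build_network(pp$pcorr, t)$adjacency))
  for (j in 2:length(taus)) {
    expect_true(all(degs[, j] <= degs[, j - 1]))
  }
})

test_that("threshold sensitivity reports identity, retention and attenuation", {
  set.seed(55)
  # identical thresholds: everything unchanged
  pp <- study_scale_pipeline(1)
  same <- sensitivity_rerank(pp$pcorr, tau = 0.20, tau2 = 0.20 + 1e-13)
  expect_true(all(same$verdicts$verdict == "unchanged"))

  # dominant hub above the strict threshold everywhere keeps its top rank
  n <- 8
  rho <- diag(n)
  rho[1, 2:n] <- rho[2:n, 1] <- 0.6
  rho[2, 3] <- rho[3, 2] <- 0.3
  dimnames(rho) <- list(paste0("v", 1:n), paste0("v", 1:n))
  rep_ <- sensitivity_rerank(rho, tau = 0.20, tau2 = 0.25)
  expect_equal(rep_$top3$strict[rep_$top3$metric == "degree"][1], "v1")
  # the hub keeps every edge here, so its row is unchanged (hence not attenuated)
  expect_true(rep_$verdicts$verdict[1] %in% c("unchanged", "stable"))

  # a node whose every edge sits in (0.20, 0.25) loses them all
  rho2 <- diag(n)
  rho2[1, 2:n] <- rho2[2:n, 1] <- 0.22
  rho2[2, 3] <- rho2[3, 2] <- 0.5
  dimnames(rho2) <- list(paste0("v", 1:n), paste0("v", 1:n))
  rep2 <- sensitivity_rerank(rho2, tau = 0.20, tau2 = 0.25)
  expect_equal(rep2$verdicts$verdict[1], "attenuated")
  expect_equal(sum(rep2$strict$adjacency[1, ]), 0L)
})

test_that("edge lists and GraphML export round-trip the network", {
  pp <- study_scale_pipeline(1)
  el <- edge_list(pp$net)
  expect_equal(nrow(el), sum(pp$net$adjacency) / 2)
  expect_true(all(abs(el$rho) > pp$net$tau))
  expect_setequal(unique(el$sign), c("positive", "negative"))

  path <- tempfile(fileext = ".graphml")
  export_graphml(pp$net, path)
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::ecount(g), nrow(el))
  expect_equal(igraph::vcount(g), 17)
})
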