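test_that("clustering coefficients match hand enumeration", {
  expect_equal(degree_and_clustering(triangle_graph())$acc, 1)
  expect_equal(degree_and_clustering(path_graph(3))$acc, 0)
  # K4 minus one edge: degrees [3,3,2,2]; the two degree-3 nodes each sit
  # in 2 of their 3 neighbor pairs (cc = 2/3), the degree-2 nodes close
  # their single pair (cc = 1): ACC = (2/3 + 2/3 + 1 + 1)/4 = 5/6
  g <- igraph::make_full_graph(4)
  g <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(3, 4)))
  g <- igraph::set_vertex_attr(g, "name", value = letters[1:4])
  dc <- degree_and_clustering(cooc_network(g))
  expect_setequal(unname(dc$degree), c(3, 3, 2, 2))
  expect_equal(dc$acc, 5 / 6, tolerance = 1e-12)
})

test_that("path metrics follow the reachable-pairs convention", {
  pm <- path_metrics(path_graph(3))
  expect_equal(pm$apl, 4 / 3)
  expect_equal(pm$diameter, 2)
  # two disjoint edges: unreachable pairs excluded
  g <- igraph::make_graph(c("a", "b", "c", "d"), directed = FALSE)
  pm2 <- path_metrics(cooc_network(g))
  expect_equal(pm2$apl, 1)
  expect_equal(pm2$diameter, 1)
  expect_equal(pm2$component_sizes, c(2, 2))
  # C5 by brute force: distances {1,1,2,2} per node
  pm3 <- path_metrics(cooc_network(igraph::make_ring(5)))
  expect_equal(pm3$apl, 1.5)
  expect_equal(pm3$diameter, 2)
  # edgeless graph: APL flagged missing, never 0
  pm4 <- path_metrics(cooc_network(igraph::make_empty_graph(4, directed = FALSE)))
  expect_true(is.na(pm4$apl))
})

test_that("diameter >= APL on random graphs", {
  for (seed in 1:20) {
    set.seed(seed)
    g <- igraph::sample_gnm(30, sample(30:60, 1))
    pm <- path_metrics(cooc_network(g))
    if (!is.na(pm$apl)) expect_gte(pm$diameter, pm$apl)
  }
})

test_that("modularity formula matches analytic values and independent oracles", {
  b <- generate_benchmark_graph("two-cliques", clique_size = 4)
  expect_equal(modularity_q(b$network, b$membership), 0.5, tolerance = 1e-12)
  one <- setNames(rep(1L, length(b$membership)), names(b$membership))
  expect_equal(modularity_q(b$network, one), 0, tolerance = 1e-12)

  for (seed in 1:10) {
    set.seed(seed)
    g <- igraph::sample_gnm(25, 60)
    g <- igraph::set_vertex_attr(g, "name", value = paste0("v", 1:25))
    mem <- setNames(sample(1:4, 25, replace = TRUE), paste0("v", 1:25))
    q <- modularity_q(cooc_network(g), mem)
    expect_equal(q, oracle_modularity(g, mem), tolerance = 1e-12)
    expect_equal(q, igraph::modularity(g, mem), tolerance = 1e-12)
  }
})

test_that("Louvain detection finds exact structure and beats trivial partitions", {
  b <- generate_benchmark_graph("two-cliques", clique_size = 4)
  part <- detect_modules(b$network, seed = 3)
  expect_equal(part$n_modules, 2)
  expect_equal(part$Q, 0.5, tolerance = 1e-12)
  expect_true(part$modular)
  # detected modules are exactly the cliques
  split_by <- unname(lapply(split(names(part$membership), part$membership), sort))
  truth_split <- unname(lapply(split(names(b$membership), b$membership), sort))
  expect_setequal(split_by, truth_split)
  expect_gte(part$Q, 0)
  # random partitions never beat the optimizer on the fixture
  set.seed(1)
  for (i in 1:20) {
    mem <- setNames(sample(1:2, 8, replace = TRUE), names(b$membership))
    expect_lte(modularity_q(b$network, mem), part$Q + 1e-12)
  }
  expect_error(detect_modules(cooc_network(igraph::make_empty_graph(2, directed = FALSE))),
               "no edges")
})

test_that("planted-partition benchmark is recovered with high ARI", {
  skip_if_not_installed("mclust")
  bench <- generate_benchmark_graph("planted-partition", k = 4, block_size = 20,
                                    p_in = 0.9, p_out = 0.01, seed = 5)
  part <- detect_modules(bench$network, seed = 5)
  ari <- mclust::adjustedRandIndex(part$membership[names(bench$membership)],
                                   bench$membership)
  expect_gt(ari, 0.9)
})

test_that("null models honor their invariants", {
  set.seed(10)
  for (i in 1:100) {
    g <- igraph::sample_gnm(20, 35)
    net <- cooc_network(g)
    rw <- randomize_network(net, model = "rewire", n_swaps_factor = 5, seed = i)
    expect_identical(sort(unname(igraph::degree(rw$graph))),
                     sort(unname(igraph::degree(g))))
    expect_false(igraph::any_loop(rw$graph) || igraph::any_multiple(rw$graph))
  }
  gm <- randomize_network(cooc_network(igraph::sample_gnm(100, 200)),
                          model = "gnm", seed = 3)
  expect_equal(igraph::vcount(gm$graph), 100)
  expect_equal(igraph::ecount(gm$graph), 200)
})

test_that("gnm ensemble mean ACC matches the 2m/(n(n-1)) expectation", {
  base <- cooc_network(igraph::sample_gnm(60, 300))
  accs <- vapply(1:200, function(i)
    degree_and_clustering(randomize_network(base, model = "gnm", seed = i))$acc, 0)
  expected <- 2 * 300 / (60 * 59)
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - expected), 3 * se)
})

test_that("rewiring destroys planted modularity", {
  b <- generate_benchmark_graph("two-cliques", clique_size = 4)
  qs <- vapply(1:100, function(i) {
    rn <- randomize_network(b$network, model = "rewire", n_swaps_factor = 100, seed = i)
    detect_modules(rn, seed = i)$Q
  }, 0)
  expect_gte(mean(qs < 0.5), 0.95)
})

test_that("null ensemble z-scores separate structure from noise", {
  # self-consistency: a gnm draw against its own gnm ensemble has small |z|
  g <- withr::with_seed(4, igraph::sample_gnm(40, 120))
  s <- null_ensemble_summary(cooc_network(g), model = "gnm", n_replicates = 50, seed = 4)
  for (k in c("acc", "apl", "Q"))
    expect_lt(abs(s$null_stats[[k]]$z), 3)
  # planted modules against rewired nulls: z(Q) > 3
  bench <- generate_benchmark_graph("planted-partition", k = 4, block_size = 15,
                                    p_in = 0.8, p_out = 0.02, seed = 6)
  s2 <- null_ensemble_summary(bench$network, model = "rewire",
                              n_replicates = 50, seed = 6)
  expect_gt(s2$null_stats$Q$z, 3)
  expect_true(s2$modular_small_world)
})

test_that("null means are stable in the number of replicates", {
  bench <- generate_benchmark_graph("planted-partition", k = 3, block_size = 12,
                                    p_in = 0.7, p_out = 0.05, seed = 9)
  s10 <- null_ensemble_summary(bench$network, model = "rewire", n_replicates = 10, seed = 1)
  s100 <- null_ensemble_summary(bench$network, model = "rewire", n_replicates = 100, seed = 2)
  for (k in c("acc", "Q")) {
    tol <- 3 * s100$null_stats[[k]]$null_sd / sqrt(10)
    expect_lt(abs(s10$null_stats[[k]]$null_mean - s100$null_stats[[k]]$null_mean), tol)
  }
})

test_that("positive edge fraction counts signs and complements the negative share", {
  g <- igraph::make_ring(5)
  g <- igraph::set_edge_attr(g, "sign", value = rep("+", 5))
  expect_equal(positive_edge_fraction(cooc_network(g)), 1)
  g2 <- igraph::set_edge_attr(igraph::make_star(5, mode = "undirected"), "sign",
                              value = c("+", "+", "+", "-"))
  pf <- positive_edge_fraction(cooc_network(g2))
  expect_equal(pf, 0.75)
  neg <- mean(igraph::E(g2)$sign == "-")
  expect_equal(pf, 1 - neg)
  expect_warning(positive_edge_fraction(
    cooc_network(igraph::make_empty_graph(2, directed = FALSE))), "undefined")
})
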