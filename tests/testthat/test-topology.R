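test_that("global metrics match closed forms on canonical graphs", {
  k4 <- graph_as_network(local({
    g <- igraph::make_full_graph(4)
    igraph::V(g)$name <- paste0("v", 1:4)
    g
  }))
  gm <- global_metrics(k4)
  expect_equal(gm$avg_degree, 3)
  expect_equal(gm$avg_clustering_coefficient, 1)

  p3 <- graph_as_network(local({
    g <- igraph::make_graph(~ a - b, b - c)
    g
  }))
  gm3 <- global_metrics(p3)
  expect_equal(gm3$avg_path_length, 4 / 3)

  # two disjoint triangles: 6 connected pairs (all length 1), 9 excluded
  tg <- graph_as_network(local({
    g <- igraph::make_full_graph(3) + igraph::make_full_graph(3)
    igraph::V(g)$name <- paste0("v", 1:6)
    g
  }))
  gmt <- global_metrics(tg)
  expect_equal(gmt$avg_path_length, 1)
  expect_equal(gmt$n_disconnected_pairs, 9)
})

test_that("Louvain recovers the two-clique bridge partition (Newman oracle)", {
  net <- graph_as_network(two_clique_bridge())
  part <- louvain_partition(net, seed = 1)
  expect_equal(part$n_modules, 2L)
  # direct evaluation of Q = sum(e_c/m - (d_c/2m)^2): m = 13, e_c = 6,
  # d_c = 13 per clique -> Q = 2 * (6/13 - 1/4) = 0.4230769...
  expect_equal(part$modularity, 2 * (6 / 13 - 0.25), tolerance = 1e-6)
  expect_equal(part$modularity,
               newman_q(net$edges[, c("otu_a", "otu_b")],
                        part$membership),
               tolerance = 1e-12)
  # determinism
  part2 <- louvain_partition(net, seed = 1)
  expect_identical(part$membership, part2$membership)
  # single clique: nothing to split
  k5 <- graph_as_network(local({
    g <- igraph::make_full_graph(5)
    igraph::V(g)$name <- paste0("v", 1:5)
    g
  }))
  expect_equal(louvain_partition(k5, seed = 1)$n_modules, 1L)
})

test_that("module size statistics reproduce printed arithmetic", {
  expect_equal(module_size_stats(n_nodes = 426,
                                 n_modules = 119)$avg_module_size, 3.58)
  expect_equal(module_size_stats(n_nodes = 657,
                                 n_modules = 161)$avg_module_size, 4.08)
  # all-isolated degenerate case via an edgeless network
  iso <- chronet:::new_cooccurrence_network(
    tibble::tibble(otu_id = paste0("v", 1:7), phylum = "P",
                   degree = 0L),
    tibble::tibble(otu_a = character(), otu_b = character(),
                   rho = numeric(), q = numeric(), sign = integer()),
    0.7, 0.01)
  part <- louvain_partition(iso)
  expect_equal(part$n_modules, 7L)
  expect_equal(module_size_stats(part)$avg_module_size, 1)
  expect_equal(part$modularity, 0)
})

test_that("Zi and Pi match hand evaluations", {
  # two triangles bridged by node x with degree 4 split 2/2
  g <- igraph::make_graph(~ a1 - a2, a2 - a3, a1 - a3,
                          b1 - b2, b2 - b3, b1 - b3,
                          x - a1, x - a2, x - b1, x - b2)
  net <- graph_as_network(g)
  part <- louvain_partition(net, seed = 1)
  roles <- zipi_roles(net, part)
  x_row <- roles[roles$otu_id == "x", ]
  # the two triangles land in different modules; x's degree 4 splits 2/2
  # across them: Pi = 1 - 2*(2/4)^2 = 0.5
  expect_false(part$membership["a1"] == part$membership["b1"])
  expect_equal(x_row$pi, 0.5)
  # nodes with all edges inside their module have Pi = 0
  a3_row <- roles[roles$otu_id == "a3", ]
  expect_equal(a3_row$pi, 0)
  expect_true(all(roles$pi >= 0 & roles$pi <= 1))
})

test_that("role boxes tile the (Zi, Pi) plane", {
  grid <- expand.grid(zi = seq(-2, 5, by = 0.5),
                      pi = seq(0, 1, by = 0.05))
  roles <- classify_role(grid$zi, grid$pi)
  expect_true(all(roles %in% c("Peripheral", "Connector", "ModuleHub",
                               "NetworkHub")))
  expect_identical(classify_role(3.0, 0.7), "NetworkHub")
  expect_identical(classify_role(3.0, 0.62), "ModuleHub")
  expect_identical(classify_role(2.5, 0.7), "Connector")
  expect_identical(classify_role(2.5, 0.62), "Peripheral")
  # boundary values are exclusive for > and inclusive for <=
  expect_identical(classify_role(2.500001, 0.620001), "NetworkHub")
})

test_that("null-model Z-score satisfies its formula and sign properties", {
  net <- graph_as_network(two_clique_bridge())
  nm <- modularity_zscore(net, n_random = 50, seed = 7)
  expect_equal(nm$z, (nm$q_obs - mean(nm$q_rand)) / sd(nm$q_rand))
  expect_gt(nm$z, 0)
  # reproducibility
  nm2 <- modularity_zscore(net, n_random = 50, seed = 7)
  expect_identical(nm$q_rand, nm2$q_rand)
  # invariance to node relabeling
  relab <- net
  relab$nodes$otu_id <- paste0("w", seq_len(nrow(net$nodes)))
  key <- setNames(relab$nodes$otu_id, net$nodes$otu_id)
  relab$edges$otu_a <- unname(key[net$edges$otu_a])
  relab$edges$otu_b <- unname(key[net$edges$otu_b])
  nm3 <- modularity_zscore(relab, n_random = 50, seed = 7)
  expect_equal(nm$z, nm3$z)
})

test_that("a random graph is not called modular against its own null", {
  g <- withr::with_seed(99, igraph::sample_gnm(40, 90))
  igraph::V(g)$name <- paste0("v", 1:40)
  nm <- modularity_zscore(graph_as_network(g), n_random = 60, seed = 3)
  expect_lt(abs(nm$z), 3)
})

test_that("keystone taxonomy profiles count phyla per role", {
  roles <- tibble::tibble(
    otu_id = paste0("o", 1:5),
    phylum = c("A", "A", "B", "C", "C"),
    module = 1L, degree = 3L, zi = c(3, 3, 3, 0, 0),
    pi = c(0.1, 0.1, 0.1, 0.2, 0.2),
    role = c("ModuleHub", "ModuleHub", "ModuleHub", "Peripheral",
             "Peripheral"))
  prof <- keystone_taxonomy_profile(roles)
  expect_equal(prof$fraction[prof$phylum == "A"], 2 / 3)
  expect_equal(prof$fraction[prof$phylum == "B"], 1 / 3)
  expect_equal(sum(prof$fraction), 1)
  none <- dplyr::mutate(roles, role = "Peripheral")
  expect_message(empty <- keystone_taxonomy_profile(none), "No keystone")
  expect_equal(nrow(empty), 0L)
})

test_that("planted modules are recovered from generated counts", {
  aris <- vapply(1:3, function(s) {
    gen <- generate_chronosequence(seed = 400 + s)
    rec <- gen$truth$stages$sample_id[gen$truth$stages$stage == "recovery"]
    net <- build_network(correlation_edges(
      filter_core_otus(subset_otu_table(gen$table, samples = rec))))
    part <- louvain_partition(net, seed = s)
    tr <- gen$truth$otus
    common <- intersect(names(part$membership),
                        tr$otu_id[!is.na(tr$recovery_module)])
    ari(part$membership[common],
        tr$recovery_module[match(common, tr$otu_id)])
  }, numeric(1))
  expect_gte(mean(aris >= 0.8), 2 / 3)
})
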