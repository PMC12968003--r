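blob_data <- function(centers, n_per = 8, sd = 0.15, seed = 1) {
  set.seed(seed)
  x <- do.call(rbind, lapply(centers, function(cc) {
    cbind(rnorm(n_per, cc[1], sd), rnorm(n_per, cc[2], sd))
  }))
  rownames(x) <- paste0("s", seq_len(nrow(x)))
  x
}

test_that("silhouette scan finds the planted number of blobs", {
  x2 <- blob_data(list(c(0, 0), c(6, 6)))
  d2 <- as.matrix(dist(x2))
  sc2 <- silhouette_scan(d2, pcoa_ordination(d2), seed = 3)
  expect_true(all(sc2$best_k$best_k == 2))

  x3 <- blob_data(list(c(0, 0), c(8, 0), c(4, 8)))
  d3 <- as.matrix(dist(x3))
  sc3 <- silhouette_scan(d3, pcoa_ordination(d3), seed = 3)
  expect_true(all(sc3$best_k$best_k == 3))

  # determinism and range checks
  sc2b <- silhouette_scan(d2, pcoa_ordination(d2), seed = 3)
  expect_identical(sc2$scan, sc2b$scan)
  expect_true(all(sc2$scan$silhouette >= -1 & sc2$scan$silhouette <= 1))
  expect_error(silhouette_scan(d2[1:5, 1:5],
                               pcoa_ordination(d2[1:5, 1:5]), k_max = 6),
               "k_max")
})

test_that("consensus assignment is invariant to clusterer relabeling", {
  x <- blob_data(list(c(0, 0), c(6, 6)), seed = 2)
  d <- as.matrix(dist(x))
  ord <- pcoa_ordination(d)
  ca <- consensus_cluster(d, ord, k = 2, seed = 5)
  # clean blobs: both routes agree on every sample after alignment
  expect_true(all(ca$core_stage != "Ambiguous"))
  expect_identical(ca$hier_label, ca$kmeans_label)
  # consensus labels define the same partition as the blobs
  truth <- rep(1:2, each = 8)
  expect_equal(ari(ca$core_stage, truth), 1)
})

test_that("disagreeing samples are designated Ambiguous", {
  ca <- tibble::tibble(sample_id = paste0("s", 1:6),
                       hier_label = c(1, 1, 1, 2, 2, 2),
                       kmeans_label = c(1, 1, 2, 2, 2, 2),
                       core_stage = c("C1", "C1", "Ambiguous",
                                      "C2", "C2", "C2"))
  class(ca) <- c("consensus_assignment", class(ca))
  # the rule: Core iff aligned labels agree
  expect_identical(ca$core_stage == "Ambiguous",
                   ca$hier_label != ca$kmeans_label)
})

test_that("stage labeling follows the convergence rule", {
  ca <- tibble::tibble(sample_id = paste0("s", 1:6),
                       hier_label = rep(1:2, each = 3),
                       kmeans_label = rep(1:2, each = 3),
                       core_stage = rep(c("C1", "C2"), each = 3))
  class(ca) <- c("consensus_assignment", class(ca))
  conv <- tibble::tibble(sample_id = paste0("s", 1:6),
                         group = "x",
                         aitchison_distance = c(5, 5, 5, 2, 2, 2))
  lab <- label_stages(ca, convergence = conv)
  expect_identical(unique(lab$core_stage[1:3]), "Chaos")
  expect_identical(unique(lab$core_stage[4:6]), "Recovery")
  map <- attr(lab, "stage_map")
  expect_identical(map$stage[map$cluster == "C2"], "Recovery")

  tie <- dplyr::mutate(conv, aitchison_distance = 3)
  expect_error(label_stages(ca, convergence = tie), "tied")
})

test_that("stage identities recover planted regimes on synthetic data", {
  ok <- 0
  n_seeds <- 6
  for (s in seq_len(n_seeds)) {
    gen <- generate_chronosequence(seed = 200 + s)
    bc <- bray_curtis_matrix(relative_abundance(gen$table))
    ord <- pcoa_ordination(bc)
    ca <- consensus_cluster(bc, ord, k = 2, seed = s)
    conv <- convergence_to_reference(clr_transform(gen$table),
                                     gen$table$metadata)
    lab <- label_stages(ca, convergence = conv)
    joined <- dplyr::inner_join(tibble::as_tibble(lab), gen$truth$stages,
                                by = "sample_id") |>
      dplyr::filter(core_stage != "Ambiguous")
    agree <- mean((joined$core_stage == "Recovery") ==
                    (joined$stage == "recovery"))
    if (agree >= 0.9) ok <- ok + 1
  }
  expect_gte(ok, n_seeds - 1)
})

test_that("core-stage labels track planted regimes (ARI)", {
  aris <- vapply(1:10, function(s) {
    gen <- generate_chronosequence(seed = 300 + s)
    bc <- bray_curtis_matrix(relative_abundance(gen$table))
    ca <- consensus_cluster(bc, pcoa_ordination(bc), k = 2, seed = s)
    core <- ca$core_stage != "Ambiguous"
    truth <- gen$truth$stages$stage[match(ca$sample_id,
                                          gen$truth$stages$sample_id)]
    ari(ca$core_stage[core], truth[core])
  }, numeric(1))
  expect_gte(mean(aris >= 0.8), 0.9)
})

test_that("stage composition counts per group and sums to one", {
  ca <- tibble::tibble(
    sample_id = paste0("s", 1:5),
    hier_label = 1, kmeans_label = 1,
    core_stage = c("Chaos", "Chaos", "Chaos", "Recovery", "Recovery"))
  md <- data.frame(sample_id = paste0("s", 1:5), group = "4y")
  comp <- stage_composition(ca, md)
  expect_equal(comp$proportion[comp$stage == "Chaos"], 0.6)
  expect_equal(comp$proportion[comp$stage == "Recovery"], 0.4)
  expect_equal(comp$proportion[comp$stage == "Ambiguous"], 0)
  expect_equal(sum(comp$proportion), 1)
})
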