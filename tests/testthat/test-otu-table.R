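test_that("OTU tables round-trip through TSV files", {
  tab <- toy_table()
  ab <- withr::local_tempfile(fileext = ".tsv")
  md <- withr::local_tempfile(fileext = ".tsv")
  write_otu_table(tab, ab, md)
  back <- read_otu_table(ab, md)
  expect_identical(unname(back$counts), unname(tab$counts))
  expect_identical(rownames(back$counts), rownames(tab$counts))
  expect_identical(colnames(back$counts), colnames(tab$counts))
  expect_identical(back$taxonomy$phylum, tab$taxonomy$phylum)
  expect_identical(back$metadata$group, tab$metadata$group)
})

test_that("validation names the offending identifier", {
  counts <- matrix(1, 2, 2, dimnames = list(c("s1", "s2"), c("oX", "oX")))
  expect_error(
    otu_table(counts,
              taxonomy = data.frame(otu_id = "oX", phylum = "P"),
              metadata = data.frame(sample_id = c("s1", "s2"),
                                    group = "SD", replicate = 1:2,
                                    kingdom = "bacteria")),
    "oX")
  tab <- toy_table()
  expect_error(
    otu_table(tab$counts, tab$taxonomy, tab$metadata[-2, ]),
    "s2")
  bad <- tab$counts
  bad[1, 1] <- -3
  expect_error(otu_table(bad, tab$taxonomy, tab$metadata), "s1")
})

test_that("relative abundance closes samples to unit sum", {
  tab <- toy_table(matrix(c(2, 3, 5), 1,
                          dimnames = list("s1", paste0("o", 1:3))))
  expect_equal(unname(relative_abundance(tab)$values[1, ]),
               c(0.2, 0.3, 0.5))
  eq <- toy_table(matrix(7, 2, 4, dimnames = list(paste0("s", 1:2),
                                                  paste0("o", 1:4))))
  expect_true(all(relative_abundance(eq)$values == 1 / 4))
  zero <- toy_table(matrix(c(1, 1, 0, 0), 2, byrow = TRUE,
                           dimnames = list(paste0("s", 1:2),
                                           paste0("o", 1:2))))
  expect_error(relative_abundance(zero), "s2")
})

test_that("CLR transform matches its definition and identities", {
  tab <- toy_table(matrix(1, 1, 4, dimnames = list("s1", paste0("o", 1:4))))
  expect_equal(unname(clr_transform(tab, 1)$values[1, ]), rep(0, 4))

  # geometric progression, pseudocount -> 0 limit: clr = ln3 * (-1.5..1.5)
  gp <- toy_table(matrix(c(1, 3, 9, 27), 1,
                         dimnames = list("s1", paste0("o", 1:4))))
  got <- clr_transform(gp, 1e-10)$values[1, ]
  expect_equal(unname(got), log(3) * c(-1.5, -0.5, 0.5, 1.5),
               tolerance = 1e-6)

  set.seed(42)
  rnd <- toy_table(matrix(rpois(40, 20) + 1, 4, 10,
                          dimnames = list(paste0("s", 1:4),
                                          paste0("o", 1:10))))
  expect_lt(max(abs(rowSums(clr_transform(rnd, 0.5)$values))), 1e-9)

  # scale invariance: multiplying counts and pseudocount by a constant
  # shifts logs uniformly, leaving the centered values unchanged
  scaled <- rnd
  scaled$counts <- scaled$counts * 10
  expect_equal(clr_transform(scaled, 5)$values,
               clr_transform(rnd, 0.5)$values, tolerance = 1e-9)
  expect_error(clr_transform(rnd, 0), "positive")
})

test_that("core-OTU filter applies strict dual thresholds", {
  # 5 samples, 4 OTUs: o1 passes both; o2 fails prevalence (exactly 50%
  # impossible with 5 samples, so use 2/5); o3 fails abundance; o4 passes
  counts <- matrix(
    c(100, 0, 1, 50,
      100, 0, 0, 50,
      100, 5, 0, 50,
      100, 5, 1, 0,
      100, 0, 0, 50),
    nrow = 5, byrow = TRUE,
    dimnames = list(paste0("s", 1:5), paste0("o", 1:4))
  )
  tab <- toy_table(counts, groups = rep("SD", 5))
  kept <- filter_core_otus(tab, prevalence_min = 0.5,
                           mean_relabund_min = 1e-4)
  expect_identical(colnames(kept$counts), c("o1", "o4"))
  expect_identical(rownames(kept$counts), rownames(counts))

  # boundary: prevalence exactly at the threshold is excluded
  counts2 <- matrix(c(10, 10, 0, 0,
                      10, 10, 10, 10), 4, 2,
                    dimnames = list(paste0("s", 1:4), c("oA", "oB")))
  tab2 <- toy_table(counts2, groups = rep("SD", 4))
  kept2 <- filter_core_otus(tab2, prevalence_min = 0.5,
                            mean_relabund_min = 1e-4)
  expect_identical(colnames(kept2$counts), "oB")

  # idempotence
  again <- filter_core_otus(kept, prevalence_min = 0.5,
                            mean_relabund_min = 1e-4)
  expect_identical(again$counts, kept$counts)
  expect_error(filter_core_otus(tab, prevalence_min = 1.2), "\\[0, 1\\]")
})

test_that("phylum aggregation conserves abundance and lumps minor phyla", {
  counts <- matrix(
    c(60, 10, 25, 5,
      55, 15, 25, 5),
    nrow = 2, byrow = TRUE,
    dimnames = list(paste0("s", 1:2), paste0("o", 1:4))
  )
  tab <- toy_table(counts, phyla = c("Alpha", "Alpha", "Beta", "Gamma"))
  prof <- aggregate_phylum(tab, others_threshold = 0.10)
  # same-phylum OTUs add: Alpha in s1 = 0.60 + 0.10
  expect_equal(prof$relative_abundance[prof$sample_id == "s1" &
                                         prof$phylum == "Alpha"], 0.70)
  # Gamma grand mean 0.05 < 0.10 -> lumped
  expect_setequal(unique(prof$phylum), c("Alpha", "Beta", "Others"))
  sums <- tapply(prof$relative_abundance, prof$sample_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})
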