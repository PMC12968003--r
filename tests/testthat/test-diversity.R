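test_that("alpha metrics match their closed forms", {
  eq <- toy_table(matrix(5, 1, 4, dimnames = list("s1", paste0("o", 1:4))))
  a <- alpha_metrics(eq)
  expect_equal(a$shannon, log(4))
  expect_equal(a$simpson, 0.75)
  expect_equal(a$observed_otus, 4L)
  # no singletons or doubletons -> chao1 = observed
  expect_equal(a$chao1, 4)

  # S_obs = 10, F1 = 4, F2 = 2 -> chao1 = 10 + 4*3/(2*3) = 12
  counts <- matrix(c(rep(1, 4), rep(2, 2), rep(5, 4)), 1,
                   dimnames = list("s1", paste0("o", 1:10)))
  a2 <- alpha_metrics(toy_table(counts, groups = "SD"))
  expect_equal(a2$observed_otus, 10L)
  expect_equal(a2$chao1, 12)

  # column-permutation invariance
  set.seed(9)
  m <- matrix(rpois(60, 3), 3, 20,
              dimnames = list(paste0("s", 1:3), paste0("o", 1:20)))
  m[1, 1] <- 1  # ensure positive totals
  perm <- sample(ncol(m))
  a_orig <- alpha_metrics(toy_table(m))
  a_perm <- alpha_metrics(toy_table(m[, perm]))
  expect_equal(a_orig, a_perm)
})

test_that("group comparison separates and degenerates correctly", {
  df <- data.frame(v = c(1, 2, 3, 11, 12, 13),
                   g = rep(c("lo", "hi"), each = 3))
  gt <- compare_groups(df, v, g)
  expect_lt(gt$pairwise$q[1], 0.05)
  expect_false(gt$letters$letters[1] == gt$letters$letters[2])
  expect_true(all(gt$pairwise$q >= gt$pairwise$p))

  const <- data.frame(v = rep(7, 8), g = rep(c("a", "b"), 4))
  gt0 <- compare_groups(const, v, g)
  expect_equal(gt0$omnibus$statistic, 0)
  expect_equal(gt0$omnibus$p, 1)
  expect_identical(gt0$letters$letters[1], gt0$letters$letters[2])

  expect_error(compare_groups(data.frame(v = 1:4, g = "one"), v, g),
               "two groups")
})

test_that("Kruskal-Wallis type-I error is nominal under the null", {
  set.seed(123)
  rej <- mean(replicate(1000, {
    v <- rnorm(24)
    g <- sample(rep(letters[1:3], 8))
    stats::kruskal.test(v, factor(g))$p.value < 0.05
  }))
  expect_lt(abs(rej - 0.05), 0.02)
})

test_that("Bray-Curtis matches hand values and vegan", {
  m <- rbind(s1 = c(0.4, 0.2, 0.4), s2 = c(0.2, 0.2, 0.6),
             s3 = c(1, 0, 0), s4 = c(0, 1, 0))
  colnames(m) <- paste0("o", 1:3)
  comp <- chronet:::composition_matrix(m, "relative")
  bc <- bray_curtis_matrix(comp)
  expect_equal(unname(diag(bc)), rep(0, 4))
  expect_equal(bc["s1", "s2"], 0.2)
  expect_equal(bc["s3", "s4"], 1)
  expect_equal(bc, t(bc))
  expect_true(all(bc >= 0 & bc <= 1))

  skip_if_not_installed("vegan")
  set.seed(4)
  r <- matrix(runif(40), 4, 10)
  r <- r / rowSums(r)
  rownames(r) <- paste0("s", 1:4)
  colnames(r) <- paste0("o", 1:10)
  ours <- bray_curtis_matrix(chronet:::composition_matrix(r, "relative"))
  ref <- as.matrix(vegan::vegdist(r, method = "bray"))
  expect_equal(unname(ours), unname(ref), tolerance = 1e-12)
})

test_that("PCoA recovers Euclidean configurations", {
  pts <- matrix(c(0, 1, 2), dimnames = list(paste0("s", 1:3), NULL))
  d <- as.matrix(dist(pts))
  ord <- pcoa_ordination(d)
  expect_equal(ord$proportion_explained[1], 1)
  expect_equal(as.matrix(dist(ord$coordinates[, 1])), d,
               tolerance = 1e-9)

  z <- matrix(0, 3, 3, dimnames = list(paste0("s", 1:3), paste0("s", 1:3)))
  ordz <- pcoa_ordination(z)
  expect_true(all(abs(ordz$coordinates) < 1e-9))

  set.seed(5)
  x <- matrix(rnorm(24), 8, 3)
  rownames(x) <- paste0("s", 1:8)
  de <- as.matrix(dist(x))
  orde <- pcoa_ordination(de)
  expect_equal(as.matrix(dist(orde$coordinates)), de, tolerance = 1e-8)
  expect_true(all(diff(orde$eigenvalues) <= 1e-8))

  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(pcoa_ordination(bad), "symmetric")
})

test_that("PERMANOVA detects separation and matches vegan's F", {
  set.seed(6)
  x <- rbind(matrix(rnorm(20, 0), 10, 2), matrix(rnorm(20, 8), 10, 2))
  rownames(x) <- paste0("s", 1:20)
  d <- as.matrix(dist(x))
  g <- rep(c("a", "b"), each = 10)
  res <- permanova(d, g, n_perm = 999, seed = 3)
  expect_equal(res$p, 0.001)

  skip_if_not_installed("vegan")
  ref <- vegan::adonis2(as.dist(d) ~ g, permutations = 99)
  expect_equal(res$statistic, ref$F[1], tolerance = 1e-10)
  expect_equal(res$r2, ref$R2[1], tolerance = 1e-10)

  # identical samples -> 0/0
  dz <- matrix(0, 6, 6, dimnames = list(paste0("s", 1:6), paste0("s", 1:6)))
  expect_warning(rz <- permanova(dz, rep(c("a", "b"), 3), n_perm = 19),
                 "undefined")
  expect_true(is.nan(rz$statistic))
})

test_that("permutation p-values are seed-reproducible and bounded", {
  set.seed(8)
  x <- matrix(rnorm(30), 15, 2)
  rownames(x) <- paste0("s", 1:15)
  d <- as.matrix(dist(x))
  g <- rep(c("a", "b", "c"), 5)
  p1 <- permanova(d, g, n_perm = 199, seed = 42)
  p2 <- permanova(d, g, n_perm = 199, seed = 42)
  expect_identical(p1, p2)
  expect_gte(p1$p, 1 / 200)
  a1 <- anosim(d, g, n_perm = 199, seed = 42)
  a2 <- anosim(d, g, n_perm = 199, seed = 42)
  expect_identical(a1, a2)
})

test_that("ANOSIM hits its boundary values and matches vegan", {
  # perfect separation: all between-distances exceed all within-distances
  x <- c(0, 0.1, 0.2, 10, 10.1, 10.2)
  d <- as.matrix(dist(x))
  rownames(d) <- colnames(d) <- paste0("s", 1:6)
  g <- rep(c("a", "b"), each = 3)
  res <- anosim(d, g, n_perm = 99, seed = 1)
  expect_equal(res$statistic, 1)

  # all distances equal -> all ranks tied -> R = 0
  deq <- matrix(1, 6, 6, dimnames = list(paste0("s", 1:6),
                                         paste0("s", 1:6)))
  diag(deq) <- 0
  expect_equal(anosim(deq, g, n_perm = 19, seed = 1)$statistic, 0)

  skip_if_not_installed("vegan")
  set.seed(10)
  y <- matrix(rnorm(36), 12, 3)
  rownames(y) <- paste0("s", 1:12)
  dy <- as.matrix(dist(y))
  gy <- rep(c("a", "b", "c"), each = 4)
  ref <- vegan::anosim(as.dist(dy), factor(gy), permutations = 9)
  expect_equal(anosim(dy, gy, n_perm = 9, seed = 1)$statistic,
               unname(ref$statistic), tolerance = 1e-10)
})

test_that("ANOSIM R is centered under the null", {
  set.seed(77)
  x <- matrix(rnorm(40), 20, 2)
  rownames(x) <- paste0("s", 1:20)
  d <- as.matrix(dist(x))
  rs <- replicate(200, {
    g <- sample(rep(c("a", "b"), 10))
    anosim(d, g, n_perm = 1, seed = 1)$statistic
  })
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("convergence to the reference centroid is Euclidean in CLR space", {
  m <- rbind(ref = c(1, -1, 0), probe = c(1, -1, 0) + c(1, 0, 0))
  colnames(m) <- paste0("o", 1:3)
  clr <- chronet:::composition_matrix(m, "clr")
  md <- data.frame(sample_id = c("ref", "probe"), group = c("ND", "SD"))
  conv <- convergence_to_reference(clr, md, "ND")
  expect_equal(conv$aitchison_distance[conv$sample_id == "ref"], 0)
  expect_equal(conv$aitchison_distance[conv$sample_id == "probe"], 1)
  expect_error(convergence_to_reference(clr, md, "XX"), "XX")
})

test_that("late groups converge toward the reference on synthetic data", {
  gen <- generate_chronosequence(seed = 13)
  clr <- clr_transform(gen$table)
  conv <- convergence_to_reference(clr, gen$table$metadata, "ND")
  by_group <- tapply(conv$aitchison_distance, conv$group, mean)
  early <- mean(by_group[c("SD", "1y", "4y")])
  late <- mean(by_group[c("14y", "16y", "18y")])
  expect_lt(late, early)
})
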