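#' Per-sample alpha diversity
#'
#' Computes observed OTU richness, the Chao1 richness estimator, Shannon
#' entropy (natural log) and the Gini-Simpson index \eqn{1 - \sum p_i^2}
#' from raw counts.
#'
#' @param x An [otu_table].
#' @param chao1 `"bias_corrected"` (default), the variant
#'   \eqn{S_{obs} + F_1(F_1-1)/(2(F_2+1))} which is defined even without
#'   doubletons, or `"classic"` \eqn{S_{obs} + F_1^2/(2F_2)} (falls back
#'   to the bias-corrected form when \eqn{F_2 = 0}).
#' @return A tibble with columns `sample_id`, `observed_otus`, `chao1`,
#'   `shannon`, `simpson`.
#' @export
alpha_metrics <- function(x, chao1 = c("bias_corrected", "classic")) {
  stopifnot(inherits(x, "otu_table"))
  chao1 <- match.arg(chao1)
  counts <- x$counts
  totals <- rowSums(counts)
  if (any(totals <= 0)) {
    stop("Sample(s) with zero total count: ",
         paste(rownames(counts)[totals <= 0], collapse = ", "), ".",
         call. = FALSE)
  }
  purrr::map_dfr(seq_len(nrow(counts)), function(i) {
    ct <- counts[i, ]
    p <- ct / sum(ct)
    p <- p[p > 0]
    s_obs <- sum(ct > 0)
    f1 <- sum(ct == 1)
    f2 <- sum(ct == 2)
    chao <- if (chao1 == "classic" && f2 > 0) {
      s_obs + f1^2 / (2 * f2)
    } else {
      s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
    }
    tibble::tibble(sample_id = rownames(counts)[i],
                   observed_otus = s_obs,
                   chao1 = chao,
                   shannon = -sum(p * log(p)),
                   simpson = 1 - sum(p^2))
  })
}

#' Kruskal-Wallis group comparison with Dunn's post hoc test
#'
#' Omnibus Kruskal-Wallis test (with tie correction) followed by all
#' pairwise Dunn Z tests, Benjamini-Hochberg adjustment, and a compact
#' letter display in which groups sharing a letter are not separated at
#' `alpha` on the adjusted p-values.
#'
#' @param data A data frame.
#' @param value,group Column names (unquoted) holding the response and the
#'   group labels.
#' @param alpha Significance level for the letter display (default 0.05).
#' @return A `group_test` object: list with tibbles `omnibus`
#'   (`statistic`, `df`, `p`), `pairwise` (`group1`, `group2`,
#'   `statistic`, `p`, `q`) and `letters` (`group`, `mean_rank`,
#'   `letters`).
#' @export
compare_groups <- function(data, value, group, alpha = 0.05) {
  value <- rlang::eval_tidy(rlang::enquo(value), data)
  group <- as.character(rlang::eval_tidy(rlang::enquo(group), data))
  keep <- !is.na(value) & !is.na(group)
  value <- value[keep]
  group <- group[keep]
  glev <- unique(group)
  if (length(glev) < 2) stop("Need at least two groups.", call. = FALSE)
  kw <- if (length(unique(value)) == 1L) {
    # all observations tied: no rank variation, H = 0 by convention
    list(statistic = c(H = 0), parameter = c(df = length(glev) - 1),
         p.value = 1)
  } else {
    stats::kruskal.test(value, factor(group))
  }
  n <- length(value)
  r <- rank(value)
  mean_rank <- tapply(r, group, mean)[glev]
  n_g <- tapply(r, group, length)[glev]
  ties <- table(value)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  pairs <- utils::combn(glev, 2)
  pw <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    g1 <- pairs[1, k]; g2 <- pairs[2, k]
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / n_g[g1] + 1 / n_g[g2]))
    z <- if (se > 0) (mean_rank[g1] - mean_rank[g2]) / se else 0
    tibble::tibble(group1 = g1, group2 = g2, statistic = unname(z),
                   p = 2 * stats::pnorm(-abs(z)))
  })
  pw$q <- stats::p.adjust(pw$p, method = "BH")
  letters_tb <- compact_letters(glev, pw, alpha) |>
    dplyr::mutate(mean_rank = as.numeric(mean_rank[.data$group]),
                  .after = "group") |>
    dplyr::arrange(dplyr::desc(.data$mean_rank))
  structure(list(
    omnibus = tibble::tibble(statistic = unname(kw$statistic),
                             df = unname(kw$parameter), p = kw$p.value),
    pairwise = pw,
    letters = letters_tb,
    alpha = alpha
  ), class = "group_test")
}

# letters from maximal cliques of the non-separation graph: sharing a
# letter implies q >= alpha, and every non-separated pair shares one
compact_letters <- function(groups, pairwise, alpha) {
  ns <- dplyr::filter(pairwise, .data$q >= alpha)
  g <- igraph::graph_from_data_frame(
    ns[, c("group1", "group2")], directed = FALSE,
    vertices = data.frame(name = groups))
  cliques <- igraph::max_cliques(g)
  cliques <- cliques[order(-lengths(cliques),
                           vapply(cliques, function(cl)
                             min(match(names(cl), groups)), 1))]
  lab <- stats::setNames(rep("", length(groups)), groups)
  for (k in seq_along(cliques)) {
    members <- names(cliques[[k]])
    lab[members] <- paste0(lab[members], letters[(k - 1) %% 26 + 1])
  }
  tibble::tibble(group = groups, letters = unname(lab[groups]))
}

#' @export
print.group_test <- function(x, ...) {
  cat("Kruskal-Wallis: H =", signif(x$omnibus$statistic, 4),
      ", df =", x$omnibus$df, ", p =", signif(x$omnibus$p, 3), "\n")
  print(x$letters)
  invisible(x)
}

#' Bray-Curtis dissimilarity matrix
#'
#' \eqn{BC(x, y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)} between every
#' pair of samples.
#'
#' @param comp A `composition_matrix` of kind `"relative"` (see
#'   [relative_abundance()]).
#' @return A symmetric numeric matrix with zero diagonal and sample ids as
#'   dimnames.
#' @export
bray_curtis_matrix <- function(comp) {
  stopifnot(inherits(comp, "composition_matrix"))
  if (comp$kind != "relative") {
    stop("Bray-Curtis expects a relative-abundance composition.",
         call. = FALSE)
  }
  v <- comp$values
  num <- as.matrix(stats::dist(v, method = "manhattan"))
  rs <- rowSums(v)
  bc <- num / outer(rs, rs, "+")
  diag(bc) <- 0
  bc
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Eigendecomposition of the double-centered Gower matrix. Axes with
#' negative eigenvalues are dropped from the coordinates but their
#' eigenvalues are reported; `proportion_explained` is computed over the
#' positive eigenvalues only (no Lingoes/Cailliez correction).
#'
#' @param d A square symmetric dissimilarity matrix with zero diagonal.
#' @return A `pcoa_ordination` object: list with `coordinates`
#'   (samples-by-axes matrix, axes named `PCo1`, `PCo2`, ...),
#'   `eigenvalues` (all, decreasing) and `proportion_explained` (per
#'   retained axis).
#' @export
pcoa_ordination <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || any(abs(d - t(d)) > 1e-8)) {
    stop("Distance matrix must be square and symmetric.", call. = FALSE)
  }
  n <- nrow(d)
  # cmdscale warns when fewer than k eigenvalues are positive; negative
  # eigenvalues are expected for non-Euclidean dissimilarities and are
  # reported, not corrected
  sc <- suppressWarnings(
    stats::cmdscale(stats::as.dist(d), k = n - 1, eig = TRUE)
  )
  eig <- sc$eig
  pos <- which(eig > 1e-9 * max(abs(eig), 1))
  coords <- sc$points[, seq_along(pos), drop = FALSE]
  if (length(pos) == 0) {
    coords <- matrix(0, n, 1, dimnames = list(rownames(d), "PCo1"))
    prop <- 1
  } else {
    colnames(coords) <- paste0("PCo", seq_along(pos))
    rownames(coords) <- rownames(d)
    prop <- eig[pos] / sum(eig[pos])
  }
  structure(list(coordinates = coords, eigenvalues = eig,
                 proportion_explained = prop),
            class = "pcoa_ordination")
}

#' @export
print.pcoa_ordination <- function(x, ...) {
  cat("<pcoa_ordination> ", nrow(x$coordinates), " samples, ",
      ncol(x$coordinates), " positive axes; PCo1 ",
      round(100 * x$proportion_explained[1], 1), "%\n", sep = "")
  invisible(x)
}

# indicator batching shared by permanova/anosim permutation loops:
# returns per-permutation sums of z' M z over groups, for M symmetric
perm_group_quadsums <- function(M, labels, perms) {
  glev <- unique(labels)
  n <- length(labels)
  res <- matrix(0, ncol(perms), length(glev))
  Z <- matrix(0, n, length(glev) * ncol(perms))
  for (b in seq_len(ncol(perms))) {
    lp <- labels[perms[, b]]
    for (gi in seq_along(glev)) {
      Z[lp == glev[gi], (b - 1) * length(glev) + gi] <- 1
    }
  }
  W <- M %*% Z
  qs <- colSums(Z * W)
  matrix(qs, ncol(perms), length(glev), byrow = TRUE)
}

#' Permutational multivariate analysis of variance (one factor)
#'
#' Pseudo-F from the distance-based partition of sums of squares
#' (\eqn{SS_{total} = \sum_{i<j} d_{ij}^2 / n}), with a permutation
#' p-value under the convention \eqn{p = (1 + \#\{F^* \ge F\})/(1 + B)}.
#'
#' @param d Square symmetric dissimilarity matrix.
#' @param groups Group labels, one per row of `d`.
#' @param n_perm Number of label permutations (default 999).
#' @param seed Integer seed for the permutations.
#' @return A tibble with columns `statistic` (pseudo-F), `df_between`,
#'   `df_within`, `r2`, `p`, `n_perm`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1) {
  d <- as.matrix(d)
  groups <- as.character(groups)
  stopifnot(nrow(d) == length(groups))
  glev <- unique(groups)
  a <- length(glev)
  if (a < 2) stop("Need at least two groups.", call. = FALSE)
  n <- nrow(d)
  n_g <- table(groups)[glev]
  if (any(n_g < 2)) {
    warning("Group(s) with a single sample: ",
            paste(names(n_g)[n_g < 2], collapse = ", "))
  }
  D2 <- d^2
  ss_total <- sum(D2) / (2 * n)
  ss_w_obs <- sum(vapply(glev, function(g) {
    z <- groups == g
    sum(D2[z, z]) / (2 * sum(z))
  }, numeric(1)))
  df_b <- a - 1
  df_w <- n - a
  f_from_ssw <- function(ssw) ((ss_total - ssw) / df_b) / (ssw / df_w)
  f_obs <- f_from_ssw(ss_w_obs)
  if (!is.finite(f_obs)) {
    warning("Degenerate distances: pseudo-F undefined (0/0).")
    return(tibble::tibble(statistic = NaN, df_between = df_b,
                          df_within = df_w, r2 = NaN, p = NaN,
                          n_perm = n_perm))
  }
  perms <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(b) sample.int(n), integer(n))
  })
  qs <- perm_group_quadsums(D2, groups, perms)
  ssw_perm <- qs %*% (1 / (2 * as.numeric(n_g)))
  f_perm <- f_from_ssw(ssw_perm)
  p <- (1 + sum(f_perm >= f_obs)) / (1 + n_perm)
  tibble::tibble(statistic = f_obs, df_between = df_b, df_within = df_w,
                 r2 = (ss_total - ss_w_obs) / ss_total, p = p,
                 n_perm = n_perm)
}

#' Analysis of similarities (ANOSIM)
#'
#' \eqn{R = (\bar r_{between} - \bar r_{within}) / (n(n-1)/4)} on the
#' ranks of all pairwise dissimilarities, with a permutation p-value under
#' the add-one convention.
#'
#' @inheritParams permanova
#' @return A tibble with columns `statistic` (R), `p`, `n_perm`.
#' @export
anosim <- function(d, groups, n_perm = 999, seed = 1) {
  d <- as.matrix(d)
  groups <- as.character(groups)
  stopifnot(nrow(d) == length(groups))
  if (length(unique(groups)) < 2) {
    stop("Need at least two groups.", call. = FALSE)
  }
  n <- nrow(d)
  ut <- upper.tri(d)
  rk <- matrix(0, n, n)
  rk[ut] <- rank(d[ut])
  rk <- rk + t(rk)
  n_pairs <- n * (n - 1) / 2
  total_rank <- n_pairs * (n_pairs + 1) / 2
  n_g <- table(groups)[unique(groups)]
  n_within <- sum(n_g * (n_g - 1) / 2)
  n_between <- n_pairs - n_within
  denom <- n * (n - 1) / 4
  r_stat <- function(within_sum) {
    ((total_rank - within_sum) / n_between - within_sum / n_within) / denom
  }
  within_obs <- sum(vapply(unique(groups), function(g) {
    z <- groups == g
    sum(rk[z, z]) / 2
  }, numeric(1)))
  r_obs <- r_stat(within_obs)
  perms <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(b) sample.int(n), integer(n))
  })
  qs <- perm_group_quadsums(rk, groups, perms)
  r_perm <- r_stat(rowSums(qs) / 2)
  p <- (1 + sum(r_perm >= r_obs)) / (1 + n_perm)
  tibble::tibble(statistic = r_obs, p = p, n_perm = n_perm)
}

#' Aitchison distance of each sample to a reference-group centroid
#'
#' Euclidean distance in CLR space from every sample to the arithmetic
#' centroid of the reference group's CLR rows; a declining trend along a
#' chronosequence indicates compositional convergence toward the
#' reference community.
#'
#' @param clr A `composition_matrix` of kind `"clr"` (see
#'   [clr_transform()]).
#' @param metadata A data frame with columns `sample_id` and `group`
#'   covering the rows of `clr`.
#' @param reference_group Label of the reference group (default `"ND"`).
#' @return A tibble with columns `sample_id`, `group`,
#'   `aitchison_distance`.
#' @export
convergence_to_reference <- function(clr, metadata,
                                     reference_group = "ND") {
  stopifnot(inherits(clr, "composition_matrix"))
  if (clr$kind != "clr") {
    stop("Convergence requires a CLR composition.", call. = FALSE)
  }
  v <- clr$values
  md <- metadata[match(rownames(v), metadata$sample_id), ]
  ref <- which(md$group == reference_group)
  if (!length(ref)) {
    stop("Reference group '", reference_group, "' not found.",
         call. = FALSE)
  }
  centroid <- colMeans(v[ref, , drop = FALSE])
  tibble::tibble(
    sample_id = rownames(v),
    group = md$group,
    aitchison_distance = unname(sqrt(rowSums(sweep(v, 2, centroid)^2)))
  )
}
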