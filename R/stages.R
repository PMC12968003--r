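#' Silhouette scan over candidate cluster numbers on two routes
#'
#' Scores k in `[k_min, k_max]` for (1) Ward-linkage hierarchical
#' clustering cut on the supplied dissimilarity matrix and (2) k-means on
#' the ordination coordinates, both by the mean silhouette width. The two
#' routes deliberately mirror each other so their agreement can be used as
#' a consensus criterion.
#'
#' @param d Square symmetric dissimilarity matrix.
#' @param ordination A `pcoa_ordination` of the same samples (see
#'   [pcoa_ordination()]).
#' @param k_min,k_max Range of cluster numbers to scan (defaults 2 and 6).
#' @param seed Integer seed for the k-means restarts.
#' @param restarts k-means restarts per k (best inertia kept; default 10).
#' @param axes Number of leading ordination axes fed to k-means; default
#'   all positive-eigenvalue axes.
#' @param sqrt_dist Apply a square-root transform to `d` before Ward
#'   linkage (metric safety for non-Euclidean dissimilarities).
#' @return A `silhouette_scan` object: list with `scan` (tibble `route`,
#'   `k`, `silhouette`) and `best_k` (tibble `route`, `best_k`).
#' @export
silhouette_scan <- function(d, ordination, k_min = 2, k_max = 6, seed = 1,
                            restarts = 10, axes = NULL,
                            sqrt_dist = FALSE) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (k_max >= n) stop("k_max must be smaller than the number of samples.",
                       call. = FALSE)
  coords <- ordination$coordinates
  if (!is.null(axes)) {
    coords <- coords[, seq_len(min(axes, ncol(coords))), drop = FALSE]
  }
  dh <- if (sqrt_dist) sqrt(d) else d
  hc <- stats::hclust(stats::as.dist(dh), method = "ward.D2")
  coord_d <- as.matrix(stats::dist(coords))
  scan <- withr::with_seed(seed, {
    purrr::map_dfr(seq(k_min, k_max), function(k) {
      hl <- stats::cutree(hc, k = k)
      km <- stats::kmeans(coords, centers = k, nstart = restarts)
      tibble::tibble(
        route = c("hierarchical", "kmeans"),
        k = k,
        silhouette = c(mean_silhouette(hl, d),
                       mean_silhouette(km$cluster, coord_d))
      )
    })
  })
  best <- scan |>
    dplyr::slice_max(.data$silhouette, n = 1, by = "route",
                     with_ties = FALSE) |>
    dplyr::transmute(route = .data$route, best_k = .data$k)
  structure(list(scan = scan, best_k = best), class = "silhouette_scan")
}

mean_silhouette <- function(labels, d) {
  sil <- cluster::silhouette(labels, dmatrix = d)
  mean(sil[, "sil_width"])
}

#' @export
print.silhouette_scan <- function(x, ...) {
  print(tidyr::pivot_wider(x$scan, names_from = "route",
                           values_from = "silhouette"))
  cat("best k: ",
      paste(x$best_k$route, x$best_k$best_k, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# align labels of `b` to labels of `a` (both 1..k) by maximum agreement
# over all k! relabelings
align_labels <- function(a, b, k) {
  perms <- permutations_of(k)
  tab <- table(factor(a, levels = seq_len(k)),
               factor(b, levels = seq_len(k)))
  agree <- apply(perms, 1, function(p) sum(tab[cbind(p, seq_len(k))]))
  best <- perms[which.max(agree), ]
  best[b]
}

permutations_of <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Consensus clustering of samples into core stages
#'
#' Runs Ward-linkage hierarchical clustering on the dissimilarity matrix
#' and k-means on the ordination coordinates, aligns the k-means labels to
#' the hierarchical labels by maximum-agreement matching, and assigns each
#' sample to a Core cluster only when the two routes agree; conflicting
#' samples are designated Ambiguous.
#'
#' @inheritParams silhouette_scan
#' @param k Number of clusters (k >= 2).
#' @return A `consensus_assignment` tibble with columns `sample_id`,
#'   `hier_label`, `kmeans_label` (aligned) and `core_stage` (the agreed
#'   cluster id as `"C1"`, `"C2"`, ... or `"Ambiguous"`), with attribute
#'   `k`.
#' @export
consensus_cluster <- function(d, ordination, k, seed = 1, restarts = 10,
                              axes = NULL, sqrt_dist = FALSE) {
  if (k < 2) stop("k must be at least 2.", call. = FALSE)
  d <- as.matrix(d)
  coords <- ordination$coordinates
  if (!is.null(axes)) {
    coords <- coords[, seq_len(min(axes, ncol(coords))), drop = FALSE]
  }
  dh <- if (sqrt_dist) sqrt(d) else d
  hl <- stats::cutree(stats::hclust(stats::as.dist(dh),
                                    method = "ward.D2"), k = k)
  km <- withr::with_seed(seed,
                         stats::kmeans(coords, centers = k,
                                       nstart = restarts))
  kl <- align_labels(hl, km$cluster, k)
  core <- ifelse(hl == kl, paste0("C", hl), "Ambiguous")
  out <- tibble::tibble(sample_id = rownames(d),
                        hier_label = unname(hl),
                        kmeans_label = unname(kl),
                        core_stage = core)
  attr(out, "k") <- k
  class(out) <- c("consensus_assignment", class(out))
  out
}

#' Assign ecological identities (Chaos / Recovery) to core clusters
#'
#' Two rules are available. The default `"convergence"` rule calls the
#' core cluster with the smaller mean Aitchison distance to the
#' non-degraded reference Recovery and the other Chaos. The `"topology"`
#' rule builds a co-occurrence network per core cluster and calls the
#' cluster with the higher Erdos-Renyi modularity Z-score Recovery — the
#' stage identities are then defined by network organization rather than
#' chronological age.
#'
#' @param assignment A `consensus_assignment` (see [consensus_cluster()]).
#' @param convergence Tibble from [convergence_to_reference()]
#'   (required for the `"convergence"` rule).
#' @param table The [otu_table] the assignment was computed from
#'   (required for the `"topology"` rule).
#' @param rule `"convergence"` (default) or `"topology"`.
#' @param n_random Null-ensemble size for the topology rule (default 100).
#' @param seed Seed for the topology rule's null models.
#' @param ... Passed to [filter_core_otus()] / [build_network()]
#'   thresholds for the topology rule (`prevalence_min`,
#'   `mean_relabund_min`, `rho_min`, `q_max`).
#' @return The assignment tibble with `core_stage` recoded to `"Chaos"`,
#'   `"Recovery"` or `"Ambiguous"`, plus a `stage_map` attribute recording
#'   the cluster-to-stage mapping and the criterion values.
#' @export
label_stages <- function(assignment, convergence = NULL, table = NULL,
                         rule = c("convergence", "topology"),
                         n_random = 100, seed = 1, ...) {
  rule <- match.arg(rule)
  clusters <- sort(setdiff(unique(assignment$core_stage), "Ambiguous"))
  if (length(clusters) != 2) {
    stop("Stage labeling requires exactly two core clusters; found ",
         length(clusters), ".", call. = FALSE)
  }
  crit <- if (rule == "convergence") {
    if (is.null(convergence)) {
      stop("The convergence rule needs a `convergence` table.",
           call. = FALSE)
    }
    vapply(clusters, function(cl) {
      ids <- assignment$sample_id[assignment$core_stage == cl]
      mean(convergence$aitchison_distance[convergence$sample_id %in% ids])
    }, numeric(1))
  } else {
    if (is.null(table)) {
      stop("The topology rule needs the source `table`.", call. = FALSE)
    }
    vapply(clusters, function(cl) {
      ids <- assignment$sample_id[assignment$core_stage == cl]
      sub <- subset_otu_table(table, samples = ids)
      net <- build_network(correlation_edges(filter_core_otus(sub, ...)),
                           ...)
      if (nrow(net$edges) == 0) return(-Inf)
      -modularity_zscore(net, n_random = n_random, seed = seed)$z
    }, numeric(1))
  }
  if (isTRUE(all.equal(unname(crit[1]), unname(crit[2])))) {
    stop("Stage-identity criterion is tied between the clusters; use the ",
         "alternative rule.", call. = FALSE)
  }
  # convergence rule: smaller distance -> Recovery; topology rule: crit is
  # the negated Z-score so the same ordering applies
  recovery <- clusters[which.min(crit)]
  map <- stats::setNames(ifelse(clusters == recovery, "Recovery", "Chaos"),
                         clusters)
  out <- dplyr::mutate(
    assignment,
    core_stage = dplyr::recode(.data$core_stage, !!!map)
  )
  attr(out, "k") <- attr(assignment, "k")
  attr(out, "stage_map") <-
    tibble::tibble(cluster = clusters, stage = unname(map[clusters]),
                   criterion = unname(crit), rule = rule)
  class(out) <- c("consensus_assignment", setdiff(class(out),
                                                  "consensus_assignment"))
  out
}

#' Per-group stage composition
#'
#' Fraction of each chronosequence group's samples assigned to each stage
#' category (including Ambiguous); the stage-composition profile of the
#' succession.
#'
#' @param assignment A `consensus_assignment`, typically after
#'   [label_stages()].
#' @param metadata Data frame with `sample_id` and `group`.
#' @return A tibble `group`, `stage`, `n`, `proportion`; proportions sum
#'   to 1 within each group.
#' @export
stage_composition <- function(assignment, metadata) {
  stages <- union(unique(assignment$core_stage), "Ambiguous")
  md <- metadata[, c("sample_id", "group")]
  dplyr::left_join(tibble::as_tibble(assignment), md, by = "sample_id") |>
    dplyr::count(.data$group, stage = factor(.data$core_stage,
                                             levels = stages)) |>
    tidyr::complete(.data$group, .data$stage, fill = list(n = 0L)) |>
    dplyr::mutate(proportion = .data$n / sum(.data$n), .by = "group") |>
    dplyr::mutate(stage = as.character(.data$stage))
}
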