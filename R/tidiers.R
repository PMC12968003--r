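#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy methods for chronet result objects
#'
#' `tidy()` returns the per-unit table of a result (pairwise tests,
#' coordinates, edges, memberships, per-fold AUCs, curve points);
#' `glance()` returns a one-row summary.
#'
#' @param x A chronet result object.
#' @param ... Unused.
#' @return A tibble.
#' @name chronet-tidiers
NULL

#' @rdname chronet-tidiers
#' @export
tidy.group_test <- function(x, ...) x$pairwise

#' @rdname chronet-tidiers
#' @export
glance.group_test <- function(x, ...) x$omnibus

#' @rdname chronet-tidiers
#' @export
tidy.pcoa_ordination <- function(x, ...) {
  tibble::as_tibble(x$coordinates, rownames = "sample_id")
}

#' @rdname chronet-tidiers
#' @export
glance.pcoa_ordination <- function(x, ...) {
  tibble::tibble(n_axes = ncol(x$coordinates),
                 prop_axis1 = x$proportion_explained[1],
                 prop_axis2 = if (length(x$proportion_explained) > 1) {
                   x$proportion_explained[2]
                 } else NA_real_,
                 n_negative_eigenvalues = sum(x$eigenvalues < 0))
}

#' @rdname chronet-tidiers
#' @export
tidy.cooccurrence_network <- function(x, ...) x$edges

#' @rdname chronet-tidiers
#' @export
glance.cooccurrence_network <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(n_nodes = nrow(x$nodes)),
                   edge_sign_summary(x))
}

#' @rdname chronet-tidiers
#' @export
tidy.module_partition <- function(x, ...) {
  tibble::tibble(otu_id = names(x$membership),
                 module = unname(x$membership))
}

#' @rdname chronet-tidiers
#' @export
glance.module_partition <- function(x, ...) {
  tibble::tibble(modularity = x$modularity, n_modules = x$n_modules,
                 avg_module_size = round(x$avg_module_size, 2))
}

#' @rdname chronet-tidiers
#' @export
tidy.nullmodel_result <- function(x, ...) {
  tibble::tibble(replicate = seq_along(x$q_rand), q_rand = x$q_rand)
}

#' @rdname chronet-tidiers
#' @export
glance.nullmodel_result <- function(x, ...) {
  tibble::tibble(q_obs = x$q_obs, q_rand_mean = x$q_rand_mean,
                 q_rand_sd = x$q_rand_sd, z = x$z, n_random = x$n_random)
}

#' @rdname chronet-tidiers
#' @export
tidy.crossval_report <- function(x, ...) x$folds

#' @rdname chronet-tidiers
#' @export
glance.crossval_report <- function(x, ...) {
  cm <- x$confusion
  tibble::tibble(mean_auc = x$mean_auc, sd_auc = x$sd_auc,
                 n_core = x$n_core, accuracy = sum(diag(cm)) / sum(cm))
}

#' @rdname chronet-tidiers
#' @export
tidy.robustness_curve <- function(x, ...) {
  dplyr::mutate(x$points, strategy = x$strategy, .before = 1)
}

#' @rdname chronet-tidiers
#' @export
glance.robustness_curve <- function(x, ...) {
  tibble::tibble(strategy = x$strategy, auc = robustness_auc(x),
                 n_points = nrow(x$points))
}

#' @rdname chronet-tidiers
#' @export
tidy.silhouette_scan <- function(x, ...) x$scan

#' @rdname chronet-tidiers
#' @export
glance.silhouette_scan <- function(x, ...) {
  tidyr::pivot_wider(x$best_k, names_from = "route",
                     values_from = "best_k", names_prefix = "best_k_")
}
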