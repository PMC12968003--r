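#' Ordination scatter plot
#'
#' @param object A `pcoa_ordination`.
#' @param metadata Optional data frame with `sample_id` and a grouping
#'   column.
#' @param colour Name of the metadata column mapped to colour.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pcoa_ordination <- function(object, metadata = NULL,
                                     colour = "group", ...) {
  df <- tidy(object)
  lab <- function(i) {
    sprintf("PCo%d (%.1f%%)", i, 100 * object$proportion_explained[i])
  }
  p <- if (!is.null(metadata)) {
    ggplot2::ggplot(dplyr::left_join(df, metadata, by = "sample_id"),
                    ggplot2::aes(.data$PCo1, .data$PCo2,
                                 colour = .data[[colour]]))
  } else {
    ggplot2::ggplot(df, ggplot2::aes(.data$PCo1, .data$PCo2))
  }
  p + ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = lab(1), y = lab(2)) +
    ggplot2::theme_minimal()
}

#' Silhouette scan profile
#'
#' @param object A `silhouette_scan`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.silhouette_scan <- function(object, ...) {
  ggplot2::ggplot(object$scan,
                  ggplot2::aes(.data$k, .data$silhouette,
                               colour = .data$route)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = unique(object$scan$k)) +
    ggplot2::labs(x = "number of clusters k",
                  y = "mean silhouette width") +
    ggplot2::theme_minimal()
}

#' Robustness curves under node-removal strategies
#'
#' @param curves A named list of `robustness_curve` objects (or a single
#'   one).
#' @return A ggplot object.
#' @export
plot_robustness <- function(curves) {
  if (inherits(curves, "robustness_curve")) curves <- list(curves)
  df <- dplyr::bind_rows(lapply(curves, tidy.robustness_curve))
  ggplot2::ggplot(df, ggplot2::aes(.data$fraction_removed,
                                   .data$relative_lcc,
                                   colour = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "fraction of nodes removed",
                  y = "relative size of largest component") +
    ggplot2::theme_minimal()
}

#' @rdname plot_robustness
#' @param object A `robustness_curve`.
#' @param ... Unused.
#' @export
autoplot.robustness_curve <- function(object, ...) plot_robustness(object)

#' Zi-Pi role plane
#'
#' Scatter of within-module degree against participation coefficient with
#' the role-box thresholds (Zi = 2.5, Pi = 0.62) drawn in.
#'
#' @param roles A `node_role_table` from [zipi_roles()].
#' @return A ggplot object.
#' @export
plot_zipi <- function(roles) {
  ggplot2::ggplot(tibble::as_tibble(roles),
                  ggplot2::aes(.data$pi, .data$zi,
                               colour = .data$role)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = 2.5, linetype = 2) +
    ggplot2::geom_vline(xintercept = 0.62, linetype = 2) +
    ggplot2::labs(x = "participation coefficient (Pi)",
                  y = "within-module degree (Zi)") +
    ggplot2::theme_minimal()
}

#' Stacked stage-composition profile along the chronosequence
#'
#' @param composition Tibble from [stage_composition()].
#' @param group_order Optional character vector fixing the group order on
#'   the x axis.
#' @return A ggplot object.
#' @export
plot_stage_composition <- function(composition, group_order = NULL) {
  df <- composition
  if (!is.null(group_order)) {
    df$group <- factor(df$group, levels = group_order)
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$group, .data$proportion,
                                   fill = .data$stage)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "group", y = "proportion of samples") +
    ggplot2::theme_minimal()
}

#' Aitchison convergence toward the reference community
#'
#' @param convergence Tibble from [convergence_to_reference()].
#' @param group_order Optional group ordering.
#' @return A ggplot object.
#' @export
plot_convergence <- function(convergence, group_order = NULL) {
  df <- convergence
  if (!is.null(group_order)) {
    df$group <- factor(df$group, levels = group_order)
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$group,
                                   .data$aitchison_distance)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::labs(x = "group",
                  y = "Aitchison distance to reference centroid") +
    ggplot2::theme_minimal()
}

#' Phylum composition of keystone roles
#'
#' @param profile Tibble from [keystone_taxonomy_profile()].
#' @return A ggplot object.
#' @export
plot_keystone_taxonomy <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(.data$fraction, .data$role,
                                        fill = .data$phylum)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "fraction of OTUs", y = NULL) +
    ggplot2::theme_minimal()
}
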