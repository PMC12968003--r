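#' All-pairs Spearman correlations among core OTUs
#'
#' Computes Spearman's rank correlation (average-rank tie handling) for
#' every pair of OTUs, a two-sided p-value, and Benjamini-Hochberg
#' adjusted q-values across all tested pairs jointly. For very small
#' sample numbers (n <= 7) the p-value is an exact permutation tail
#' probability over all n! rank permutations; otherwise the t
#' approximation \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} is used. Pairs
#' involving a constant OTU (undefined rank correlation) are skipped with
#' a message.
#'
#' @param x An [otu_table] of the core OTUs of one stage.
#' @param on Correlate `"relative"` abundances (default) or raw
#'   `"counts"`; Spearman ranks make the distinction minor.
#' @return A tibble `otu_a`, `otu_b`, `rho`, `p`, `q`, carrying the OTU
#'   ids and taxonomy as attributes for [build_network()].
#' @export
correlation_edges <- function(x, on = c("relative", "counts")) {
  stopifnot(inherits(x, "otu_table"))
  on <- match.arg(on)
  v <- if (on == "relative") relative_abundance(x)$values else x$counts
  n <- nrow(v)
  if (n < 4) stop("Need at least 4 samples for rank correlations.",
                  call. = FALSE)
  keep <- apply(v, 2, function(col) stats::sd(col) > 0)
  if (any(!keep)) {
    message(sum(!keep), " constant OTU(s) skipped: ",
            paste(utils::head(colnames(v)[!keep], 5), collapse = ", "))
  }
  vk <- v[, keep, drop = FALSE]
  ranks <- apply(vk, 2, rank)
  C <- suppressWarnings(stats::cor(ranks))
  ut <- which(upper.tri(C), arr.ind = TRUE)
  rho <- C[upper.tri(C)]
  p <- if (n <= 7) {
    exact_spearman_p(ranks, ut, rho)
  } else {
    tt <- abs(rho) * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
    pmin(1, 2 * stats::pt(-tt, df = n - 2))
  }
  out <- tibble::tibble(
    otu_a = colnames(vk)[ut[, 1]],
    otu_b = colnames(vk)[ut[, 2]],
    rho = rho,
    p = p,
    q = stats::p.adjust(p, method = "BH")
  )
  attr(out, "otu_ids") <- colnames(v)
  attr(out, "taxonomy") <- x$taxonomy
  out
}

# exact two-sided permutation p for Spearman rho at tiny n: enumerate all
# permutations of the second margin's ranks (tie pattern preserved)
exact_spearman_p <- function(ranks, ut, rho) {
  n <- nrow(ranks)
  perms <- as.matrix(expand_permutations(n))
  vapply(seq_len(nrow(ut)), function(k) {
    xr <- ranks[, ut[k, 1]]
    yr <- ranks[, ut[k, 2]]
    rho_null <- suppressWarnings(
      stats::cor(xr, matrix(yr[t(perms)], nrow = n))
    )
    mean(abs(rho_null) >= abs(rho[k]) - 1e-12)
  }, numeric(1))
}

expand_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- expand_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

new_cooccurrence_network <- function(nodes, edges, rho_min, q_max) {
  structure(list(nodes = nodes, edges = edges,
                 rho_min = rho_min, q_max = q_max),
            class = "cooccurrence_network")
}

#' Assemble a signed co-occurrence network from a correlation table
#'
#' An edge is a pair with `|rho| > rho_min` and `q < q_max` (both strict,
#' the conventional dual-threshold rule); its sign is the sign of the
#' correlation. By default the node set contains only edge-incident OTUs;
#' `include_isolated = TRUE` keeps every core OTU as a node.
#'
#' @param pairs Tibble from [correlation_edges()].
#' @param rho_min Absolute-correlation threshold (default 0.7).
#' @param q_max FDR threshold (default 0.01).
#' @param include_isolated Keep edge-free core OTUs as nodes?
#' @param taxonomy Optional taxonomy tibble (`otu_id`, `phylum`); taken
#'   from the `pairs` attributes when absent.
#' @return A `cooccurrence_network`: list with `nodes` (tibble `otu_id`,
#'   `phylum`, `degree`), `edges` (tibble `otu_a`, `otu_b`, `rho`, `q`,
#'   `sign`) and the thresholds used.
#' @export
build_network <- function(pairs, rho_min = 0.7, q_max = 0.01,
                          include_isolated = FALSE, taxonomy = NULL) {
  if (rho_min < 0 || rho_min > 1 || q_max < 0 || q_max > 1) {
    stop("Thresholds must lie in [0, 1].", call. = FALSE)
  }
  taxonomy <- taxonomy %||% attr(pairs, "taxonomy")
  edges <- pairs |>
    dplyr::filter(abs(.data$rho) > rho_min, .data$q < q_max) |>
    dplyr::mutate(sign = as.integer(sign(.data$rho))) |>
    dplyr::select("otu_a", "otu_b", "rho", "q", "sign")
  node_ids <- if (include_isolated) {
    attr(pairs, "otu_ids") %||% union(pairs$otu_a, pairs$otu_b)
  } else {
    union(edges$otu_a, edges$otu_b)
  }
  deg <- table(factor(c(edges$otu_a, edges$otu_b), levels = node_ids))
  nodes <- tibble::tibble(otu_id = node_ids,
                          degree = as.integer(deg[node_ids]))
  if (!is.null(taxonomy)) {
    nodes <- dplyr::left_join(nodes,
                              dplyr::select(taxonomy, "otu_id", "phylum"),
                              by = "otu_id") |>
      dplyr::relocate("phylum", .after = "otu_id")
  } else {
    nodes$phylum <- NA_character_
  }
  new_cooccurrence_network(nodes, edges, rho_min, q_max)
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  s <- edge_sign_summary(x)
  cat("<cooccurrence_network> ", nrow(x$nodes), " nodes, ",
      nrow(x$edges), " edges (", s$positive_edges, " +, ",
      s$negative_edges, " -)\n", sep = "")
  invisible(x)
}

#' Convert a co-occurrence network to an igraph object
#'
#' @param net A `cooccurrence_network`.
#' @return An undirected `igraph` graph with `rho`, `q` and `sign` edge
#'   attributes and `phylum` vertex attribute.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "cooccurrence_network"))
  igraph::graph_from_data_frame(
    net$edges, directed = FALSE,
    vertices = as.data.frame(net$nodes)
  )
}

#' Edge-sign summary of a network
#'
#' Counts positive and negative edges and the negative-edge share, the
#' quantity whose rise along succession signals a shift toward
#' competitive interactions.
#'
#' @param x A `cooccurrence_network`, or any data frame with a `sign`
#'   column (one row per edge).
#' @return A one-row tibble `positive_edges`, `negative_edges`,
#'   `total_edges`, `negative_proportion` (fraction) and
#'   `negative_percent` (percentage rounded to one decimal). An empty
#'   network yields `NaN` proportions.
#' @export
edge_sign_summary <- function(x) {
  edges <- if (inherits(x, "cooccurrence_network")) x$edges else
    tibble::as_tibble(x)
  stopifnot("sign" %in% names(edges))
  pos <- sum(edges$sign > 0)
  neg <- sum(edges$sign < 0)
  tot <- pos + neg
  prop <- if (tot > 0) neg / tot else NaN
  tibble::tibble(positive_edges = pos, negative_edges = neg,
                 total_edges = tot, negative_proportion = prop,
                 negative_percent = round(100 * prop, 1))
}

#' Write network tables to disk
#'
#' @param net A `cooccurrence_network`.
#' @param edges_path,nodes_path Output TSV paths.
#' @return `net`, invisibly.
#' @export
write_network <- function(net, edges_path, nodes_path) {
  readr::write_tsv(net$edges, edges_path)
  readr::write_tsv(net$nodes, nodes_path)
  invisible(net)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
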