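#' Louvain modular decomposition
#'
#' Runs Louvain community detection on the unweighted, unsigned skeleton
#' of the network (edge signs and correlation strengths are ignored for
#' module detection), keeps the best of `restarts` runs by Newman
#' modularity, and reports module statistics. Nodes without edges each
#' form their own module.
#'
#' @param net A `cooccurrence_network`.
#' @param seed Integer seed governing the restarts.
#' @param resolution Louvain resolution parameter (default 1).
#' @param restarts Number of restarts (default 10).
#' @return A `module_partition`: list with `membership` (named integer
#'   vector), `modularity` (Q of the reported partition), `n_modules` and
#'   `avg_module_size`.
#' @export
louvain_partition <- function(net, seed = 1, resolution = 1,
                              restarts = 10) {
  stopifnot(inherits(net, "cooccurrence_network"))
  g <- as_igraph(net)
  if (igraph::ecount(g) == 0) {
    membership <- stats::setNames(seq_len(igraph::vcount(g)),
                                  igraph::V(g)$name)
    return(new_module_partition(membership, 0))
  }
  gs <- g  # rho/q/sign edge attributes are not weights; detection is unweighted
  best <- withr::with_seed(seed, {
    runs <- lapply(seq_len(restarts), function(i) {
      cl <- igraph::cluster_louvain(gs, resolution = resolution)
      memb <- igraph::membership(cl)
      list(membership = memb,
           q = igraph::modularity(gs, memb))
    })
    runs[[which.max(vapply(runs, `[[`, numeric(1), "q"))]]
  })
  membership <- stats::setNames(as.integer(best$membership),
                                igraph::V(g)$name)
  new_module_partition(membership, best$q)
}

new_module_partition <- function(membership, q) {
  n_mod <- length(unique(membership))
  structure(list(membership = membership,
                 modularity = q,
                 n_modules = n_mod,
                 avg_module_size = length(membership) / n_mod),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat("<module_partition> ", length(x$membership), " nodes, ",
      x$n_modules, " modules (Q = ", signif(x$modularity, 4), ")\n",
      sep = "")
  invisible(x)
}

#' Module count and average module size
#'
#' `avg_module_size = n_nodes / n_modules`, rounded to two decimals as in
#' standard topology reports. Either pass a partition or the two counts
#' directly.
#'
#' @param partition A `module_partition`, or `NULL` when passing counts.
#' @param n_nodes,n_modules Counts, used when `partition` is `NULL`.
#' @return A one-row tibble `n_nodes`, `n_modules`, `avg_module_size`.
#' @export
module_size_stats <- function(partition = NULL, n_nodes = NULL,
                              n_modules = NULL) {
  if (!is.null(partition)) {
    stopifnot(inherits(partition, "module_partition"))
    n_nodes <- length(partition$membership)
    n_modules <- partition$n_modules
  }
  tibble::tibble(n_nodes = n_nodes, n_modules = n_modules,
                 avg_module_size = round(n_nodes / n_modules, 2))
}

#' Global network topology metrics
#'
#' Average degree (2M/N), mean local clustering coefficient (nodes of
#' degree < 2 contribute 0), average shortest-path length over connected
#' pairs only (the number of disconnected pairs is reported), and module
#' statistics from the supplied partition.
#'
#' @param net A `cooccurrence_network`.
#' @param partition Optional `module_partition`; computed with default
#'   settings when absent.
#' @return A one-row tibble `n_nodes`, `n_edges`, `avg_degree`,
#'   `avg_clustering_coefficient`, `avg_path_length`,
#'   `n_disconnected_pairs`, `modularity`, `n_modules`,
#'   `avg_module_size`.
#' @export
global_metrics <- function(net, partition = NULL) {
  stopifnot(inherits(net, "cooccurrence_network"))
  g <- as_igraph(net)
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  if (n == 0) {
    warning("Empty network: all metrics undefined.")
    return(tibble::tibble(n_nodes = 0L, n_edges = 0L, avg_degree = NaN,
                          avg_clustering_coefficient = NaN,
                          avg_path_length = NaN,
                          n_disconnected_pairs = NaN, modularity = NaN,
                          n_modules = NaN, avg_module_size = NaN))
  }
  partition <- partition %||% louvain_partition(net)
  cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  sp <- igraph::distances(g)
  ut <- sp[upper.tri(sp)]
  connected <- is.finite(ut)
  tibble::tibble(
    n_nodes = n,
    n_edges = m,
    avg_degree = 2 * m / n,
    avg_clustering_coefficient = mean(cc),
    avg_path_length = if (any(connected)) mean(ut[connected]) else NaN,
    n_disconnected_pairs = sum(!connected),
    modularity = partition$modularity,
    n_modules = partition$n_modules,
    avg_module_size = round(n / partition$n_modules, 2)
  )
}

#' Within-module degree (Zi) and participation coefficient (Pi)
#'
#' For each node, \eqn{Z_i = (\kappa_i - \bar\kappa_{m(i)}) /
#' \sigma_{\kappa_{m(i)}}} where \eqn{\kappa_i} is the number of edges
#' from node i into its own module (Zi = 0 when the module's within-degree
#' standard deviation is 0), and \eqn{P_i = 1 - \sum_s (k_{is}/k_i)^2}
#' over modules s (Pi = 0 for isolated nodes). Roles follow the standard
#' threshold boxes: Peripheral (Zi <= 2.5, Pi <= 0.62), Connector
#' (Zi <= 2.5, Pi > 0.62), Module Hub (Zi > 2.5, Pi <= 0.62), Network Hub
#' (Zi > 2.5, Pi > 0.62). Connectors, module hubs and network hubs are
#' collectively the keystone taxa.
#'
#' @param net A `cooccurrence_network`.
#' @param partition A `module_partition` covering all nodes.
#' @return A `node_role_table` tibble: `otu_id`, `phylum`, `module`,
#'   `degree`, `zi`, `pi`, `role`.
#' @export
zipi_roles <- function(net, partition) {
  stopifnot(inherits(net, "cooccurrence_network"),
            inherits(partition, "module_partition"))
  memb <- partition$membership
  nodes <- net$nodes$otu_id
  if (!all(nodes %in% names(memb))) {
    stop("Partition does not cover all network nodes.", call. = FALSE)
  }
  memb <- memb[nodes]
  edges <- net$edges
  # per-node counts of edges into each module
  k_to_module <- function(ids_self, ids_other) {
    tapply(memb[ids_other], list(ids_self, memb[ids_other]), length)
  }
  long <- tibble::tibble(
    self = c(edges$otu_a, edges$otu_b),
    other = c(edges$otu_b, edges$otu_a)
  ) |>
    dplyr::count(.data$self, module_other = memb[.data$other])
  degree <- stats::setNames(rep(0L, length(nodes)), nodes)
  dtot <- tapply(long$n, long$self, sum)
  degree[names(dtot)] <- as.integer(dtot)
  kappa <- stats::setNames(rep(0L, length(nodes)), nodes)
  own <- long[long$module_other == memb[long$self], ]
  kappa[own$self] <- as.integer(own$n)
  zi <- stats::setNames(rep(0, length(nodes)), nodes)
  for (mod in unique(memb)) {
    ids <- nodes[memb == mod]
    kv <- kappa[ids]
    s <- stats::sd(kv)
    if (length(ids) > 1 && isTRUE(s > 0)) {
      zi[ids] <- (kv - mean(kv)) / s
    }
  }
  pi_sq <- tapply((long$n)^2, long$self, sum)
  pi <- stats::setNames(rep(0, length(nodes)), nodes)
  has_deg <- names(pi_sq)
  pi[has_deg] <- 1 - pi_sq[has_deg] / degree[has_deg]^2
  role <- dplyr::case_when(
    zi > 2.5 & pi > 0.62 ~ "NetworkHub",
    zi > 2.5 ~ "ModuleHub",
    pi > 0.62 ~ "Connector",
    .default = "Peripheral"
  )
  out <- tibble::tibble(
    otu_id = nodes,
    phylum = net$nodes$phylum,
    module = unname(memb),
    degree = unname(degree),
    zi = unname(zi),
    pi = unname(pi),
    role = role
  )
  class(out) <- c("node_role_table", class(out))
  out
}

#' Classify a (Zi, Pi) pair into its ecological role
#'
#' @param zi,pi Numeric vectors (recycled).
#' @return Character vector of roles.
#' @export
classify_role <- function(zi, pi) {
  dplyr::case_when(
    zi > 2.5 & pi > 0.62 ~ "NetworkHub",
    zi > 2.5 ~ "ModuleHub",
    pi > 0.62 ~ "Connector",
    .default = "Peripheral"
  )
}

#' Erdos-Renyi null-model modularity Z-score
#'
#' Measures how far the observed modular organization departs from a
#' baseline of structureless connectivity: an ensemble of `n_random`
#' G(N, M) graphs (identical node and edge counts, exactly M distinct
#' edges, uniform) is partitioned with the same Louvain settings as the
#' observed network, and \eqn{Z = (Q_{obs} - \bar Q_{rand}) /
#' \sigma_{rand}}. A higher Z indicates stronger deterministic
#' topological constraints.
#'
#' @param net A `cooccurrence_network` with at least 2 nodes and 1 edge.
#' @param n_random Null-ensemble size (default 100).
#' @param seed Integer master seed; each null graph and its Louvain run
#'   get fresh randomness derived from it.
#' @param resolution,restarts Louvain settings, applied identically to
#'   the observed network and every null graph.
#' @param partition Optional precomputed `module_partition` of `net`.
#' @return A `nullmodel_result`: list with `q_obs`, `q_rand_mean`,
#'   `q_rand_sd`, `z`, `n_random`, `seed` and the full `q_rand` ensemble.
#' @export
modularity_zscore <- function(net, n_random = 100, seed = 1,
                              resolution = 1, restarts = 10,
                              partition = NULL) {
  stopifnot(inherits(net, "cooccurrence_network"))
  n <- nrow(net$nodes)
  m <- nrow(net$edges)
  if (n < 2 || m < 1) {
    stop("Null-model analysis needs at least 2 nodes and 1 edge.",
         call. = FALSE)
  }
  partition <- partition %||% louvain_partition(net, seed = seed,
                                                resolution = resolution,
                                                restarts = restarts)
  q_obs <- partition$modularity
  q_rand <- withr::with_seed(seed + 1L, {
    vapply(seq_len(n_random), function(i) {
      g <- igraph::sample_gnm(n, m)
      best <- -Inf
      for (r in seq_len(restarts)) {
        cl <- igraph::cluster_louvain(g, resolution = resolution)
        q <- igraph::modularity(g, igraph::membership(cl))
        if (q > best) best <- q
      }
      best
    }, numeric(1))
  })
  q_mean <- mean(q_rand)
  q_sd <- stats::sd(q_rand)
  z <- if (isTRUE(q_sd > 0)) (q_obs - q_mean) / q_sd else {
    warning("Null ensemble has zero modularity spread; Z reported as Inf.")
    Inf * sign(q_obs - q_mean + .Machine$double.eps)
  }
  structure(list(q_obs = q_obs, q_rand_mean = q_mean, q_rand_sd = q_sd,
                 z = z, n_random = n_random, seed = seed,
                 q_rand = q_rand),
            class = "nullmodel_result")
}

#' @export
print.nullmodel_result <- function(x, ...) {
  cat("Modularity Z-score: Q_obs =", signif(x$q_obs, 4),
      ", null", signif(x$q_rand_mean, 4), "+/-", signif(x$q_rand_sd, 4),
      "-> Z =", round(x$z, 2), "\n")
  invisible(x)
}

#' Phylum composition of keystone roles
#'
#' For each non-peripheral role (Connector, ModuleHub, NetworkHub),
#' the fraction of member OTUs per phylum.
#'
#' @param roles A `node_role_table` from [zipi_roles()].
#' @return A tibble `role`, `phylum`, `n`, `fraction`; fractions sum to 1
#'   within each role. When no keystone nodes exist the tibble is empty
#'   and a note is emitted.
#' @export
keystone_taxonomy_profile <- function(roles) {
  keystone <- dplyr::filter(tibble::as_tibble(roles),
                            .data$role != "Peripheral")
  if (nrow(keystone) == 0) {
    message("No keystone taxa (connectors or hubs) in this network.")
    return(tibble::tibble(role = character(), phylum = character(),
                          n = integer(), fraction = numeric()))
  }
  keystone |>
    dplyr::count(.data$role, .data$phylum) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n), .by = "role") |>
    dplyr::arrange(.data$role, dplyr::desc(.data$fraction))
}
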