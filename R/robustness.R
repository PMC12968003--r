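#' Node-removal robustness simulation
#'
#' Tracks the relative size of the largest connected component (LCC,
#' denominator = original node count) as nodes are progressively removed
#' under one of three strategies: `"random"` (fresh uniform removal order
#' per repetition, mean curve over `n_reps` with per-rep curves
#' retained), `"degree"` (descending initial degree, deterministic id
#' tie-break), or `"keystone"` (role-priority buckets NetworkHub >
#' ModuleHub > Connector > Peripheral, within-bucket descending initial
#' degree, id tie-break). Orders are static: they are fixed from the
#' intact network, not recomputed as it erodes (set `adaptive = TRUE`
#' for degree attack with recomputation).
#'
#' @param net A non-empty `cooccurrence_network`.
#' @param strategy `"random"`, `"degree"` or `"keystone"`.
#' @param roles A `node_role_table` (required for the keystone strategy;
#'   a planted-role table with columns `otu_id`, `role`, `degree` also
#'   works). With no keystone nodes present the bucket rule degrades to
#'   peripheral-by-degree order.
#' @param n_reps Repetitions for the random strategy (default 50).
#' @param seed Integer seed (random strategy).
#' @param adaptive Recompute degrees after every removal (degree attack
#'   only).
#' @return A `robustness_curve`: list with `strategy`, `points` (tibble
#'   `fraction_removed`, `relative_lcc`; the mean curve for random) and,
#'   for random, `reps` (per-rep curves, tibble with `rep` column).
#' @export
simulate_attack <- function(net, strategy = c("random", "degree",
                                              "keystone"),
                            roles = NULL, n_reps = 50, seed = 1,
                            adaptive = FALSE) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(net, "cooccurrence_network"))
  n <- nrow(net$nodes)
  if (n == 0) stop("Empty network.", call. = FALSE)
  g <- as_igraph(net)
  ids <- net$nodes$otu_id
  if (strategy == "random") {
    reps <- withr::with_seed(seed, {
      purrr::map_dfr(seq_len(n_reps), function(r) {
        ord <- sample(ids)
        cv <- lcc_curve(g, ord)
        dplyr::mutate(cv, rep = r)
      })
    })
    pts <- reps |>
      dplyr::summarise(relative_lcc = mean(.data$relative_lcc),
                       .by = "fraction_removed")
    return(structure(list(strategy = strategy, points = pts, reps = reps,
                          n_reps = n_reps, seed = seed),
                     class = "robustness_curve"))
  }
  deg0 <- table(factor(c(net$edges$otu_a, net$edges$otu_b), levels = ids))
  ord <- if (strategy == "degree") {
    if (adaptive) {
      adaptive_degree_order(g)
    } else {
      ids[order(-as.integer(deg0[ids]), ids)]
    }
  } else {
    if (is.null(roles)) {
      stop("Keystone attack requires a role table.", call. = FALSE)
    }
    rk <- c(NetworkHub = 1, ModuleHub = 2, Connector = 3, Peripheral = 4)
    rt <- tibble::as_tibble(roles)
    if (!"degree" %in% names(rt)) {
      rt$degree <- as.integer(deg0[rt$otu_id])
    }
    rt <- rt[match(ids, rt$otu_id), c("otu_id", "role", "degree")]
    if (anyNA(rt$role)) {
      stop("Role table does not cover all network nodes.", call. = FALSE)
    }
    ids[order(rk[rt$role], -rt$degree, ids)]
  }
  structure(list(strategy = strategy, points = lcc_curve(g, ord),
                 order = ord),
            class = "robustness_curve")
}

lcc_curve <- function(g, order) {
  n0 <- igraph::vcount(g)
  lcc <- numeric(length(order) + 1L)
  lcc[1L] <- max(igraph::components(g)$csize) / n0
  for (i in seq_along(order)) {
    g <- igraph::delete_vertices(g, order[i])
    lcc[i + 1L] <- if (igraph::vcount(g) == 0) 0 else
      max(igraph::components(g)$csize) / n0
  }
  tibble::tibble(fraction_removed = (0:length(order)) / n0,
                 relative_lcc = lcc)
}

adaptive_degree_order <- function(g) {
  ord <- character(0)
  while (igraph::vcount(g) > 0) {
    dg <- igraph::degree(g)
    nm <- igraph::V(g)$name
    pick <- nm[order(-dg, nm)][1L]
    ord <- c(ord, pick)
    g <- igraph::delete_vertices(g, pick)
  }
  ord
}

#' @export
print.robustness_curve <- function(x, ...) {
  cat("<robustness_curve> strategy=", x$strategy, ", ",
      nrow(x$points), " points\n", sep = "")
  invisible(x)
}

#' Collapse threshold of a robustness curve
#'
#' The fraction of removed nodes at which the (piecewise-linear
#' interpolation of the) relative LCC first falls to `level`. A curve
#' that never drops below `level` yields 1.0 with `crossed = FALSE`.
#'
#' @param curve A `robustness_curve`.
#' @param level Collapse level in (0, 1); default 0.5.
#' @return A one-row tibble `level`, `fraction_removed`, `crossed`.
#' @export
collapse_threshold <- function(curve, level = 0.5) {
  stopifnot(inherits(curve, "robustness_curve"))
  if (level <= 0 || level >= 1) {
    stop("`level` must lie strictly between 0 and 1.", call. = FALSE)
  }
  f <- curve$points$fraction_removed
  l <- curve$points$relative_lcc
  below <- which(l < level)
  if (!length(below)) {
    return(tibble::tibble(level = level, fraction_removed = 1,
                          crossed = FALSE))
  }
  i <- below[1L]
  thr <- if (i == 1L) {
    f[1L]
  } else {
    f[i - 1L] + (l[i - 1L] - level) / (l[i - 1L] - l[i]) * (f[i] - f[i - 1L])
  }
  tibble::tibble(level = level, fraction_removed = thr, crossed = TRUE)
}

#' Area under a robustness curve
#'
#' Trapezoidal area under the relative-LCC curve; a scalar summary of
#' robustness (1 is maximally robust).
#'
#' @param curve A `robustness_curve`.
#' @return A single number.
#' @export
robustness_auc <- function(curve) {
  f <- curve$points$fraction_removed
  l <- curve$points$relative_lcc
  sum(diff(f) * (utils::head(l, -1) + utils::tail(l, -1)) / 2)
}
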