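#' Parameterize one latent community regime
#'
#' A regime is the generator's unit of ground truth: a block-structured
#' latent correlation model (blocks = planted modules), a stated fraction
#' of negative within-module associations, optional planted keystone nodes
#' (module hubs, connectors, network hubs), observation noise, and a
#' centroid shift that places the regime's samples in composition space.
#'
#' @param n_modules Number of planted modules.
#' @param module_size_mean Members per module.
#' @param intra_module_corr Latent correlation between members of the same
#'   module, in (0, 1).
#' @param negative_edge_fraction Target fraction of within-module OTU pairs
#'   whose latent correlation is negated.
#' @param n_network_hubs,n_module_hubs,n_connectors Planted keystone
#'   counts. Module hubs are designated members with elevated loading;
#'   connectors and network hubs are extra nodes loading across 3 and 4
#'   modules respectively.
#' @param noise_sd Standard deviation of independent observation noise
#'   added to the latent signal (attenuates realized correlations by
#'   \eqn{1/(1+\sigma^2)}).
#' @param regime_centroid_shift Per-OTU log-abundance shift (standard
#'   deviation of the regime contrast) separating this regime's centroid
#'   from the other regime's.
#' @return A `regime_spec` list.
#' @export
regime_spec <- function(n_modules, module_size_mean, intra_module_corr,
                        negative_edge_fraction, n_network_hubs = 0,
                        n_module_hubs = 0, n_connectors = 0,
                        noise_sd = 0.5, regime_centroid_shift = 1.5) {
  stopifnot(intra_module_corr > 0, intra_module_corr < 1,
            negative_edge_fraction >= 0, negative_edge_fraction <= 1,
            noise_sd > 0, regime_centroid_shift > 0,
            n_module_hubs <= n_modules)
  structure(list(n_modules = n_modules,
                 module_size_mean = module_size_mean,
                 intra_module_corr = intra_module_corr,
                 negative_edge_fraction = negative_edge_fraction,
                 n_network_hubs = n_network_hubs,
                 n_module_hubs = n_module_hubs,
                 n_connectors = n_connectors,
                 noise_sd = noise_sd,
                 regime_centroid_shift = regime_centroid_shift),
            class = "regime_spec")
}

#' @rdname regime_spec
#' @details `chaos_regime()` and `recovery_regime()` are the default
#'   presets: a sparse, weakly correlated, hub-free regime versus a dense,
#'   strongly modular regime with planted keystones and a higher share of
#'   negative associations.
#' @export
chaos_regime <- function() {
  regime_spec(n_modules = 4, module_size_mean = 8,
              intra_module_corr = 0.85, negative_edge_fraction = 0.05,
              noise_sd = 0.35, regime_centroid_shift = 1.5)
}

#' @rdname regime_spec
#' @export
recovery_regime <- function() {
  regime_spec(n_modules = 6, module_size_mean = 8,
              intra_module_corr = 0.9, negative_edge_fraction = 0.3,
              n_network_hubs = 2, n_module_hubs = 4, n_connectors = 6,
              noise_sd = 0.2, regime_centroid_shift = 1.5)
}

# choose per-block counts of negative-sign members so the realized
# fraction of negative within-block pairs tracks the target
plan_block_signs <- function(sizes, target_frac) {
  neg_pairs <- 0
  tot_pairs <- 0
  m_per_block <- integer(length(sizes))
  for (b in seq_along(sizes)) {
    g <- sizes[b]
    pairs_b <- choose(g, 2)
    cand <- 0:floor(g / 2)
    # pick m minimizing deviation of the cumulative negative fraction
    frac_after <- (neg_pairs + cand * (g - cand)) / (tot_pairs + pairs_b)
    m <- cand[which.min(abs(frac_after - target_frac))]
    m_per_block[b] <- m
    neg_pairs <- neg_pairs + m * (g - m)
    tot_pairs <- tot_pairs + pairs_b
  }
  m_per_block
}

# loading matrix (n_otus x n_modules) for one regime plus role/membership
# bookkeeping; planted nodes occupy the leading OTU indices
regime_loadings <- function(spec, n_otus) {
  n_mod <- spec$n_modules
  g <- spec$module_size_mean
  r <- spec$intra_module_corr
  n_members <- n_mod * g
  n_extra <- spec$n_connectors + spec$n_network_hubs
  if (n_members + n_extra > n_otus) {
    stop("n_otus too small for the planted structure (needs ",
         n_members + n_extra, ").", call. = FALSE)
  }
  L <- matrix(0, n_otus, n_mod)
  module <- rep(NA_integer_, n_otus)
  role <- rep(NA_character_, n_otus)
  m_neg <- plan_block_signs(rep(g, n_mod), spec$negative_edge_fraction)
  idx <- 0L
  for (b in seq_len(n_mod)) {
    members <- idx + seq_len(g)
    signs <- rep(1, g)
    if (m_neg[b] > 0) signs[seq_len(m_neg[b])] <- -1
    signs <- sample(signs)
    load <- rep(sqrt(r), g)
    if (b <= spec$n_module_hubs) {
      hub <- sample.int(g, 1)
      load[hub] <- sqrt(min(0.97, r + 0.05))
      role[members[hub]] <- "ModuleHub"
    }
    L[members, b] <- signs * load
    module[members] <- b
    role[members][is.na(role[members])] <- "Peripheral"
    idx <- idx + g
  }
  if (spec$n_connectors > 0) {
    for (ci in seq_len(spec$n_connectors)) {
      idx <- idx + 1L
      mods <- ((ci - 1L) + 0:2) %% n_mod + 1L  # cyclic triple of modules
      L[idx, mods] <- sqrt(0.9 / 3)
      role[idx] <- "Connector"
    }
  }
  if (spec$n_network_hubs > 0) {
    for (hi in seq_len(spec$n_network_hubs)) {
      idx <- idx + 1L
      mods <- ((hi - 1L) * 2 + 0:3) %% n_mod + 1L
      L[idx, mods] <- sqrt(0.9 / 4)
      role[idx] <- "NetworkHub"
    }
  }
  list(L = L, module = module, role = role, n_planted = idx)
}

loadings_to_corr <- function(L) {
  uniq <- pmax(0, 1 - rowSums(L^2))
  C <- tcrossprod(L) + diag(uniq)
  # factor structure is positive semi-definite by construction; repair
  # any numerically indefinite matrix by eigenvalue clipping
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    e <- eigen(C, symmetric = TRUE)
    lam <- pmax(e$values, 1e-10)
    C <- e$vectors %*% (lam * t(e$vectors))
    d <- sqrt(diag(C))
    C <- C / tcrossprod(d)
    message("Planted correlation block repaired by nearest ",
            "positive-definite projection.")
  }
  C
}

#' Generate a chronosequence OTU table with planted ground truth
#'
#' Emulates a restoration chronosequence: `n_groups` groups (a degraded
#' control, a ladder of restoration ages, and a non-degraded reference)
#' with `reps_per_group` replicates each. Early groups are drawn from the
#' `chaos` regime, later groups and the reference from the `recovery`
#' regime. Counts arise from a Gaussian copula: per sample, module factors
#' and idiosyncratic noise produce a latent vector with the regime's block
#' correlation structure; group means shift along a regime contrast axis;
#' the latent values map monotonically (softmax of log-weights) to expected
#' relative abundances from which multinomial counts are drawn at `depth`.
#'
#' @param chaos,recovery [regime_spec] objects for the two regimes.
#' @param n_groups Number of chronosequence groups (default 11).
#' @param reps_per_group Replicates per group (default 5).
#' @param n_otus Total OTUs, planted plus unstructured (default 120).
#' @param depth Sequencing depth (counts per sample, default 20000).
#' @param seed Integer seed; all randomness flows from it.
#' @param kingdom `"bacteria"` or `"fungi"` (sets metadata and the
#'   taxonomy pool).
#' @param regime_split Number of leading groups assigned to the chaos
#'   regime (default 4).
#' @return A list with elements `table` (an [otu_table]) and `truth` (a
#'   `synthetic_truth`: per-sample stage labels, per-OTU planted module and
#'   role for each regime, and the planted latent correlation matrices).
#' @export
generate_chronosequence <- function(chaos = chaos_regime(),
                                    recovery = recovery_regime(),
                                    n_groups = 11, reps_per_group = 5,
                                    n_otus = 120, depth = 20000,
                                    seed = 1, kingdom = c("bacteria", "fungi"),
                                    regime_split = 4) {
  kingdom <- match.arg(kingdom)
  stopifnot(depth > 0, n_groups >= 2, regime_split >= 1,
            regime_split < n_groups)
  groups <- if (n_groups == 11) {
    c("SD", "1y", "4y", "6y", "8y", "9y", "12y", "14y", "16y", "18y", "ND")
  } else {
    paste0("G", seq_len(n_groups))
  }
  withr::with_seed(seed, {
    ch <- regime_loadings(chaos, n_otus)
    rc <- regime_loadings(recovery, n_otus)
    corr <- list(chaos = loadings_to_corr(ch$L),
                 recovery = loadings_to_corr(rc$L))
    otu_ids <- sprintf("OTU%04d", seq_len(n_otus))
    dimnames(corr$chaos) <- dimnames(corr$recovery) <- list(otu_ids, otu_ids)

    mu <- stats::rnorm(n_otus, 0, 1)          # baseline log-weights
    axis <- stats::rnorm(n_otus, 0, 1)        # regime contrast direction

    group_regime <- ifelse(seq_len(n_groups) <= regime_split,
                           "chaos", "recovery")
    pos <- (seq_len(n_groups) - 1) / (n_groups - 1)
    samples <- tidyr::expand_grid(group = factor(groups, levels = groups),
                                  replicate = seq_len(reps_per_group)) |>
      dplyr::mutate(sample_id = sprintf("%s_r%d", .data$group,
                                        .data$replicate))

    counts <- matrix(0L, nrow(samples), n_otus,
                     dimnames = list(samples$sample_id, otu_ids))
    stage <- character(nrow(samples))
    for (i in seq_len(nrow(samples))) {
      gi <- match(samples$group[i], groups)
      regime <- group_regime[gi]
      spec <- if (regime == "chaos") chaos else recovery
      ld <- if (regime == "chaos") ch else rc
      in_regime <- pos[group_regime == regime]
      # step offset between regimes plus a mild within-regime ramp
      shift <- spec$regime_centroid_shift
      offset <- (if (regime == "chaos") -shift / 2 else shift / 2) +
        (pos[gi] - mean(in_regime)) * 0.25 * shift
      f <- stats::rnorm(ncol(ld$L))
      eps <- stats::rnorm(n_otus)
      latent <- drop(ld$L %*% f) + sqrt(pmax(0, 1 - rowSums(ld$L^2))) * eps
      obs <- latent + spec$noise_sd * stats::rnorm(n_otus)
      lw <- mu + offset * axis + obs
      p <- exp(lw - max(lw))
      p <- p / sum(p)
      counts[i, ] <- stats::rmultinom(1, depth, p)[, 1]
      stage[i] <- regime
    }

    phyla_pool <- if (kingdom == "bacteria") {
      c("Proteobacteria", "Acidobacteria", "Actinobacteria", "Chloroflexi",
        "Planctomycetes", "Bacteroidetes", "Verrucomicrobia",
        "Gemmatimonadetes", "Firmicutes", "Unclassified")
    } else {
      c("Ascomycota", "Basidiomycota", "Mortierellomycota",
        "Glomeromycota", "Chytridiomycota", "Unclassified")
    }
    taxonomy <- tibble::tibble(
      otu_id = otu_ids,
      phylum = sample(phyla_pool, n_otus, replace = TRUE,
                      prob = seq(length(phyla_pool), 1) /
                        sum(seq(length(phyla_pool), 1)))
    )
    metadata <- tibble::tibble(sample_id = samples$sample_id,
                               group = as.character(samples$group),
                               replicate = samples$replicate,
                               kingdom = kingdom)
    table <- otu_table(counts, taxonomy = taxonomy, metadata = metadata)

    truth <- structure(list(
      stages = tibble::tibble(sample_id = samples$sample_id,
                              group = as.character(samples$group),
                              stage = stage),
      otus = tibble::tibble(otu_id = otu_ids,
                            chaos_module = ch$module,
                            chaos_role = ch$role,
                            recovery_module = rc$module,
                            recovery_role = rc$role),
      corr = corr,
      specs = list(chaos = chaos, recovery = recovery),
      seed = seed
    ), class = "synthetic_truth")
    list(table = table, truth = truth)
  })
}

#' Summarize planted ground truth
#'
#' @param truth A `synthetic_truth` from [generate_chronosequence()].
#' @return A tibble with one row per planted feature (stage sample counts,
#'   module counts and mean sizes, hub counts per regime).
#' @export
truth_report <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  stage_rows <- truth$stages |>
    dplyr::count(.data$stage, name = "value") |>
    dplyr::transmute(regime = .data$stage, feature = "n_samples",
                     value = as.numeric(.data$value))
  per_regime <- function(regime) {
    mod <- truth$otus[[paste0(regime, "_module")]]
    rol <- truth$otus[[paste0(regime, "_role")]]
    sizes <- table(mod)
    dplyr::bind_rows(
      tibble::tibble(regime = regime, feature = "n_modules",
                     value = as.numeric(length(sizes))),
      tibble::tibble(regime = regime, feature = "mean_module_size",
                     value = if (length(sizes)) mean(sizes) else NA_real_),
      tibble::tibble(regime = regime,
                     feature = c("n_network_hubs", "n_module_hubs",
                                 "n_connectors"),
                     value = c(sum(rol == "NetworkHub", na.rm = TRUE),
                               sum(rol == "ModuleHub", na.rm = TRUE),
                               sum(rol == "Connector", na.rm = TRUE)))
    )
  }
  dplyr::bind_rows(stage_rows, per_regime("chaos"), per_regime("recovery"))
}

#' Materialize the planted interaction graph of one regime
#'
#' Builds the explicit graph the regime's ground truth encodes: module
#' members form dense within-module neighbourhoods, module hubs attach to
#' every member of their module, connectors attach to a few members in
#' each of their 3 bridged modules, and network hubs attach to members
#' across 4 modules. This is the noiseless topological view of the
#' regime, used to test module, role and robustness machinery against a
#' known answer.
#'
#' @param truth A `synthetic_truth`.
#' @param regime `"recovery"` (default) or `"chaos"`.
#' @param p_within Probability of an edge between two members of the same
#'   module (default 0.9).
#' @param seed Integer seed for the within-module Bernoulli draws.
#' @return A [cooccurrence_network] whose nodes carry the planted roles
#'   (in `$nodes$planted_role`) and modules (`$nodes$planted_module`).
#' @export
planted_network <- function(truth, regime = c("recovery", "chaos"),
                            p_within = 0.9, seed = 1) {
  regime <- match.arg(regime)
  stopifnot(inherits(truth, "synthetic_truth"))
  otus <- truth$otus
  module <- otus[[paste0(regime, "_module")]]
  role <- otus[[paste0(regime, "_role")]]
  spec <- truth$specs[[regime]]
  n_mod <- spec$n_modules
  planted <- which(!is.na(role))
  edges <- list()
  withr::with_seed(seed, {
    for (b in seq_len(n_mod)) {
      members <- which(!is.na(module) & module == b)
      if (length(members) < 2) next
      pr <- utils::combn(members, 2)
      keep <- stats::runif(ncol(pr)) < p_within
      # module hubs attach to every member of their module
      hub_pair <- otus$otu_id[pr[1, ]] %in%
        otus$otu_id[role == "ModuleHub" & !is.na(role)] |
        otus$otu_id[pr[2, ]] %in%
        otus$otu_id[role == "ModuleHub" & !is.na(role)]
      keep <- keep | hub_pair
      edges[[length(edges) + 1L]] <-
        tibble::tibble(a = pr[1, keep], b = pr[2, keep])
    }
    conn <- which(!is.na(role) & role == "Connector")
    for (ci in seq_along(conn)) {
      mods <- ((ci - 1L) + 0:2) %% n_mod + 1L
      for (m in mods) {
        members <- which(!is.na(module) & module == m)
        tgt <- sample(members, min(3L, length(members)))
        edges[[length(edges) + 1L]] <- tibble::tibble(a = conn[ci], b = tgt)
      }
    }
    hubs <- which(!is.na(role) & role == "NetworkHub")
    for (hi in seq_along(hubs)) {
      mods <- ((hi - 1L) * 2 + 0:3) %% n_mod + 1L
      for (m in mods) {
        members <- which(!is.na(module) & module == m)
        tgt <- sample(members, min(4L, length(members)))
        edges[[length(edges) + 1L]] <- tibble::tibble(a = hubs[hi], b = tgt)
      }
    }
  })
  ed <- dplyr::bind_rows(edges) |>
    dplyr::transmute(otu_a = otus$otu_id[pmin(.data$a, .data$b)],
                     otu_b = otus$otu_id[pmax(.data$a, .data$b)]) |>
    dplyr::distinct() |>
    dplyr::mutate(rho = 1, q = 0, sign = 1L)
  deg <- table(factor(c(ed$otu_a, ed$otu_b),
                      levels = otus$otu_id[planted]))
  nodes <- tibble::tibble(
    otu_id = otus$otu_id[planted],
    phylum = "Unclassified",
    degree = as.integer(deg[otus$otu_id[planted]]),
    planted_module = module[planted],
    planted_role = role[planted]
  )
  new_cooccurrence_network(nodes, ed, rho_min = NA_real_, q_max = NA_real_)
}

#' Planted roles of a planted network as a role table
#'
#' Extracts the ground-truth role of every node of a [planted_network()]
#' in the format [simulate_attack()] expects for the keystone strategy.
#'
#' @param net A `cooccurrence_network` from [planted_network()].
#' @return A tibble `otu_id`, `role`, `degree`.
#' @export
planted_roles <- function(net) {
  stopifnot(inherits(net, "cooccurrence_network"),
            "planted_role" %in% names(net$nodes))
  tibble::tibble(otu_id = net$nodes$otu_id,
                 role = net$nodes$planted_role,
                 degree = net$nodes$degree)
}
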