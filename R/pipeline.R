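#' Pipeline configuration
#'
#' Collects every tunable threshold of the analysis chain and validates
#' them against the preconditions of the stages that consume them, before
#' any computation runs.
#'
#' @param pseudocount CLR pseudocount (> 0).
#' @param prevalence_min,mean_relabund_min Core-OTU filter thresholds in
#'   \[0, 1\].
#' @param rho_min,q_max Network edge thresholds in \[0, 1\].
#' @param k_min,k_max Silhouette scan range.
#' @param n_trees,n_folds Random-forest settings.
#' @param n_random Null-model ensemble size.
#' @param n_reps Random-failure repetitions.
#' @param collapse_level Collapse-threshold level in (0, 1).
#' @param stage_rule `"convergence"` or `"topology"` stage-identity rule.
#' @param reference_group Non-degraded reference group label.
#' @param n_perm Permutations for PERMANOVA/ANOSIM.
#' @param seed Master seed for every stochastic stage.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(pseudocount = 1, prevalence_min = 0.5,
                            mean_relabund_min = 1e-4, rho_min = 0.7,
                            q_max = 0.01, k_min = 2, k_max = 6,
                            n_trees = 100, n_folds = 5, n_random = 100,
                            n_reps = 50, collapse_level = 0.5,
                            stage_rule = c("convergence", "topology"),
                            reference_group = "ND", n_perm = 999,
                            seed = 1) {
  stage_rule <- match.arg(stage_rule)
  in01 <- function(v) is.numeric(v) && length(v) == 1 && v >= 0 && v <= 1
  if (!is.numeric(pseudocount) || pseudocount <= 0) {
    stop("pseudocount must be positive.", call. = FALSE)
  }
  for (nm in c("prevalence_min", "mean_relabund_min", "rho_min", "q_max")) {
    if (!in01(get(nm))) stop(nm, " must lie in [0, 1].", call. = FALSE)
  }
  if (collapse_level <= 0 || collapse_level >= 1) {
    stop("collapse_level must lie strictly in (0, 1).", call. = FALSE)
  }
  if (k_min < 2 || k_max < k_min) {
    stop("Need 2 <= k_min <= k_max.", call. = FALSE)
  }
  if (n_trees < 1 || n_folds < 2 || n_random < 2 || n_reps < 1 ||
      n_perm < 1) {
    stop("Counts (n_trees, n_folds, n_random, n_reps, n_perm) out of ",
         "range.", call. = FALSE)
  }
  structure(list(pseudocount = pseudocount,
                 prevalence_min = prevalence_min,
                 mean_relabund_min = mean_relabund_min,
                 rho_min = rho_min, q_max = q_max,
                 k_min = k_min, k_max = k_max,
                 n_trees = n_trees, n_folds = n_folds,
                 n_random = n_random, n_reps = n_reps,
                 collapse_level = collapse_level,
                 stage_rule = stage_rule,
                 reference_group = reference_group,
                 n_perm = n_perm, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full succession analysis pipeline
#'
#' End-to-end orchestration for one kingdom (tables holding several
#' kingdoms are split and processed independently): alpha diversity with
#' group tests; Bray-Curtis, PCoA, PERMANOVA and ANOSIM; CLR convergence
#' to the reference group; silhouette scan and consensus stage
#' assignment with stage-identity labeling; random-forest validation and
#' biomarker ranking on the Core samples; per-stage co-occurrence
#' networks with edge-sign summaries, Louvain modules, global metrics,
#' Zi-Pi roles, keystone taxonomy, null-model Z-scores and
#' attack-robustness curves. A manifest records the configuration hash,
#' the master seed and a content hash of every result, so identical
#' seeds yield identical manifests.
#'
#' @param table An [otu_table] (real or from
#'   [generate_chronosequence()]).
#' @param config A [pipeline_config].
#' @param out_dir Optional directory; when given, tables are written as
#'   TSV, summaries as JSON, and the manifest as `manifest.json`.
#' @return A `pipeline_result`: list of per-kingdom result bundles plus
#'   `manifest`.
#' @export
run_pipeline <- function(table, config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(table, "otu_table"),
            inherits(config, "pipeline_config"))
  kingdoms <- unique(table$metadata$kingdom)
  results <- lapply(kingdoms, function(kg) {
    ids <- table$metadata$sample_id[table$metadata$kingdom == kg]
    run_pipeline_one(subset_otu_table(table, samples = ids), config)
  })
  names(results) <- kingdoms
  manifest <- list(
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed,
    kingdoms = as.list(kingdoms),
    result_hash = rlang::hash(results)
  )
  out <- structure(list(kingdoms = results, manifest = manifest),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

run_pipeline_one <- function(table, config) {
  seed <- config$seed
  md <- table$metadata
  # diversity
  alpha <- alpha_metrics(table)
  alpha_md <- dplyr::left_join(alpha, md, by = "sample_id")
  alpha_tests <- lapply(
    stats::setNames(nm = c("observed_otus", "chao1", "shannon", "simpson")),
    function(metric) {
      compare_groups(alpha_md, .data[[metric]], .data$group)
    })
  rel <- relative_abundance(table)
  bc <- bray_curtis_matrix(rel)
  ord <- pcoa_ordination(bc)
  groups <- md$group[match(rownames(bc), md$sample_id)]
  beta_tests <- list(
    permanova = permanova(bc, groups, n_perm = config$n_perm, seed = seed),
    anosim = anosim(bc, groups, n_perm = config$n_perm, seed = seed)
  )
  clr <- clr_transform(table, pseudocount = config$pseudocount)
  conv <- convergence_to_reference(clr, md,
                                   reference_group = config$reference_group)
  # stages
  scan <- silhouette_scan(bc, ord, k_min = config$k_min,
                          k_max = config$k_max, seed = seed)
  k <- as.integer(names(sort(table(scan$best_k$best_k),
                             decreasing = TRUE))[1])
  assignment <- consensus_cluster(bc, ord, k = k, seed = seed)
  labeled <- if (length(setdiff(unique(assignment$core_stage),
                                "Ambiguous")) == 2) {
    if (config$stage_rule == "convergence") {
      label_stages(assignment, convergence = conv, rule = "convergence")
    } else {
      label_stages(assignment, table = table, rule = "topology",
                   n_random = config$n_random, seed = seed,
                   prevalence_min = config$prevalence_min,
                   mean_relabund_min = config$mean_relabund_min,
                   rho_min = config$rho_min, q_max = config$q_max)
    }
  } else {
    assignment
  }
  composition <- stage_composition(labeled, md)
  # supervised validation on Core samples
  core <- dplyr::filter(tibble::as_tibble(labeled),
                        .data$core_stage != "Ambiguous")
  stage_of <- stats::setNames(core$core_stage, core$sample_id)
  cv <- NULL
  biomarkers <- NULL
  if (length(unique(core$core_stage)) == 2 &&
      min(table(core$core_stage)) >= config$n_folds) {
    core_tab <- subset_otu_table(table, samples = core$sample_id)
    cv <- crossval_classify(core_tab, stage_of, n_trees = config$n_trees,
                            n_folds = config$n_folds, seed = seed)
    biomarkers <- rank_biomarkers(core_tab, stage_of,
                                  n_trees = config$n_trees, seed = seed)
  }
  # per-stage networks
  stages <- setdiff(unique(core$core_stage), "Ambiguous")
  networks <- lapply(stats::setNames(nm = stages), function(st) {
    ids <- core$sample_id[core$core_stage == st]
    sub <- subset_otu_table(table, samples = ids)
    core_otus <- filter_core_otus(sub,
                                  prevalence_min = config$prevalence_min,
                                  mean_relabund_min = config$mean_relabund_min)
    if (n_otus(core_otus) < 2) {
      return(list(note = "fewer than 2 core OTUs; network skipped"))
    }
    net <- build_network(correlation_edges(core_otus),
                         rho_min = config$rho_min, q_max = config$q_max)
    if (nrow(net$edges) == 0) {
      return(list(network = net, summary = edge_sign_summary(net),
                  note = "no significant edges"))
    }
    part <- louvain_partition(net, seed = seed)
    roles <- zipi_roles(net, part)
    robustness <- list(
      random = simulate_attack(net, "random", n_reps = config$n_reps,
                               seed = seed),
      degree = simulate_attack(net, "degree"),
      keystone = simulate_attack(net, "keystone", roles = roles)
    )
    list(
      network = net,
      summary = edge_sign_summary(net),
      partition = part,
      metrics = global_metrics(net, part),
      roles = roles,
      keystone_taxonomy = keystone_taxonomy_profile(roles),
      nullmodel = modularity_zscore(net, n_random = config$n_random,
                                    seed = seed, partition = part),
      robustness = robustness,
      collapse = purrr::map_dfr(robustness, function(cv) {
        collapse_threshold(cv, level = config$collapse_level)
      }, .id = "strategy")
    )
  })
  list(alpha = alpha, alpha_tests = alpha_tests, bray_curtis = bc,
       ordination = ord, beta_tests = beta_tests, convergence = conv,
       phylum_profile = aggregate_phylum(table),
       silhouette = scan, k = k, assignment = labeled,
       composition = composition, crossval = cv,
       biomarkers = biomarkers, networks = networks)
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  wtsv <- function(x, name) {
    readr::write_tsv(x, file.path(out_dir, name))
    files <<- c(files, name)
  }
  wjson <- function(x, name) {
    jsonlite::write_json(x, file.path(out_dir, name), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    files <<- c(files, name)
  }
  for (kg in names(result$kingdoms)) {
    r <- result$kingdoms[[kg]]
    px <- function(nm) paste0(kg, "_", nm)
    wtsv(r$alpha, px("alpha.tsv"))
    wtsv(tibble::as_tibble(r$bray_curtis, rownames = "sample_id"),
         px("bray_curtis.tsv"))
    wtsv(tibble::as_tibble(r$ordination$coordinates,
                           rownames = "sample_id"),
         px("pcoa.tsv"))
    wtsv(r$convergence, px("convergence.tsv"))
    wtsv(r$silhouette$scan, px("silhouette.tsv"))
    wtsv(tibble::as_tibble(r$assignment), px("assignment.tsv"))
    wtsv(r$composition, px("stage_composition.tsv"))
    wjson(list(permanova = as.list(r$beta_tests$permanova),
               anosim = as.list(r$beta_tests$anosim)),
          px("beta_tests.json"))
    if (!is.null(r$crossval)) {
      wjson(list(mean_auc = r$crossval$mean_auc,
                 sd_auc = r$crossval$sd_auc,
                 per_fold_auc = r$crossval$folds$auc,
                 confusion = as.list(as.data.frame(r$crossval$confusion))),
            px("crossval.json"))
      wtsv(r$biomarkers, px("biomarkers.tsv"))
    }
    for (st in names(r$networks)) {
      nb <- r$networks[[st]]
      if (is.null(nb$network)) next
      wtsv(nb$network$edges, px(paste0(st, "_edges.tsv")))
      wtsv(nb$network$nodes, px(paste0(st, "_nodes.tsv")))
      if (!is.null(nb$roles)) {
        wtsv(nb$roles, px(paste0(st, "_roles.tsv")))
        wtsv(dplyr::bind_rows(lapply(nb$robustness, `[[`, "points"),
                              .id = "strategy"),
             px(paste0(st, "_robustness.tsv")))
        wjson(list(summary = as.list(nb$summary),
                   metrics = as.list(nb$metrics),
                   nullmodel = nb$nullmodel[c("q_obs", "q_rand_mean",
                                              "q_rand_sd", "z",
                                              "n_random", "seed")],
                   collapse = as.list(nb$collapse)),
              px(paste0(st, "_topology.json")))
      }
    }
  }
  manifest <- c(result$manifest, list(files = as.list(sort(files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(result)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> kingdoms:",
      paste(names(x$kingdoms), collapse = ", "),
      "| config", x$manifest$config_hash, "\n")
  invisible(x)
}
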