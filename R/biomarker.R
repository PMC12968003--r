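#' Stratified cross-validated random-forest validation of the stages
#'
#' Trains a random-forest classifier (100 trees by default) on relative
#' abundances to discriminate the two core stages, under stratified
#' k-fold cross-validation: folds preserve class proportions, each model
#' is scored on its held-out fold, per-fold AUC is computed from the
#' out-of-fold class probabilities, and a cumulative confusion matrix is
#' accumulated over folds at a 0.5 probability threshold.
#'
#' @param x An [otu_table] restricted to Core samples.
#' @param stages Stage label per sample of `x` (two classes), in row
#'   order or as a named vector.
#' @param n_trees Trees per forest (default 100).
#' @param n_folds Folds (default 5); every class must have at least
#'   `n_folds` samples.
#' @param seed Integer seed for fold assignment and forest growth.
#' @param features `"relative"` abundances (default) or `"clr"`.
#' @return A `crossval_report`: list with `folds` (tibble `fold`, `auc`),
#'   `mean_auc`, `sd_auc`, `confusion` (2x2 matrix, rows = truth),
#'   `roc` (out-of-fold ROC points per fold), `fold_assignment`,
#'   `n_core`, `positive_class`.
#' @export
crossval_classify <- function(x, stages, n_trees = 100, n_folds = 5,
                              seed = 1, features = c("relative", "clr")) {
  stopifnot(inherits(x, "otu_table"))
  features <- match.arg(features)
  stages <- align_stage_labels(x, stages)
  classes <- sort(unique(stages))
  if (length(classes) != 2) {
    stop("Exactly two stage classes are required.", call. = FALSE)
  }
  counts <- table(stages)
  if (any(counts < n_folds)) {
    stop("Class '", names(counts)[which.min(counts)], "' has fewer ",
         "samples (", min(counts), ") than folds (", n_folds,
         "); use fewer folds.", call. = FALSE)
  }
  feat <- if (features == "relative") relative_abundance(x)$values else
    clr_transform(x)$values
  pos <- classes[2L]
  withr::with_seed(seed, {
    fold <- integer(length(stages))
    for (cl in classes) {
      idx <- sample(which(stages == cl))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    prob <- rep(NA_real_, length(stages))
    fold_auc <- numeric(n_folds)
    roc <- vector("list", n_folds)
    confusion <- matrix(0L, 2, 2, dimnames = list(truth = classes,
                                                  predicted = classes))
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      fit <- randomForest::randomForest(x = feat[tr, , drop = FALSE],
                                        y = factor(stages[tr],
                                                   levels = classes),
                                        ntree = n_trees)
      pp <- stats::predict(fit, feat[!tr, , drop = FALSE],
                           type = "prob")[, pos]
      prob[!tr] <- pp
      truth <- stages[!tr]
      fold_auc[f] <- rank_auc(pp, truth == pos)
      roc[[f]] <- roc_points(pp, truth == pos) |>
        dplyr::mutate(fold = f, .before = 1)
      pred <- ifelse(pp > 0.5, classes[2L], classes[1L])
      confusion <- confusion + table(factor(truth, levels = classes),
                                     factor(pred, levels = classes))
    }
    structure(list(
      folds = tibble::tibble(fold = seq_len(n_folds), auc = fold_auc),
      mean_auc = mean(fold_auc),
      sd_auc = stats::sd(fold_auc),
      confusion = confusion,
      roc = dplyr::bind_rows(roc),
      fold_assignment = tibble::tibble(sample_id = rownames(feat),
                                       stage = stages, fold = fold,
                                       oof_probability = prob),
      n_core = length(stages),
      positive_class = pos,
      n_trees = n_trees
    ), class = "crossval_report")
  })
}

align_stage_labels <- function(x, stages) {
  ids <- rownames(x$counts)
  if (!is.null(names(stages))) {
    if (!all(ids %in% names(stages))) {
      stop("Stage labels missing for some samples.", call. = FALSE)
    }
    stages <- stages[ids]
  }
  stopifnot(length(stages) == length(ids))
  as.character(stages)
}

# Mann-Whitney AUC from out-of-fold probabilities
rank_auc <- function(prob, is_pos) {
  n1 <- sum(is_pos)
  n0 <- sum(!is_pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(prob)
  (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

roc_points <- function(prob, is_pos) {
  ord <- order(prob, decreasing = TRUE)
  tp <- cumsum(is_pos[ord])
  fp <- cumsum(!is_pos[ord])
  tibble::tibble(
    fpr = c(0, fp / max(1, sum(!is_pos))),
    tpr = c(0, tp / max(1, sum(is_pos)))
  )
}

#' @export
print.crossval_report <- function(x, ...) {
  cat("Stratified ", nrow(x$folds), "-fold CV: mean AUC = ",
      round(x$mean_auc, 3), " +/- ", round(x$sd_auc, 3), " (n = ",
      x$n_core, ")\n", sep = "")
  print(x$confusion)
  invisible(x)
}

#' Gini-importance biomarker ranking
#'
#' Fits a single random forest on all Core samples and ranks OTUs by
#' normalized Gini (mean decrease in impurity) importance.
#'
#' @inheritParams crossval_classify
#' @param top_n Number of top biomarkers to flag (default 20).
#' @return A tibble `otu_id`, `phylum`, `importance` (sums to 1), `rank`,
#'   `top` (logical), sorted by decreasing importance.
#' @export
rank_biomarkers <- function(x, stages, n_trees = 100, seed = 1,
                            top_n = 20, features = c("relative", "clr")) {
  stopifnot(inherits(x, "otu_table"))
  features <- match.arg(features)
  stages <- align_stage_labels(x, stages)
  classes <- sort(unique(stages))
  if (length(classes) != 2) {
    stop("Exactly two stage classes are required.", call. = FALSE)
  }
  feat <- if (features == "relative") relative_abundance(x)$values else
    clr_transform(x)$values
  fit <- withr::with_seed(seed, {
    randomForest::randomForest(x = feat, y = factor(stages),
                               ntree = n_trees, importance = FALSE)
  })
  imp <- fit$importance[, "MeanDecreaseGini"]
  total <- sum(imp)
  if (total <= 0) total <- 1
  tibble::tibble(otu_id = rownames(fit$importance),
                 importance = unname(imp) / total) |>
    dplyr::left_join(dplyr::select(x$taxonomy, "otu_id", "phylum"),
                     by = "otu_id") |>
    dplyr::relocate("phylum", .after = "otu_id") |>
    dplyr::arrange(dplyr::desc(.data$importance)) |>
    dplyr::mutate(rank = dplyr::row_number(),
                  top = .data$rank <= top_n)
}
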