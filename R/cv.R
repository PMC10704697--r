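# Cross-validation protocol: k-fold splits repeated over several random
# seeds, per-fold metric records, seed-level averages, and the grand
# mean +/- sd report; plus the full-training single model and the
# fold-model ensemble.

#' Cross-validation plan
#'
#' The default protocol: 5 folds, repeated under 5 random seeds, fold
#' membership drawn uniformly at random (optionally stratified by the
#' soluble/insoluble class at 0.5).
#'
#' @param n_folds Number of folds (>= 2).
#' @param seeds Integer vector of seeds; one full CV round per seed.
#' @param stratify Stratify folds by the 0.5 solubility class.
#' @return Object of class `cv_plan`.
#' @export
cv_plan <- function(n_folds = 5L, seeds = 1:5, stratify = FALSE) {
  stopifnot(n_folds >= 2L, length(seeds) >= 1L)
  structure(list(n_folds = as.integer(n_folds), seeds = as.integer(seeds),
                 stratify = isTRUE(stratify)), class = "cv_plan")
}

#' Seed-reproducible fold assignment
#'
#' IDs are sorted before the draw so the partition depends only on the set
#' of IDs and the seed, not on input order. Fold sizes differ by at most
#' one.
#'
#' @param ids Character vector of record IDs.
#' @param n_folds Number of folds.
#' @param seed RNG seed.
#' @param stratify Stratify by class.
#' @param y Labels (required when `stratify = TRUE`).
#' @return Named integer vector of fold numbers in `1..n_folds`, one per id.
#' @export
make_folds <- function(ids, n_folds = 5L, seed = 1L, stratify = FALSE,
                       y = NULL) {
  ord <- order(ids)
  ids_sorted <- ids[ord]
  set.seed(seed)
  if (stratify) {
    if (is.null(y)) stop("y is required for stratified folds", call. = FALSE)
    cls <- (y[ord] >= 0.5)
    fold <- integer(length(ids))
    for (cl in unique(cls)) {
      idx <- which(cls == cl)
      fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
  } else {
    fold <- sample(rep_len(seq_len(n_folds), length(ids)))
  }
  setNames(fold, ids_sorted)[ids]
}

#' Run the k-fold x multi-seed cross-validation protocol
#'
#' For each seed, the labeled records are partitioned into `n_folds` folds;
#' each fold in turn is held out while a model is trained on the remaining
#' folds (with its own internal early-stopping split) and evaluated on the
#' held-out fold. Fold metrics are averaged per seed, and the final report
#' is the mean +/- sd across the seed-level means.
#'
#' @param records Labeled `protein_record` list.
#' @param config A [hybridgcn_config()]; its `seed` is replaced per CV seed.
#' @param plan A [cv_plan()].
#' @param verbose Print progress.
#' @return Object of class `hybridgcn_cv`: `folds` (per-seed, per-fold
#'   metric rows), `seed_means`, `summary` (per metric: grand mean, sd
#'   across seeds, formatted `"mean± sd"` string, plus fold-level sd).
#' @export
run_cv <- function(records, config = hybridgcn_config(), plan = cv_plan(),
                   verbose = FALSE) {
  y <- vapply(records, function(r)
    if (is.null(r$solubility)) NA_real_ else r$solubility, numeric(1))
  if (anyNA(y)) stop("all records must be labeled for cross-validation",
                     call. = FALSE)
  ids <- vapply(records, `[[`, character(1), "id")
  fold_rows <- list()
  for (seed in plan$seeds) {
    folds <- make_folds(ids, plan$n_folds, seed, plan$stratify, y)
    for (k in seq_len(plan$n_folds)) {
      test_i <- which(folds == k)
      train_i <- which(folds != k)
      cfg <- config
      cfg$seed <- as.integer(seed)
      fit <- hybridgcn(records[train_i], cfg)
      pred <- predict(fit, records[test_i])
      cm <- classify_metrics(y[test_i], pred)
      row <- data.frame(seed = seed, fold = k,
                        rmse = rmse(y[test_i], pred),
                        r2 = r2(y[test_i], pred),
                        accuracy = cm$accuracy, precision = cm$precision,
                        recall = cm$recall, f1 = cm$f1, auc = cm$auc)
      fold_rows[[length(fold_rows) + 1L]] <- row
      if (verbose) {
        message(sprintf("seed %d fold %d: RMSE %.4f R2 %.4f", seed, k,
                        row$rmse, row$r2))
      }
    }
  }
  folds_df <- do.call(rbind, fold_rows)
  metric_cols <- c("rmse", "r2", "accuracy", "precision", "recall", "f1",
                   "auc")
  seed_means <- stats::aggregate(folds_df[metric_cols],
                                 by = list(seed = folds_df$seed),
                                 FUN = mean, na.rm = TRUE)
  summary_df <- data.frame(
    metric = metric_cols,
    mean = vapply(metric_cols, function(m) mean(seed_means[[m]]), numeric(1)),
    sd_seeds = vapply(metric_cols, function(m)
      if (nrow(seed_means) > 1L) stats::sd(seed_means[[m]]) else 0,
      numeric(1)),
    sd_folds = vapply(metric_cols, function(m)
      stats::sd(folds_df[[m]]), numeric(1)),
    row.names = NULL)
  summary_df$formatted <- format_mean_sd(summary_df$mean, summary_df$sd_seeds)
  structure(list(folds = folds_df, seed_means = seed_means,
                 summary = summary_df, plan = plan, config = config),
            class = "hybridgcn_cv")
}

#' @export
print.hybridgcn_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation over %d seed(s)\n",
              x$plan$n_folds, length(x$plan$seeds)))
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %-9s %s\n", x$summary$metric[i], x$summary$formatted[i]))
  }
  invisible(x)
}

#' Train the full-data single model and the fold-model ensemble
#'
#' The single model is trained on the entire training set. The ensemble
#' consists of the `n_folds` models from one cross-validation round (first
#' seed of the plan); its prediction is the arithmetic mean of the fold
#' models' predictions, which stays inside (0,1) as a convex combination of
#' sigmoid outputs.
#'
#' @inheritParams run_cv
#' @return List with `single` (a `hybridgcn` fit) and `ensemble` (class
#'   `hybridgcn_ensemble`, a list of fold models with a `predict` method).
#' @export
train_full_and_ensemble <- function(records, config = hybridgcn_config(),
                                    plan = cv_plan()) {
  y <- vapply(records, function(r)
    if (is.null(r$solubility)) NA_real_ else r$solubility, numeric(1))
  ids <- vapply(records, `[[`, character(1), "id")
  seed <- plan$seeds[1]
  cfg <- config
  cfg$seed <- as.integer(seed)
  single <- hybridgcn(records, cfg)
  folds <- make_folds(ids, plan$n_folds, seed, plan$stratify, y)
  members <- lapply(seq_len(plan$n_folds), function(k) {
    hybridgcn(records[folds != k], cfg)
  })
  ensemble <- structure(list(members = members, n_folds = plan$n_folds,
                             seed = seed), class = "hybridgcn_ensemble")
  list(single = single, ensemble = ensemble)
}

#' @export
predict.hybridgcn_ensemble <- function(object, newdata, ...) {
  preds <- vapply(object$members, function(m) unname(predict(m, newdata)),
                  numeric(length(newdata)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1L)
  setNames(rowMeans(preds),
           vapply(newdata, `[[`, character(1), "id"))
}

#' @export
print.hybridgcn_ensemble <- function(x, ...) {
  cat(sprintf("Ensemble of %d cross-validation fold models (seed %d)\n",
              length(x$members), x$seed))
  invisible(x)
}
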