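# Feature and module ablation experiment grids.

# Configurations for each ablation mode. The module-ablation grid crosses
# the ESM block and the AFR gate against the five-traditional-feature GCN
# baseline; single-feature and ESM-pairwise runs disable AFR (they probe
# raw feature value); leave-one-out runs keep the base configuration's AFR.
ablation_configs <- function(base_config,
                             mode = c("leave_one_out", "single_feature",
                                      "pairwise_with_ESM",
                                      "module_ablation")) {
  mode <- match.arg(mode)
  all_blocks <- canonical_blocks()
  traditional <- setdiff(all_blocks, "ESM")
  dims <- default_block_dims()
  dims[names(base_config$block_dims)] <- base_config$block_dims
  mk <- function(label, blocks, use_afr) {
    cfg <- base_config
    cfg$blocks <- all_blocks[all_blocks %in% blocks]
    cfg$block_dims <- dims[cfg$blocks]
    cfg$use_afr <- use_afr
    list(label = label, config = cfg)
  }
  switch(mode,
    module_ablation = list(
      mk("GCN", traditional, FALSE),
      mk("ESM+GCN", all_blocks, FALSE),
      mk("AFR+GCN", traditional, TRUE),
      mk("ESM+AFR+GCN", all_blocks, TRUE)),
    single_feature = lapply(all_blocks, function(b) mk(b, b, FALSE)),
    leave_one_out = lapply(all_blocks, function(b)
      mk(paste0("-", b), setdiff(all_blocks, b), base_config$use_afr)),
    pairwise_with_ESM = lapply(traditional, function(b)
      mk(paste0("ESM+", b), c("ESM", b), FALSE)))
}

#' Run (or enumerate) a feature/module ablation grid
#'
#' Four experiment designs:
#' \describe{
#'   \item{`module_ablation`}{4 runs crossing the ESM feature block and the
#'     AFR module against the five-traditional-feature GCN baseline: GCN,
#'     ESM+GCN, AFR+GCN, ESM+AFR+GCN.}
#'   \item{`single_feature`}{6 runs, one feature block at a time, AFR off.}
#'   \item{`leave_one_out`}{6 runs, the full model minus one block.}
#'   \item{`pairwise_with_ESM`}{5 runs combining ESM with each other block.}
#' }
#'
#' @param records Labeled records (may be `NULL` when `evaluate = FALSE`).
#' @param base_config The configuration every run is derived from.
#' @param mode One of the four designs above.
#' @param plan A [cv_plan()] used when evaluating.
#' @param evaluate Run cross-validation for every configuration (`TRUE`) or
#'   only enumerate the grid with its channel bookkeeping (`FALSE`).
#' @param verbose Print progress.
#' @return data.frame with one row per run: `label`, `blocks`, `use_afr`,
#'   `n_channels`, and (when evaluated) the cross-validated metrics as
#'   `mean± sd` columns plus numeric `r2_mean`, `rmse_mean`.
#' @export
ablation_grid <- function(records = NULL, base_config = hybridgcn_config(),
                          mode = c("leave_one_out", "single_feature",
                                   "pairwise_with_ESM", "module_ablation"),
                          plan = cv_plan(), evaluate = TRUE,
                          verbose = FALSE) {
  mode <- match.arg(mode)
  runs <- ablation_configs(base_config, mode)
  if (length(runs) == 0L) stop("empty ablation grid", call. = FALSE)
  rows <- lapply(runs, function(run) {
    cfg <- run$config
    row <- data.frame(label = run$label,
                      blocks = paste(cfg$blocks, collapse = "+"),
                      use_afr = cfg$use_afr,
                      n_channels = n_channels(cfg))
    if (evaluate) {
      if (is.null(records)) stop("records required when evaluate = TRUE",
                                 call. = FALSE)
      if (verbose) message("ablation run: ", run$label)
      cv <- run_cv(records, cfg, plan)
      s <- cv$summary
      row$r2 <- s$formatted[s$metric == "r2"]
      row$rmse <- s$formatted[s$metric == "rmse"]
      row$r2_mean <- s$mean[s$metric == "r2"]
      row$rmse_mean <- s$mean[s$metric == "rmse"]
    }
    row
  })
  out <- do.call(rbind, rows)
  attr(out, "mode") <- mode
  out
}
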