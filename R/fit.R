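# Model fitting and the S3 surface of the fitted object.

#' Fit the hybrid GCN solubility regressor
#'
#' Trains the network on labeled protein records: per-channel normalization
#' statistics are fitted on the training records, features are stacked and
#' gated (AFR), and the GCN + attention readout is optimized with Adam on
#' the per-protein squared error (RMSE is the monitored loss). When
#' `validation_fraction > 0` an internal split of the training records is
#' held out to drive early stopping; the returned parameters are those of
#' the best validation epoch.
#'
#' @param records List of labeled `protein_record` objects.
#' @param config A [hybridgcn_config()].
#' @param verbose Print per-epoch RMSE while training.
#' @return Object of class `hybridgcn` with components `params`, `config`,
#'   `norm_stats`, `block_spans`, `C`, `history` (per-epoch train/validation
#'   RMSE), `best_epoch`, `fitted`, `y`, `ids`.
#' @seealso [predict.hybridgcn()], [run_cv()], [simulate_dataset()]
#' @export
#' @examples
#' sim <- simulate_dataset(sim_config(n_proteins = 12, length_range = c(8, 12),
#'   block_dims = c(ESM = 4, HMM = 5), informative_blocks = "ESM",
#'   informative_channels_per_block = 2, seed = 7))
#' cfg <- hybridgcn_config(gcn_hidden = 8, attention_hidden = 4, epochs = 3,
#'   blocks = c("ESM", "HMM"), block_dims = c(ESM = 4, HMM = 5),
#'   dropout = 0, validation_fraction = 0)
#' fit <- hybridgcn(sim$records, cfg)
#' predict(fit, sim$records[1:2])
hybridgcn <- function(records, config = hybridgcn_config(), verbose = FALSE) {
  y_all <- vapply(records, function(r)
    if (is.null(r$solubility)) NA_real_ else r$solubility, numeric(1))
  if (anyNA(y_all)) {
    stop("all records must carry a solubility label for training", call. = FALSE)
  }
  stats <- fit_normalization(records, config$normalization, config$blocks)
  prep <- prepare_matrices(records, config, stats)
  n <- length(records)

  set.seed(config$seed)
  n_val <- floor(config$validation_fraction * n)
  if (n_val > 0L && n - n_val >= 2L) {
    val_idx <- sort(sample.int(n, n_val))
  } else {
    val_idx <- integer(0)
  }
  train_idx <- setdiff(seq_len(n), val_idx)

  par0 <- init_params(prep$C, config)
  res <- hg_train_cpp(prep$H, prep$A, prep$y, par0,
                      use_afr = config$use_afr, afr_bias = config$afr_bias,
                      train_idx = as.integer(train_idx),
                      val_idx = as.integer(val_idx),
                      epochs = config$epochs, lr = config$learning_rate,
                      dropout = config$dropout, seed = config$seed,
                      patience = config$patience, min_delta = 0,
                      clip_norm = config$clip_norm)
  ran <- seq_len(res$epochs_run)
  history <- data.frame(epoch = ran,
                        train_rmse = res$train_rmse[ran],
                        val_rmse = res$val_rmse[ran])
  if (verbose) {
    for (e in ran) {
      message(sprintf("epoch %3d  train RMSE %.4f  val RMSE %s", e,
                      history$train_rmse[e],
                      ifelse(is.na(history$val_rmse[e]), "-",
                             sprintf("%.4f", history$val_rmse[e]))))
    }
  }
  fitted_vals <- as.numeric(hg_predict_cpp(prep$H, prep$A, res$par,
                                           config$use_afr))
  obj <- structure(list(
    params = res$par, config = config, norm_stats = stats,
    block_spans = prep$spans, C = prep$C, history = history,
    best_epoch = res$best_epoch,
    n_train = length(train_idx), n_val = length(val_idx),
    fitted = setNames(fitted_vals, prep$ids),
    y = setNames(prep$y, prep$ids), ids = prep$ids),
    class = "hybridgcn")
  obj
}

#' Predict solubility for protein records
#'
#' @param object A fitted `hybridgcn` model.
#' @param newdata List of `protein_record` objects (labels optional).
#' @param type `"response"` for the named vector of predicted solubilities,
#'   `"attention"` for a list of per-residue attention weights, or
#'   `"channel_weights"` for the n x C matrix of AFR gates.
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.hybridgcn <- function(object, newdata,
                              type = c("response", "attention",
                                       "channel_weights"), ...) {
  type <- match.arg(type)
  prep <- prepare_matrices(newdata, object$config, object$norm_stats)
  if (type == "response") {
    return(setNames(as.numeric(hg_predict_cpp(prep$H, prep$A, object$params,
                                              object$config$use_afr)),
                    prep$ids))
  }
  if (type == "channel_weights") {
    if (!object$config$use_afr) stop("model was fitted without AFR", call. = FALSE)
    W <- hg_afr_weights_cpp(prep$H, object$params)
    rownames(W) <- prep$ids
    return(W)
  }
  out <- lapply(seq_along(prep$H), function(i) {
    as.numeric(hg_forward_cpp(prep$H[[i]], prep$A[[i]], object$params,
                              object$config$use_afr)$attention)
  })
  setNames(out, prep$ids)
}

#' Per-protein AFR gate vectors for a set of records
#'
#' @param object A fitted `hybridgcn` model with `use_afr = TRUE`.
#' @param records Protein records (defaults require passing records; the
#'   model does not retain feature matrices).
#' @return n x C matrix of gate weights in (0,1), one row per protein.
#' @export
afr_weights <- function(object, records) {
  predict(object, records, type = "channel_weights")
}

#' @export
print.hybridgcn <- function(x, ...) {
  cfg <- x$config
  cat("Hybrid GCN solubility regressor\n")
  cat(sprintf("  features: %s (C = %d), AFR %s\n",
              paste(cfg$blocks, collapse = "+"), x$C,
              if (cfg$use_afr) "on" else "off"))
  cat(sprintf("  trained on %d proteins (%d held out for early stopping), best epoch %d\n",
              x$n_train, x$n_val, x$best_epoch))
  cat(sprintf("  training RMSE %.4f%s\n",
              x$history$train_rmse[nrow(x$history)],
              if (x$n_val > 0)
                sprintf(", best validation RMSE %.4f",
                        min(x$history$val_rmse, na.rm = TRUE)) else ""))
  invisible(x)
}

#' @export
summary.hybridgcn <- function(object, ...) {
  res <- object$y - object$fitted
  out <- list(config = object$config, C = object$C,
              n = length(object$y), best_epoch = object$best_epoch,
              train_rmse = sqrt(mean(res^2)),
              train_r2 = r2(object$y, object$fitted),
              history = object$history)
  if (object$config$use_afr) {
    # gate summary from the fitted AFR parameters at the neutral pooled input
    out$block_spans <- object$block_spans
  }
  class(out) <- "summary.hybridgcn"
  out
}

#' @export
print.summary.hybridgcn <- function(x, ...) {
  print(x$config)
  cat(sprintf("n = %d proteins | fit RMSE %.4f | fit R2 %.4f | best epoch %d\n",
              x$n, x$train_rmse, x$train_r2, x$best_epoch))
  invisible(x)
}

#' @export
coef.hybridgcn <- function(object, ...) object$params

#' @export
fitted.hybridgcn <- function(object, ...) object$fitted

#' @export
residuals.hybridgcn <- function(object, ...) object$y - object$fitted

#' Plot training history or channel gates
#'
#' @param x A fitted `hybridgcn` model.
#' @param which `"history"` (train/validation RMSE per epoch) or
#'   `"gates"` (mean AFR gate per block; requires `records`).
#' @param records Protein records for `which = "gates"`.
#' @param ... Passed to the underlying plotting call.
#' @return `x`, invisibly.
#' @export
plot.hybridgcn <- function(x, which = c("history", "gates"), records = NULL,
                           ...) {
  which <- match.arg(which)
  if (which == "history") {
    h <- x$history
    plot(h$epoch, h$train_rmse, type = "l", xlab = "epoch", ylab = "RMSE",
         ylim = range(c(h$train_rmse, h$val_rmse), na.rm = TRUE), ...)
    if (any(!is.na(h$val_rmse))) {
      graphics::lines(h$epoch, h$val_rmse, lty = 2)
      graphics::legend("topright", c("train", "validation"), lty = 1:2,
                       bty = "n")
    }
  } else {
    if (is.null(records)) stop("records are required for gate plots",
                               call. = FALSE)
    W <- afr_weights(x, records)
    imp <- block_importance(colMeans(W), x$block_spans)
    graphics::barplot(imp, ylab = "mean AFR gate", ylim = c(0, 1), ...)
    graphics::abline(h = 0.5, lty = 3)
  }
  invisible(x)
}
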