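# Evaluation metrics: regression (RMSE, R2) and classification metrics
# derived from the continuous predictions at the 0.5 solubility threshold.

#' Root mean squared error
#'
#' @param y,y_hat Numeric vectors of equal length (>= 1).
#' @return `sqrt(mean((y - y_hat)^2))`.
#' @export
rmse <- function(y, y_hat) {
  if (length(y) != length(y_hat)) stop("length mismatch", call. = FALSE)
  if (length(y) < 1L) stop("empty input", call. = FALSE)
  sqrt(mean((y - y_hat)^2))
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot`; can be negative for predictions worse than the
#' mean of `y`.
#'
#' @param y,y_hat Numeric vectors of equal length (>= 2); `y` must vary.
#' @return R-squared.
#' @export
r2 <- function(y, y_hat) {
  if (length(y) != length(y_hat)) stop("length mismatch", call. = FALSE)
  if (length(y) < 2L) stop("need at least two observations", call. = FALSE)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("y is constant: R2 undefined", call. = FALSE)
  1 - sum((y - y_hat)^2) / ss_tot
}

#' Classification metrics at the 0.5 solubility threshold
#'
#' Both the true and the predicted continuous solubilities are binarized at
#' `threshold`: a protein is soluble iff its value is >= the threshold
#' (values exactly at the boundary count as soluble, since only values
#' strictly below it are insoluble). Soluble is the positive class.
#' Precision = TP/(TP+FP), Recall = TP/(TP+FN),
#' F1 = 2*Precision*Recall/(Precision+Recall) with the convention that an
#' undefined ratio (empty denominator) is 0 and F1 = 0 whenever
#' Precision + Recall = 0. AUC is the rank statistic (probability that a
#' randomly chosen soluble protein receives a higher continuous prediction
#' than a randomly chosen insoluble one, ties counting 1/2), computed from
#' the continuous `y_hat` against the binarized `y`.
#'
#' @param y True solubilities in \[0,1\].
#' @param y_hat Predicted solubilities in \[0,1\].
#' @param threshold Classification threshold (default 0.5).
#' @return Named list: `accuracy`, `precision`, `recall`, `f1`, `auc`
#'   (`NA` with `auc_defined = FALSE` when `y` has a single class), and the
#'   confusion counts `tp`, `fp`, `fn`, `tn`.
#' @export
classify_metrics <- function(y, y_hat, threshold = 0.5) {
  if (length(y) != length(y_hat)) stop("length mismatch", call. = FALSE)
  yb <- y >= threshold
  pb <- y_hat >= threshold
  tp <- sum(yb & pb); fp <- sum(!yb & pb)
  fn <- sum(yb & !pb); tn <- sum(!yb & !pb)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  npos <- sum(yb); nneg <- sum(!yb)
  if (npos > 0L && nneg > 0L) {
    rk <- rank(y_hat)  # midranks handle ties as 1/2
    auc <- (sum(rk[yb]) - npos * (npos + 1) / 2) / (npos * nneg)
    auc_defined <- TRUE
  } else {
    auc <- NA_real_
    auc_defined <- FALSE
  }
  list(accuracy = (tp + tn) / length(y), precision = precision,
       recall = recall, f1 = f1, auc = auc, auc_defined = auc_defined,
       tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Full metric record for a prediction vector
#'
#' Combines the regression metrics (RMSE, R2) with the threshold-0.5
#' classification metrics into a single one-row record.
#'
#' @inheritParams classify_metrics
#' @return One-row data.frame with columns `rmse`, `r2`, `accuracy`,
#'   `precision`, `recall`, `f1`, `auc`.
#' @export
evaluate_predictions <- function(y, y_hat, threshold = 0.5) {
  cm <- classify_metrics(y, y_hat, threshold)
  data.frame(rmse = rmse(y, y_hat), r2 = r2(y, y_hat),
             accuracy = cm$accuracy, precision = cm$precision,
             recall = cm$recall, f1 = cm$f1, auc = cm$auc)
}

#' Format a mean and standard deviation in the tabular report style
#'
#' @param mean,sd Numeric scalars.
#' @param digits Decimal places (default 3).
#' @return String of the form `"0.495± 0.012"`.
#' @export
format_mean_sd <- function(mean, sd, digits = 3L) {
  sprintf("%.*f± %.*f", digits, mean, digits, sd)
}
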