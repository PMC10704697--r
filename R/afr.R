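# Adaptive Feature Re-weighting (AFR): per-channel global average pooling,
# a dense cross-channel interaction, ReLU, sigmoid gating, and channel-wise
# re-weighting of the hybrid feature matrix.
#
# These are the reference (pure-R) implementations; the compiled training
# core reproduces them and is tested against them.

#' Global average pooling over residues
#'
#' Collapses the L x C hybrid feature to a 1 x C vector of per-channel means:
#' `G_c = mean(H[, c])`.
#'
#' @param H Numeric L x C matrix (L >= 1).
#' @return Numeric vector of length C.
#' @export
global_average_pool <- function(H) {
  H <- as.matrix(H)
  if (nrow(H) == 0L) stop("empty input: L must be >= 1", call. = FALSE)
  colMeans(H)
}

#' Initialize AFR interaction parameters
#'
#' The cross-channel interaction applies C filters, each spanning all C
#' channels of the pooled vector -- a dense C x C linear map. Kernels are
#' drawn from N(0, 1/C) so the initial gates sit near the neutral value 0.5;
#' the bias starts at zero.
#'
#' @param C Channel count.
#' @param seed RNG seed for the kernel draw.
#' @param bias Include a trainable bias vector (default `TRUE`).
#' @return Object of class `afr_params`: list with `V` (C x C, row c' holds
#'   filter c'), `bv` (length C) and `bias` flag.
#' @export
afr_params <- function(C, seed = 1L, bias = TRUE) {
  set.seed(seed)
  structure(list(V = matrix(rnorm(C * C, sd = 1 / sqrt(C)), C, C),
                 bv = numeric(C), bias = isTRUE(bias)),
            class = "afr_params")
}

#' Cross-channel interaction
#'
#' Linear interaction `O[c'] = sum_c V[c', c] * G[c] (+ bv[c'])` followed by
#' the ReLU nonlinearity `P_nl = max(0, O)`.
#'
#' @param G Pooled per-channel vector of length C.
#' @param params An `afr_params` object (or list with `V`, `bv`, `bias`).
#' @return List with `O` and `P_nl`, both length-C vectors.
#' @export
channel_interaction <- function(G, params) {
  G <- as.numeric(G)
  V <- params$V
  if (!is.matrix(V) || nrow(V) != ncol(V) || ncol(V) != length(G)) {
    stop(sprintf("AFR kernels must be %d x %d to match G; got %d x %d",
                 length(G), length(G), nrow(V), ncol(V)), call. = FALSE)
  }
  O <- as.numeric(V %*% G)
  if (isTRUE(params$bias)) O <- O + params$bv
  list(O = O, P_nl = pmax(0, O))
}

#' Sigmoid channel gate
#'
#' `W_c = 1 / (1 + exp(-P_c))`, elementwise. Outputs are kept strictly
#' inside (0,1): saturated gates are clamped one machine epsilon below 1 so
#' extreme interactions never round to exactly 1.
#'
#' @param P_nl Nonlinear interaction vector (length C).
#' @return Gating vector W of length C, each entry in (0,1).
#' @export
channel_weights <- function(P_nl) {
  stopifnot(all(is.finite(P_nl)))
  w <- stats::plogis(as.numeric(P_nl))
  # guard against saturation rounding to exactly 1 in double precision
  pmin(w, 1 - .Machine$double.eps)
}

#' Channel-wise re-weighting
#'
#' `R[i, c] = H[i, c] * W[c]`.
#'
#' @param H L x C matrix.
#' @param W Gating vector of length C.
#' @return L x C matrix.
#' @export
reweight <- function(H, W) {
  H <- as.matrix(H)
  if (ncol(H) != length(W)) {
    stop(sprintf("channel mismatch: H has %d channels, W has %d",
                 ncol(H), length(W)), call. = FALSE)
  }
  sweep(H, 2L, as.numeric(W), `*`)
}

#' Full AFR forward pass
#'
#' Composition pool -> interaction -> sigmoid gate -> re-weighting, keeping
#' all intermediates for diagnostics. Note that because the ReLU clamps the
#' interaction at zero before the sigmoid, every gate satisfies
#' `W_c >= 0.5`; gates therefore attenuate channels relative to one another
#' rather than switching any channel fully off.
#'
#' @param H L x C hybrid feature matrix.
#' @param params An `afr_params` object.
#' @return List with `R` (re-weighted L x C matrix) and `diagnostics`, an
#'   object of class `channel_weights` holding `G`, `O`, `P_nl`, `W`.
#' @export
afr_forward <- function(H, params) {
  G <- global_average_pool(H)
  ci <- channel_interaction(G, params)
  W <- channel_weights(ci$P_nl)
  R <- reweight(H, W)
  diag <- structure(list(G = G, O = ci$O, P_nl = ci$P_nl, W = W),
                    class = "channel_weights")
  list(R = R, diagnostics = diag)
}

#' @export
print.channel_weights <- function(x, ...) {
  cat(sprintf("<channel_weights> C=%d  W in [%.4f, %.4f], mean %.4f\n",
              length(x$W), min(x$W), max(x$W), mean(x$W)))
  invisible(x)
}

#' Mean gate weight per feature block
#'
#' Summarizes a gating vector into one importance value per feature block:
#' the mean of W over the block's channel span.
#'
#' @param diagnostics A `channel_weights` object, or a bare numeric gating
#'   vector W.
#' @param spans Named list of `c(start, end)` channel spans (see
#'   [block_spans_for()]); must partition `1..C`.
#' @return Named numeric vector, one mean weight per block.
#' @export
block_importance <- function(diagnostics, spans) {
  W <- if (inherits(diagnostics, "channel_weights")) diagnostics$W
       else as.numeric(diagnostics)
  idx <- unlist(lapply(spans, function(s) seq(s[["start"]], s[["end"]])),
                use.names = FALSE)
  if (length(idx) != length(W) || !identical(sort(idx), seq_along(W))) {
    stop("block spans must partition channels 1..C without gaps or overlaps",
         call. = FALSE)
  }
  vapply(spans, function(s) mean(W[seq(s[["start"]], s[["end"]])]), numeric(1))
}

#' Export per-channel gate diagnostics as a TSV table
#'
#' Writes columns `channel`, `block`, `mean_weight` where `mean_weight` is
#' the dataset-mean gate for each channel.
#'
#' @param W_matrix n x C matrix of per-protein gating vectors (see
#'   [afr_weights()]).
#' @param spans Channel spans as in [block_importance()].
#' @param path Output TSV path.
#' @return The written data.frame, invisibly.
#' @export
write_channel_weights <- function(W_matrix, spans, path) {
  C <- ncol(W_matrix)
  blk <- character(C)
  for (b in names(spans)) {
    s <- spans[[b]]
    blk[seq(s[["start"]], s[["end"]])] <- b
  }
  df <- data.frame(channel = seq_len(C), block = blk,
                   mean_weight = colMeans(W_matrix))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
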