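# Network definition: configuration, parameter initialization, and the
# pure-R reference forward pass (graph convolutions + self-attention
# readout + sigmoid head). The compiled core in src/ implements the same
# computation for training speed and is tested against these functions.

#' Model and training configuration
#'
#' Defaults follow the GraphSol-style GCN lineage: two graph-convolution
#' layers of width 256, a single-head tanh/softmax attention readout with a
#' 128-unit hidden layer, dropout 0.2 on the GCN activations during
#' training, AFR gating on the input channels, Adam at learning rate 5e-4
#' with unit global gradient-norm clipping,
#' and early stopping on an internal validation split (RMSE, patience 20,
#' at most 200 epochs).
#'
#' @param gcn_layers Number of graph-convolution layers (>= 1).
#' @param gcn_hidden Width of each GCN layer.
#' @param attention_hidden Hidden width of the readout's first FC layer.
#' @param attention_heads Number of softmax attention heads (default 1).
#' @param dropout Dropout rate in `[0, 1)` applied to GCN activations
#'   during training only.
#' @param use_afr Gate input channels with the AFR module.
#' @param afr_bias Trainable bias in the AFR interaction.
#' @param learning_rate Adam step size.
#' @param clip_norm Global gradient-norm clip per training step (0 disables
#'   clipping); stabilizes the ReLU layers against early activation
#'   collapse.
#' @param epochs Maximum training epochs.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement).
#' @param validation_fraction Fraction of the training set held out
#'   internally for early stopping (0 disables early stopping).
#' @param normalization Per-channel feature normalization scheme fitted on
#'   the training partition (see [normalize_block()]).
#' @param contact_threshold Contact-probability threshold for
#'   [build_graph()].
#' @param adjacency_normalization Adjacency scaling for [build_graph()].
#' @param blocks Enabled feature blocks, in any order (stacked canonically).
#' @param block_dims Named channel counts per block.
#' @param seed Seed controlling parameter initialization, the internal
#'   validation split, shuffling and dropout.
#' @return Object of class `hybridgcn_config`.
#' @export
hybridgcn_config <- function(gcn_layers = 2L, gcn_hidden = 256L,
                             attention_hidden = 128L, attention_heads = 1L,
                             dropout = 0.2, use_afr = TRUE, afr_bias = TRUE,
                             learning_rate = 5e-4, clip_norm = 1.0,
                             epochs = 200L,
                             patience = 20L, validation_fraction = 0.1,
                             normalization = "minmax_per_channel",
                             contact_threshold = 0,
                             adjacency_normalization = "sym_degree",
                             blocks = canonical_blocks(),
                             block_dims = default_block_dims(),
                             seed = 1L) {
  stopifnot(gcn_layers >= 1L, gcn_hidden >= 1L, attention_hidden >= 1L,
            attention_heads >= 1L, dropout >= 0, dropout < 1,
            learning_rate > 0, clip_norm >= 0, epochs >= 1L, patience >= 1L,
            validation_fraction >= 0, validation_fraction < 1)
  if (length(blocks) == 0L) stop("at least one feature block must be enabled",
                                 call. = FALSE)
  blocks <- match.arg(blocks, canonical_blocks(), several.ok = TRUE)
  missing_dims <- setdiff(blocks, names(block_dims))
  if (length(missing_dims)) {
    stop("no dimension declared for block(s): ",
         paste(missing_dims, collapse = ", "), call. = FALSE)
  }
  blocks <- canonical_blocks()[canonical_blocks() %in% blocks]
  structure(list(
    gcn_layers = as.integer(gcn_layers), gcn_hidden = as.integer(gcn_hidden),
    attention_hidden = as.integer(attention_hidden),
    attention_heads = as.integer(attention_heads), dropout = dropout,
    use_afr = isTRUE(use_afr), afr_bias = isTRUE(afr_bias),
    learning_rate = learning_rate, clip_norm = clip_norm,
    epochs = as.integer(epochs),
    patience = as.integer(patience),
    validation_fraction = validation_fraction,
    normalization = normalization, contact_threshold = contact_threshold,
    adjacency_normalization = adjacency_normalization,
    blocks = blocks, block_dims = block_dims[blocks], seed = as.integer(seed)),
    class = "hybridgcn_config")
}

#' Total hybrid channel count implied by a configuration
#'
#' @param config A `hybridgcn_config`.
#' @return Integer C, the sum of the enabled blocks' channel counts.
#' @export
n_channels <- function(config) as.integer(sum(config$block_dims))

#' @export
print.hybridgcn_config <- function(x, ...) {
  cat("<hybridgcn_config>\n")
  cat(sprintf("  blocks: %s (C = %d)\n", paste(x$blocks, collapse = "+"),
              n_channels(x)))
  cat(sprintf("  AFR: %s | GCN: %d x %d | attention: %d hidden, %d head(s) | dropout %.2f\n",
              if (x$use_afr) "on" else "off", x$gcn_layers, x$gcn_hidden,
              x$attention_hidden, x$attention_heads, x$dropout))
  cat(sprintf("  train: Adam lr=%g, <=%d epochs, patience %d, val fraction %.2f, seed %d\n",
              x$learning_rate, x$epochs, x$patience, x$validation_fraction,
              x$seed))
  invisible(x)
}

# He/Glorot-style initialization of all trainable parameters. Layout matches
# the compiled core: V, bv (AFR), Wg/bg (GCN layers), Wa/ba/Ua/ca (readout),
# wo/bo (output head).
init_params <- function(C, config) {
  set.seed(config$seed)
  d <- config$gcn_hidden
  ha <- config$attention_hidden
  k <- config$attention_heads
  dims_in <- c(C, rep(d, config$gcn_layers - 1L))
  Wg <- lapply(dims_in, function(din) matrix(rnorm(din * d, sd = sqrt(2 / din)),
                                             din, d))
  bg <- replicate(config$gcn_layers, numeric(d), simplify = FALSE)
  par <- list(
    Wg = Wg, bg = bg,
    Wa = matrix(rnorm(d * ha, sd = sqrt(1 / d)), d, ha),
    ba = numeric(ha),
    Ua = matrix(rnorm(ha * k, sd = sqrt(1 / ha)), ha, k),
    ca = numeric(k),
    wo = rnorm(k * d, sd = sqrt(1 / (k * d))),
    bo = 0)
  if (config$use_afr) {
    par$V <- matrix(rnorm(C * C, sd = 1 / sqrt(C)), C, C)
    par$bv <- numeric(C)
  }
  par
}

#' One graph-convolution layer
#'
#' Propagation rule `relu(A %*% X %*% W + b)`: the normalized adjacency
#' mixes each residue's features with its contact neighbours before the
#' linear map.
#'
#' @param X L x d_in node-feature matrix.
#' @param A L x L normalized adjacency (see [build_graph()]).
#' @param W d_in x d_out weight matrix.
#' @param b Optional bias vector of length d_out.
#' @param activation Apply the ReLU (`TRUE`, default) or return the linear
#'   pre-activation.
#' @return L x d_out matrix.
#' @export
gcn_layer <- function(X, A, W, b = NULL, activation = TRUE) {
  X <- as.matrix(X); A <- as.matrix(A); W <- as.matrix(W)
  if (ncol(A) != nrow(X)) stop("adjacency and node features disagree on L",
                               call. = FALSE)
  if (nrow(W) != ncol(X)) stop("weight matrix rows must match input channels",
                               call. = FALSE)
  Z <- A %*% X %*% W
  if (!is.null(b)) Z <- sweep(Z, 2L, b, `+`)
  if (activation) pmax(Z, 0) else Z
}

#' Self-attention readout
#'
#' Two fully connected layers with tanh and softmax activations produce a
#' probability distribution over residues; the pooled graph representation
#' is the attention-weighted sum of node states. With `k` heads the pooled
#' vector concatenates the per-head sums.
#'
#' @param X L x d node-state matrix (L >= 1).
#' @param params List with `Wa` (d x h), `ba` (h), `Ua` (h x k), `ca` (k).
#' @return List with `pooled` (length k*d) and `attention` (L x k matrix of
#'   non-negative weights, each column summing to 1).
#' @export
self_attention_readout <- function(X, params) {
  X <- as.matrix(X)
  if (nrow(X) == 0L) stop("empty graph: L must be >= 1", call. = FALSE)
  U <- tanh(sweep(X %*% params$Wa, 2L, params$ba, `+`))
  E <- sweep(U %*% params$Ua, 2L, params$ca, `+`)
  att <- apply(E, 2L, function(e) {
    ex <- exp(e - max(e))
    ex / sum(ex)
  })
  att <- matrix(att, nrow = nrow(X))
  pooled <- as.numeric(crossprod(X, att))  # d x k, column-major = head blocks
  list(pooled = pooled, attention = att)
}

#' Reference forward pass through the whole network
#'
#' Pure-R composition of the AFR gate, the GCN layers and the attention
#' readout on pre-built matrices. [predict.hybridgcn()] uses the compiled
#' equivalent; this function exists as the readable reference and for
#' inspecting intermediates.
#'
#' @param H L x C normalized hybrid feature matrix.
#' @param A L x L normalized adjacency.
#' @param params Parameter list (layout of `init_params`).
#' @param use_afr Apply the AFR gate before the first GCN layer.
#' @return List with `s_hat` (scalar in (0,1)), `attention` (length-L mean
#'   over heads, sums to 1), `afr` (a `channel_weights` object or `NULL`).
#' @export
hybridgcn_forward <- function(H, A, params, use_afr = TRUE) {
  afr <- NULL
  X <- as.matrix(H)
  if (use_afr) {
    out <- afr_forward(H, list(V = params$V, bv = params$bv, bias = TRUE))
    X <- out$R
    afr <- out$diagnostics
  }
  for (l in seq_along(params$Wg)) {
    X <- gcn_layer(X, A, params$Wg[[l]], params$bg[[l]])
  }
  ro <- self_attention_readout(X, params)
  z <- sum(params$wo * ro$pooled) + params$bo
  list(s_hat = stats::plogis(z), attention = rowMeans(ro$attention),
       afr = afr, pooled = ro$pooled)
}

# Turn protein records into the (H, A) matrix pairs consumed by the
# compiled core: normalize each enabled block with training-partition
# statistics, stack canonically, and build the normalized adjacency.
prepare_matrices <- function(records, config, stats) {
  blocks <- config$blocks
  spans <- block_spans_for(config$block_dims)
  Hs <- vector("list", length(records))
  As <- vector("list", length(records))
  for (i in seq_along(records)) {
    r <- records[[i]]
    missing <- setdiff(blocks, names(r$blocks))
    if (length(missing)) {
      stop(sprintf("protein '%s' lacks enabled block(s): %s", r$id,
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    fb <- lapply(blocks, function(b) {
      m <- r$blocks[[b]]
      if (ncol(m) != config$block_dims[[b]]) {
        stop(sprintf("protein '%s' block '%s': %d channels, config declares %d",
                     r$id, b, ncol(m), config$block_dims[[b]]), call. = FALSE)
      }
      m <- normalize_block(m, config$normalization,
                           stats = if (config$normalization == "none") NULL
                                   else stats$blocks[[b]])
      feature_block(b, m)
    })
    hf <- stack_features(fb)
    Hs[[i]] <- hf$matrix
    As[[i]] <- build_graph(r, threshold = config$contact_threshold,
                           normalization = config$adjacency_normalization)$adjacency
  }
  list(H = Hs, A = As,
       ids = vapply(records, `[[`, character(1), "id"),
       y = vapply(records, function(r)
         if (is.null(r$solubility)) NA_real_ else r$solubility, numeric(1)),
       spans = spans, C = as.integer(sum(config$block_dims)))
}
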