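# Shared fixtures: tiny random inputs built in code.

# random symmetric contact-probability matrix with zero diagonal
random_contact <- function(L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(runif(L * L), L, L)
  A <- (A + t(A)) / 2
  diag(A) <- 0
  A
}

# a small labeled protein record with arbitrary blocks
tiny_record <- function(id = "P1", L = 6, dims = c(ESM = 4, HMM = 5),
                        solubility = 0.6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  blocks <- lapply(dims, function(d) matrix(rnorm(L * d), L, d))
  protein_record(id, paste(rep("A", L), collapse = ""), blocks,
                 random_contact(L), solubility)
}

# small config matched to tiny_record dims, fast to train
tiny_config <- function(..., dims = c(ESM = 4, HMM = 5)) {
  defaults <- list(gcn_hidden = 8L, attention_hidden = 4L, epochs = 5L,
                   patience = 5L, dropout = 0, validation_fraction = 0,
                   blocks = names(dims), block_dims = dims)
  do.call(hybridgcn_config, utils::modifyList(defaults, list(...)))
}

# pure-loop reference for the AFR chain (pool, interaction, ReLU, sigmoid,
# reweight), independent of the package's vectorized implementations
afr_loop_oracle <- function(H, V, bv = NULL) {
  L <- nrow(H); C <- ncol(H)
  G <- numeric(C)
  for (c in seq_len(C)) {
    acc <- 0
    for (i in seq_len(L)) acc <- acc + H[i, c]
    G[c] <- acc / L
  }
  O <- numeric(C)
  for (cp in seq_len(C)) {
    acc <- if (is.null(bv)) 0 else bv[cp]
    for (c in seq_len(C)) acc <- acc + V[cp, c] * G[c]
    O[cp] <- acc
  }
  P <- ifelse(O > 0, O, 0)
  W <- 1 / (1 + exp(-P))
  R <- matrix(0, L, C)
  for (i in seq_len(L)) for (c in seq_len(C)) R[i, c] <- H[i, c] * W[c]
  list(G = G, O = O, P = P, W = W, R = R)
}

# brute-force confusion counts at the soluble-iff->=threshold convention
confusion_loop <- function(y, y_hat, threshold = 0.5) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(y)) {
    sol <- y[i] >= threshold
    pred <- y_hat[i] >= threshold
    if (sol && pred) tp <- tp + 1L
    else if (!sol && pred) fp <- fp + 1L
    else if (sol && !pred) fn <- fn + 1L
    else tn <- tn + 1L
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

# AUC as the proportion of concordant (soluble, insoluble) pairs, ties 1/2
auc_pairs_oracle <- function(y_bin, score) {
  pos <- which(y_bin); neg <- which(!y_bin)
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + (score[i] > score[j]) + 0.5 * (score[i] == score[j])
  }
  tot / (length(pos) * length(neg))
}
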