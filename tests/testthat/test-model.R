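test_that("gcn_layer follows the propagation rule", {
  set.seed(1)
  X <- matrix(abs(rnorm(4 * 3)), 4, 3)  # positive: ReLU is identity here
  expect_equal(gcn_layer(X, diag(4), diag(3)), X)
  # two structurally identical nodes get identical outputs
  A <- build_graph(matrix(c(0, 1, 1, 0), 2), threshold = 0)$adjacency
  Xs <- matrix(c(1, 1, 2, 2), 2, 2)   # identical rows
  W <- matrix(rnorm(2 * 3), 2, 3)
  out <- gcn_layer(Xs, A, W)
  expect_equal(out[1, ], out[2, ])
  # triple-loop oracle on a random 4-node case
  A <- build_graph(random_contact(4, seed = 2))$adjacency
  X <- matrix(rnorm(4 * 3), 4, 3)
  W <- matrix(rnorm(3 * 2), 3, 2)
  b <- rnorm(2)
  Z <- matrix(0, 4, 2)
  for (i in 1:4) for (j in 1:2) {
    for (k in 1:4) for (c in 1:3) Z[i, j] <- Z[i, j] + A[i, k] * X[k, c] * W[c, j]
    Z[i, j] <- Z[i, j] + b[j]
  }
  expect_equal(gcn_layer(X, A, W, b), pmax(Z, 0), tolerance = 1e-10)
  expect_error(gcn_layer(X, diag(3), W), "disagree on L")
})

test_that("self-attention readout yields a probability distribution", {
  set.seed(3)
  par <- list(Wa = matrix(rnorm(3 * 2), 3, 2), ba = rnorm(2),
              Ua = matrix(rnorm(2), 2, 1), ca = rnorm(1))
  # singleton graph: attention is exactly 1
  ro <- self_attention_readout(matrix(rnorm(3), 1, 3), par)
  expect_equal(as.numeric(ro$attention), 1)
  # identical node states: uniform attention 1/L
  X <- matrix(rep(c(1, -1, 2), each = 5), 5, 3)
  ro <- self_attention_readout(X, par)
  expect_equal(as.numeric(ro$attention), rep(0.2, 5))
  # random case: sums to 1, pooled equals the weighted-sum oracle
  X <- matrix(rnorm(6 * 3), 6, 3)
  ro <- self_attention_readout(X, par)
  expect_equal(sum(ro$attention), 1, tolerance = 1e-6)
  expect_true(all(ro$attention >= 0))
  pooled_loop <- numeric(3)
  for (c in 1:3) for (i in 1:6) {
    pooled_loop[c] <- pooled_loop[c] + ro$attention[i, 1] * X[i, c]
  }
  expect_equal(ro$pooled, pooled_loop, tolerance = 1e-10)
  expect_error(self_attention_readout(matrix(0, 0, 3), par), "empty graph")
})

test_that("the compiled forward pass matches the pure-R reference exactly", {
  set.seed(4)
  for (i in 1:10) {
    L <- sample(3:10, 1)
    C <- sample(3:7, 1)
    use_afr <- i %% 2 == 0
    cfg <- hybridgcn_config(gcn_layers = sample(1:3, 1),
                            gcn_hidden = sample(2:6, 1),
                            attention_hidden = 3, attention_heads = sample(1:2, 1),
                            blocks = "ESM", block_dims = c(ESM = C),
                            use_afr = use_afr, dropout = 0, seed = i)
    par <- hybridgcn:::init_params(C, cfg)
    H <- matrix(rnorm(L * C), L, C)
    A <- build_graph(random_contact(L))$adjacency
    rf <- hybridgcn_forward(H, A, par, use_afr)
    cf <- hybridgcn:::hg_forward_cpp(H, A, par, use_afr)
    expect_equal(rf$s_hat, cf$s_hat, tolerance = 1e-12)
    expect_equal(rf$attention, as.numeric(cf$attention), tolerance = 1e-14)
  }
})

test_that("predictions are strictly inside (0,1) and deterministic", {
  set.seed(5)
  recs <- lapply(1:8, function(i) tiny_record(sprintf("p%d", i), L = 5 + i))
  cfg <- tiny_config(seed = 42, dropout = 0.3, validation_fraction = 0.25,
                     epochs = 4)
  fit1 <- hybridgcn(recs, cfg)
  fit2 <- hybridgcn(recs, cfg)
  expect_identical(fit1$params, fit2$params)     # bitwise-identical training
  p1 <- predict(fit1, recs)
  p2 <- predict(fit2, recs)
  expect_identical(p1, p2)
  expect_true(all(p1 > 0 & p1 < 1))
})

test_that("s_hat is invariant under simultaneous residue permutation", {
  set.seed(6)
  for (i in 1:20) {
    L <- sample(4:12, 1)
    C <- 5
    cfg <- hybridgcn_config(gcn_hidden = 6, attention_hidden = 4,
                            blocks = "ESM", block_dims = c(ESM = C),
                            dropout = 0, seed = i)
    par <- hybridgcn:::init_params(C, cfg)
    H <- matrix(rnorm(L * C), L, C)
    A <- build_graph(random_contact(L))$adjacency
    perm <- sample(L)
    s1 <- hybridgcn:::hg_forward_cpp(H, A, par, TRUE)$s_hat
    s2 <- hybridgcn:::hg_forward_cpp(H[perm, ], A[perm, perm], par, TRUE)$s_hat
    expect_equal(s1, s2, tolerance = 1e-8)
  }
})

test_that("analytic gradients agree with central finite differences", {
  set.seed(7)
  L <- 5; C <- 4; y <- 0.3
  cfg <- hybridgcn_config(gcn_layers = 2, gcn_hidden = 3, attention_hidden = 3,
                          attention_heads = 2, blocks = "ESM",
                          block_dims = c(ESM = C), dropout = 0, seed = 8)
  par <- hybridgcn:::init_params(C, cfg)
  H <- matrix(rnorm(L * C), L, C)
  A <- build_graph(random_contact(L))$adjacency
  g <- hybridgcn:::hg_grad_cpp(H, A, par, TRUE, y)
  loss <- function(p) (hybridgcn:::hg_forward_cpp(H, A, p, TRUE)$s_hat - y)^2
  h <- 1e-5
  check <- function(getter, setter, gval) {
    for (j in seq_along(gval)) {
      p1 <- setter(par, j, h); p2 <- setter(par, j, -h)
      fd <- (loss(p1) - loss(p2)) / (2 * h)
      denom <- max(abs(fd), abs(gval[j]), 1e-6)
      expect_lt(abs(fd - gval[j]) / denom, 1e-4)
    }
  }
  for (nm in c("V", "bv", "Wa", "ba", "Ua", "ca", "wo", "bo")) {
    check(NULL, function(p, j, d) { p[[nm]][j] <- p[[nm]][j] + d; p }, g[[nm]])
  }
  for (l in 1:2) {
    check(NULL, function(p, j, d) { p$Wg[[l]][j] <- p$Wg[[l]][j] + d; p },
          g$Wg[[l]])
    check(NULL, function(p, j, d) { p$bg[[l]][j] <- p$bg[[l]][j] + d; p },
          g$bg[[l]])
  }
})

test_that("leave-one-out configurations keep channel bookkeeping consistent", {
  # shape audit: dropping any one block must thread a consistent C through
  # stacking, AFR and the first GCN layer
  set.seed(9)
  dims <- default_block_dims()
  rec <- tiny_record("p1", L = 7, dims = dims, seed = 10)
  for (drop in canonical_blocks()) {
    keep <- setdiff(canonical_blocks(), drop)
    cfg <- hybridgcn_config(gcn_hidden = 4, attention_hidden = 3,
                            blocks = keep, block_dims = dims[keep],
                            dropout = 0, seed = 1)
    expect_identical(n_channels(cfg), as.integer(111 - dims[[drop]]))
    par <- hybridgcn:::init_params(n_channels(cfg), cfg)
    expect_identical(nrow(par$V), 111L - dims[[drop]])
    expect_identical(nrow(par$Wg[[1]]), 111L - dims[[drop]])
    stats <- fit_normalization(list(rec), cfg$normalization, keep)
    prep <- hybridgcn:::prepare_matrices(list(rec), cfg, stats)
    expect_identical(ncol(prep$H[[1]]), 111L - dims[[drop]])
    s <- hybridgcn:::hg_forward_cpp(prep$H[[1]], prep$A[[1]], par, TRUE)$s_hat
    expect_true(s > 0 && s < 1)
  }
})

test_that("a missing enabled block names the protein and block", {
  rec <- tiny_record("prot7", dims = c(ESM = 4))
  cfg <- tiny_config()  # expects ESM and HMM
  expect_error(hybridgcn:::prepare_matrices(list(rec), cfg, NULL),
               "prot7.*HMM")
})
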