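test_that("the generator is deterministic under a fixed seed", {
  cfg <- sim_config(n_proteins = 4, length_range = c(6, 10),
                    block_dims = c(ESM = 4, HMM = 3),
                    informative_blocks = "ESM",
                    informative_channels_per_block = 2, seed = 5)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$ground_truth$informative_channels, 1:2)
})

test_that("generated records satisfy the data contracts", {
  cfg <- sim_config(n_proteins = 10, length_range = c(6, 12), seed = 6)
  sim <- simulate_dataset(cfg)
  for (r in sim$records) {
    L <- nrow(r$contact)
    expect_gte(L, 6); expect_lte(L, 12)
    expect_identical(r$contact, t(r$contact))
    expect_true(all(r$contact >= 0 & r$contact <= 1))
    expect_identical(diag(r$contact), rep(0, L))
    expect_gte(r$solubility, 0); expect_lte(r$solubility, 1)
    expect_identical(vapply(r$blocks, ncol, integer(1)), default_block_dims())
    expect_identical(nchar(r$sequence), L)
  }
  # ground-truth channels point at the leading ESM and HMM channels
  spans <- block_spans_for(default_block_dims())
  expect_identical(sim$ground_truth$informative_channels,
                   sort(c(spans$ESM[["start"]] + 0:2,
                          spans$HMM[["start"]] + 0:2)))
})

test_that("informative channel means out-correlate every noise channel", {
  # generator-level Monte-Carlo check: median over 10 seeds at n = 200
  seps <- vapply(1:10, function(seed) {
    cfg <- sim_config(n_proteins = 200, length_range = c(30, 80),
                      effect_size = 1.0, seed = seed)
    sim <- simulate_dataset(cfg)
    y <- vapply(sim$records, `[[`, numeric(1), "solubility")
    M <- t(vapply(sim$records, function(r)
      unlist(lapply(r$blocks, colMeans), use.names = FALSE), numeric(111)))
    cors <- abs(suppressWarnings(cor(M, y)))
    info <- sim$ground_truth$informative_channels
    min(cors[info]) - max(cors[-info])
  }, numeric(1))
  expect_gt(median(seps), 0)
})

test_that("effect_size 0 yields a null dataset", {
  cfg <- sim_config(n_proteins = 150, length_range = c(10, 20),
                    block_dims = c(ESM = 5), informative_blocks = "ESM",
                    informative_channels_per_block = 2, effect_size = 0,
                    seed = 7)
  sim <- simulate_dataset(cfg)
  y <- vapply(sim$records, `[[`, numeric(1), "solubility")
  M <- t(vapply(sim$records, function(r) colMeans(r$blocks$ESM), numeric(5)))
  cors <- abs(suppressWarnings(cor(M, y)))
  # no channel correlates beyond sampling noise (|r| ~ 2/sqrt(n))
  expect_lt(max(cors), 4 / sqrt(150))
})

test_that("vanishing noise makes labels a monotone function of the signal", {
  cfg <- sim_config(n_proteins = 120, length_range = c(20, 30),
                    block_dims = c(ESM = 4), informative_blocks = "ESM",
                    informative_channels_per_block = 2, effect_size = 3,
                    noise_sd = 1e-6, seed = 8)
  sim <- simulate_dataset(cfg)
  y <- vapply(sim$records, `[[`, numeric(1), "solubility")
  z <- vapply(sim$records, function(r) sum(colMeans(r$blocks$ESM[, 1:2])),
              numeric(1))
  expect_gt(cor(z, y, method = "spearman"), 0.95)
})

test_that("relevance recovery is neutral for zero interaction kernels", {
  sim <- simulate_dataset(sim_config(n_proteins = 8, length_range = c(6, 9),
                                     block_dims = c(ESM = 4, HMM = 3),
                                     informative_blocks = "ESM",
                                     informative_channels_per_block = 2,
                                     seed = 9))
  cfg <- tiny_config(dims = c(ESM = 4, HMM = 3), epochs = 1)
  fit <- hybridgcn(sim$records, cfg)
  fit$params$V[] <- 0
  fit$params$bv[] <- 0
  rep <- relevance_recovery_report(fit, sim$records, sim$ground_truth)
  expect_equal(rep$gap, 0)
  expect_equal(rep$mean_informative, 0.5)
  # and it refuses to run without AFR
  cfg2 <- tiny_config(dims = c(ESM = 4, HMM = 3), epochs = 1, use_afr = FALSE)
  fit2 <- hybridgcn(sim$records, cfg2)
  expect_error(relevance_recovery_report(fit2, sim$records, sim$ground_truth),
               "use_afr")
})

test_that("held-out fit quality does not degrade as effect size grows", {
  # monotonicity of recoverable signal: median over 3 seeds at each level
  r2_at <- function(effect, seed) {
    cfg <- sim_config(n_proteins = 120, length_range = c(10, 16),
                      block_dims = c(ESM = 6, HMM = 6),
                      informative_blocks = c("ESM", "HMM"),
                      informative_channels_per_block = 2,
                      effect_size = effect, seed = seed)
    sim <- simulate_dataset(cfg)
    y <- vapply(sim$records, `[[`, numeric(1), "solubility")
    set.seed(seed)
    test_i <- sample(120, 30)
    mcfg <- hybridgcn_config(gcn_hidden = 16, attention_hidden = 8,
                             epochs = 60, patience = 60, dropout = 0,
                             validation_fraction = 0,
                             blocks = c("ESM", "HMM"),
                             block_dims = c(ESM = 6, HMM = 6), seed = seed)
    fit <- hybridgcn(sim$records[-test_i], mcfg)
    r2(y[test_i], predict(fit, sim$records[test_i]))
  }
  meds <- vapply(c(0, 0.5, 1.0), function(e)
    median(vapply(1:3, function(s) r2_at(e, s), numeric(1))), numeric(1))
  expect_lte(meds[1], meds[2] + 0.05)
  expect_lte(meds[2], meds[3] + 0.05)
})
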