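test_that("feature matrices round-trip through disk at full precision", {
  set.seed(1)
  m <- matrix(rnorm(3 * 7), 3, 7)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_feature_matrix(m, f)
  blk <- load_feature_matrix(f, "AAPHY7", 7)
  expect_s3_class(blk, "feature_block")
  expect_identical(dim(blk$matrix), c(3L, 7L))
  expect_equal(blk$matrix, m, tolerance = 0)
  # write(load(f)) reproduces the file verbatim
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_feature_matrix(blk, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("loader rejects wrong dimensions and non-numeric cells", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("1\t2\t3", "4\t5\t6"), f)
  expect_error(load_feature_matrix(f, "AAPHY7", 7), "found 3.*expected 7")
  writeLines(c("1\t2\t3", "4\tNA\t6"), f)
  expect_error(load_feature_matrix(f, "AAPHY7", 3), "row 2, column 2")
  writeLines(c("1,2,3", "4,x,6"), f)
  expect_error(load_feature_matrix(f, "AAPHY7", 3), "'x' at row 2, column 2")
  # comma-delimited accepted
  writeLines(c("1,2,3", "4,5,6"), f)
  expect_equal(load_feature_matrix(f, "AAPHY7", 3)$matrix,
               matrix(1:6, 2, 3, byrow = TRUE))
})

test_that("stacking concatenates in canonical order with exact spans", {
  # canonical dimensions sum to the 111-channel hybrid feature
  set.seed(2)
  L <- 4
  dims <- default_block_dims()
  blocks <- lapply(names(dims), function(b)
    feature_block(b, matrix(rnorm(L * dims[[b]]), L, dims[[b]])))
  h <- stack_features(rev(blocks))  # supply out of order
  expect_identical(h$C, 111L)
  expect_identical(names(h$block_spans), canonical_blocks())
  # slicing at the spans recovers each input block bit-exactly
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    s <- h$block_spans[[b$name]]
    expect_identical(h$matrix[, s[["start"]]:s[["end"]]], b$matrix)
  }
  # spans partition 1..C
  idx <- unlist(lapply(h$block_spans, function(s) s[["start"]]:s[["end"]]),
                use.names = FALSE)
  expect_identical(sort(idx), 1:111)
})

test_that("stacking validates block compatibility", {
  b1 <- feature_block("ESM", matrix(1, 5, 20))
  b2 <- feature_block("HMM", matrix(1, 4, 30))
  expect_error(stack_features(list(b1, b2)), "disagree on sequence length")
  expect_error(stack_features(list(b1, b1)), "duplicate")
  # single block: identity stacking (individual-feature mode)
  h <- stack_features(list(b1))
  expect_identical(h$C, 20L)
  expect_identical(unname(h$block_spans$ESM), c(1L, 20L))
  expect_identical(h$matrix, b1$matrix)
  # two small blocks with known entries land in the right columns
  a <- feature_block("ESM", matrix(1:10, 5, 2), 2)
  b <- feature_block("BLOSUM", matrix(101:115, 5, 3), 3)
  h2 <- stack_features(list(b, a))
  expect_identical(h2$matrix[, 1:2], a$matrix)
  expect_identical(h2$matrix[, 3:5], b$matrix)
})

test_that("per-channel normalization follows the declared scheme", {
  m <- matrix(c(1, 2, 3, 5, 5, 5), 3, 2)  # second channel constant
  expect_identical(normalize_block(m, "none"), m)
  mm <- normalize_block(m, "minmax_per_channel")
  expect_equal(mm[, 1], c(0, 0.5, 1))
  expect_equal(mm[, 2], c(0, 0, 0))      # constant channel maps to 0
  zs <- normalize_block(m, "zscore_per_channel")
  expect_equal(mean(zs[, 1]), 0)
  expect_equal(sd(zs[, 1]), 1)
  expect_equal(zs[, 2], c(0, 0, 0))      # no division by zero
  expect_error(normalize_block(m, "quantile"), "arg")
})

test_that("training statistics transfer to test data without clipping", {
  train <- list(tiny_record("a", L = 10, seed = 3),
                tiny_record("b", L = 8, seed = 4))
  stats <- fit_normalization(train, "minmax_per_channel")
  # training data lands in [0,1] per channel
  tr_norm <- normalize_block(train[[1]]$blocks$ESM, "minmax_per_channel",
                             stats$blocks$ESM)
  expect_true(all(tr_norm >= 0 & tr_norm <= 1))
  # out-of-range test values pass through un-clipped
  extreme <- matrix(100, 2, 4)
  te_norm <- normalize_block(extreme, "minmax_per_channel", stats$blocks$ESM)
  expect_true(all(te_norm > 1))
})

test_that("graph construction matches hand-computed degree normalization", {
  g <- build_graph(matrix(c(0, 1, 1, 0), 2), threshold = 0)
  expect_equal(g$adjacency, matrix(0.5, 2, 2))
  # isolated nodes with self-loops give the identity
  expect_warning(g2 <- build_graph(matrix(0, 3, 3)), "self-loops only")
  expect_equal(g2$adjacency, diag(3))
  # row-stochastic variant: rows sum to 1
  g3 <- build_graph(random_contact(6, seed = 5),
                    normalization = "row_stochastic")
  expect_equal(rowSums(g3$adjacency), rep(1, 6))
  expect_error(build_graph(matrix(0, 2, 2), threshold = 1), "\\[0, 1\\)")
  expect_warning(build_graph(matrix(c(0, .1, .1, 0), 2), threshold = 0.5),
                 "self-loops only")
})

test_that("sym_degree adjacency of random maps has spectral radius <= 1", {
  set.seed(6)
  for (i in 1:10) {
    A <- random_contact(10)
    adj <- build_graph(A)$adjacency
    expect_equal(adj, t(adj))
    ev <- eigen(adj, symmetric = TRUE, only.values = TRUE)$values
    expect_lte(max(abs(ev)), 1 + 1e-10)
    expect_false(any(!is.finite(adj)))
  }
})

test_that("protein records validate cross-field consistency", {
  blocks <- list(ESM = matrix(0, 5, 20))
  expect_error(protein_record("p", "AAAAA", blocks, matrix(0, 4, 4)),
               "5 rows.*L=4")
  expect_error(protein_record("p", "AAAA", blocks, matrix(0, 5, 5)),
               "length 4")
  expect_error(protein_record("p", "AAAAA", blocks, matrix(0, 5, 5),
                              solubility = 1.2), "\\[0,1\\]")
  asym <- matrix(0, 5, 5); asym[1, 2] <- 0.5
  expect_error(protein_record("p", "AAAAA", blocks, asym), "symmetric")
})

test_that("a simulated dataset round-trips through the on-disk dialect", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_proteins = 3, length_range = c(6, 9),
                    block_dims = c(ESM = 4, PSSM = 3),
                    informative_blocks = "ESM",
                    informative_channels_per_block = 2, seed = 9)
  sim <- simulate_dataset(cfg, dir = dir)
  expect_true(file.exists(file.path(dir, "labels.tsv")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  back <- load_dataset(dir)
  expect_identical(names(back), names(sim$records))
  for (id in names(back)) {
    expect_equal(back[[id]]$blocks$ESM, sim$records[[id]]$blocks$ESM)
    expect_equal(back[[id]]$contact, sim$records[[id]]$contact)
    expect_equal(back[[id]]$solubility, sim$records[[id]]$solubility)
    expect_identical(back[[id]]$sequence, sim$records[[id]]$sequence)
  }
  # enabled blocks come from the manifest, and absence is a hard error
  file.remove(file.path(dir, "SYN0001.PSSM.tsv"))
  expect_error(load_dataset(dir), "missing feature file.*PSSM")
})
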