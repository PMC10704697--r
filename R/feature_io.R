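# Reading, validating, normalizing and stacking the per-residue feature
# blocks, and turning a contact-probability map into a GCN-ready graph.

#' Canonical feature blocks and their default channel counts
#'
#' The six per-residue feature blocks, in the canonical stacking order used
#' throughout the package: protein language-model probabilities (ESM, 20),
#' BLOSUM62 substitution rows (BLOSUM, 20), AAPHY7 physicochemical
#' properties (AAPHY7, 7), PSSM profile (PSSM, 20), HMM profile (HMM, 30)
#' and predicted structural properties (SPIDER3, 14). Channel counts are
#' overridable wherever a `block_dims` argument is accepted.
#'
#' @return Named integer vector of per-block channel counts, in canonical
#'   stacking order.
#' @export
#' @examples
#' default_block_dims()
#' sum(default_block_dims()) # 111 hybrid channels
default_block_dims <- function() {
  c(ESM = 20L, BLOSUM = 20L, AAPHY7 = 7L, PSSM = 20L, HMM = 30L, SPIDER3 = 14L)
}

#' @rdname default_block_dims
#' @export
canonical_blocks <- function() names(default_block_dims())

#' Construct a per-residue feature block
#'
#' @param name Block name, one of `canonical_blocks()`.
#' @param matrix Real L x d matrix of per-residue features (rows = residues).
#' @param d Declared channel count; defaults to `ncol(matrix)`.
#' @return An object of class `feature_block`.
#' @export
feature_block <- function(name, matrix, d = ncol(matrix)) {
  name <- match.arg(name, canonical_blocks())
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  if (ncol(matrix) != d) {
    stop(sprintf("feature block '%s': found %d channels, declared %d",
                 name, ncol(matrix), d), call. = FALSE)
  }
  if (!all(is.finite(matrix))) {
    stop(sprintf("feature block '%s': non-finite entries", name), call. = FALSE)
  }
  structure(list(name = name, matrix = matrix, d = as.integer(d)),
            class = "feature_block")
}

#' Load one feature matrix from a delimited text file
#'
#' Reads a whitespace- or comma-delimited numeric matrix (one row per
#' residue, no header) and validates it against the declared channel count
#' for the block.
#'
#' @param path File path.
#' @param name Block name (see [canonical_blocks()]).
#' @param expected_dim Declared channel count for this block.
#' @return A `feature_block` of shape L x `expected_dim`.
#' @export
load_feature_matrix <- function(path, name, expected_dim) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty feature file: ", path, call. = FALSE)
  toks <- strsplit(trimws(lines), "[,[:space:]]+")
  ncols <- lengths(toks)
  if (length(unique(ncols)) != 1L) {
    stop(sprintf("ragged matrix in %s: rows have %s columns", path,
                 paste(unique(ncols), collapse = "/")), call. = FALSE)
  }
  vals <- suppressWarnings(lapply(toks, as.numeric))
  for (i in seq_along(vals)) {
    bad <- which(!is.finite(vals[[i]]))
    if (length(bad)) {
      stop(sprintf("non-numeric cell '%s' at row %d, column %d of %s",
                   toks[[i]][bad[1]], i, bad[1], path), call. = FALSE)
    }
  }
  m <- do.call(rbind, vals)
  if (ncol(m) != expected_dim) {
    stop(sprintf("feature block '%s' in %s: found %d channels, expected %d",
                 name, path, ncol(m), expected_dim), call. = FALSE)
  }
  feature_block(name, m, expected_dim)
}

#' Write a feature matrix as tab-delimited text
#'
#' Values are printed with 17 significant digits so that a load/write/load
#' round trip reproduces the doubles exactly.
#'
#' @param x A `feature_block` or a plain numeric matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(x, path) {
  m <- if (inherits(x, "feature_block")) x$matrix else as.matrix(x)
  lines <- apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Stack feature blocks into the hybrid feature matrix
#'
#' Column-wise concatenation of the supplied blocks in canonical order
#' (ESM, BLOSUM, AAPHY7, PSSM, HMM, SPIDER3), regardless of the order in
#' which they are supplied. The result records each block's channel span so
#' channel indices are reproducible across runs and ablation configurations.
#'
#' @param blocks List of `feature_block` objects sharing the same number of
#'   rows (residues). Any non-empty subset of the canonical blocks.
#' @return An object of class `hybrid_feature`: list with `matrix` (L x C),
#'   `block_spans` (named list of `c(start, end)` 1-based inclusive column
#'   ranges) and `C`.
#' @export
#' @examples
#' b1 <- feature_block("ESM", matrix(rnorm(10 * 20), 10))
#' b2 <- feature_block("HMM", matrix(rnorm(10 * 30), 10))
#' h <- stack_features(list(b1, b2))
#' h$C          # 50
#' h$block_spans$HMM
stack_features <- function(blocks) {
  if (inherits(blocks, "feature_block")) blocks <- list(blocks)
  stopifnot(length(blocks) >= 1L)
  nm <- vapply(blocks, function(b) b$name, character(1))
  if (anyDuplicated(nm)) {
    stop("duplicate feature block(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  ord <- order(match(nm, canonical_blocks()))
  blocks <- blocks[ord]
  nm <- nm[ord]
  Ls <- vapply(blocks, function(b) nrow(b$matrix), integer(1))
  if (length(unique(Ls)) != 1L) {
    stop("feature blocks disagree on sequence length L: ",
         paste(sprintf("%s=%d", nm, Ls), collapse = ", "), call. = FALSE)
  }
  mats <- lapply(blocks, `[[`, "matrix")
  H <- do.call(cbind, mats)
  dims <- vapply(blocks, `[[`, integer(1), "d")
  ends <- cumsum(dims)
  starts <- ends - dims + 1L
  spans <- Map(function(s, e) c(start = s, end = e), starts, ends)
  names(spans) <- nm
  structure(list(matrix = H, block_spans = spans, C = as.integer(sum(dims))),
            class = "hybrid_feature")
}

#' Channel spans for a set of enabled blocks
#'
#' @param block_dims Named integer vector of block dimensions (subset of the
#'   canonical blocks, any order; stacked canonically).
#' @return Named list of `c(start, end)` 1-based inclusive channel ranges.
#' @export
block_spans_for <- function(block_dims) {
  nm <- names(block_dims)
  ord <- order(match(nm, canonical_blocks()))
  block_dims <- block_dims[ord]
  ends <- cumsum(as.integer(block_dims))
  starts <- ends - as.integer(block_dims) + 1L
  spans <- Map(function(s, e) c(start = s, end = e), starts, ends)
  names(spans) <- names(block_dims)
  spans
}

#' Normalize a feature block per channel
#'
#' Normalization statistics must come from the training partition; pass the
#' `stats` produced by [fit_normalization()] when transforming validation or
#' test data. With `stats = NULL` the statistics are computed from the block
#' itself. No clipping is applied, so out-of-training-range values on test
#' data may fall outside \[0,1\] under min-max scaling.
#'
#' @param block A `feature_block` (or plain matrix).
#' @param scheme One of `"none"`, `"minmax_per_channel"`,
#'   `"zscore_per_channel"`.
#' @param stats Optional per-channel statistics: list with `min`/`max`
#'   (minmax) or `mean`/`sd` (zscore) vectors.
#' @return Object of the same type with the normalized matrix. Constant
#'   channels map to 0 under both non-trivial schemes.
#' @export
normalize_block <- function(block, scheme = c("none", "minmax_per_channel",
                                              "zscore_per_channel"),
                            stats = NULL) {
  scheme <- match.arg(scheme)
  m <- if (inherits(block, "feature_block")) block$matrix else as.matrix(block)
  if (scheme == "minmax_per_channel") {
    lo <- if (is.null(stats)) apply(m, 2L, min) else stats$min
    hi <- if (is.null(stats)) apply(m, 2L, max) else stats$max
    rng <- hi - lo
    out <- sweep(m, 2L, lo, `-`)
    out <- sweep(out, 2L, ifelse(rng > 0, rng, 1), `/`)
    out[, rng == 0] <- 0
  } else if (scheme == "zscore_per_channel") {
    mu <- if (is.null(stats)) colMeans(m) else stats$mean
    sdv <- if (is.null(stats)) apply(m, 2L, stats::sd) else stats$sd
    out <- sweep(m, 2L, mu, `-`)
    out <- sweep(out, 2L, ifelse(sdv > 0, sdv, 1), `/`)
    out[, sdv == 0] <- 0
  } else {
    out <- m
  }
  if (inherits(block, "feature_block")) {
    block$matrix <- out
    block
  } else {
    out
  }
}

#' Fit per-channel normalization statistics on the training partition
#'
#' Pools all residues of all training proteins per block and channel.
#'
#' @param records List of `protein_record` objects (the training partition).
#' @param scheme Normalization scheme (see [normalize_block()]).
#' @param blocks Block names to fit; defaults to the blocks present in the
#'   first record.
#' @return Object of class `hgcn_norm_stats`: per-block statistic lists.
#' @export
fit_normalization <- function(records, scheme = "minmax_per_channel",
                              blocks = NULL) {
  scheme <- match.arg(scheme,
                      c("none", "minmax_per_channel", "zscore_per_channel"))
  if (is.null(blocks)) blocks <- names(records[[1]]$blocks)
  per_block <- lapply(blocks, function(b) {
    pooled <- do.call(rbind, lapply(records, function(r) r$blocks[[b]]))
    switch(scheme,
      none = list(),
      minmax_per_channel = list(min = apply(pooled, 2L, min),
                                max = apply(pooled, 2L, max)),
      zscore_per_channel = list(mean = colMeans(pooled),
                                sd = apply(pooled, 2L, stats::sd)))
  })
  names(per_block) <- blocks
  structure(list(scheme = scheme, blocks = per_block),
            class = "hgcn_norm_stats")
}

#' Construct a protein record
#'
#' @param id Protein identifier.
#' @param sequence Amino-acid string of length L (may be `NA` when only
#'   matrices are available).
#' @param blocks Named list of L x d feature matrices (names from
#'   [canonical_blocks()]).
#' @param contact L x L contact-probability matrix in \[0,1\], symmetric.
#' @param solubility Optional label in \[0,1\].
#' @return Object of class `protein_record`.
#' @export
protein_record <- function(id, sequence, blocks, contact, solubility = NULL) {
  contact <- as.matrix(contact)
  L <- nrow(contact)
  if (ncol(contact) != L) stop("contact map must be square", call. = FALSE)
  if (max(abs(contact - t(contact))) > 1e-6) {
    stop(sprintf("contact map of '%s' is not symmetric within 1e-6", id),
         call. = FALSE)
  }
  if (min(contact) < 0 || max(contact) > 1) {
    stop(sprintf("contact probabilities of '%s' outside [0,1]", id),
         call. = FALSE)
  }
  for (b in names(blocks)) {
    blocks[[b]] <- as.matrix(blocks[[b]])
    if (nrow(blocks[[b]]) != L) {
      stop(sprintf("block '%s' of '%s' has %d rows but contact map implies L=%d",
                   b, id, nrow(blocks[[b]]), L), call. = FALSE)
    }
  }
  if (!is.na(sequence) && nchar(sequence) != L) {
    stop(sprintf("sequence of '%s' has length %d but matrices imply L=%d",
                 id, nchar(sequence), L), call. = FALSE)
  }
  if (!is.null(solubility)) {
    if (!is.finite(solubility) || solubility < 0 || solubility > 1) {
      stop(sprintf("solubility of '%s' must lie in [0,1]", id), call. = FALSE)
    }
  }
  structure(list(id = id, sequence = sequence, blocks = blocks,
                 contact = contact, solubility = solubility),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s  L=%d  blocks: %s  solubility: %s\n",
              x$id, nrow(x$contact), paste(names(x$blocks), collapse = ","),
              if (is.null(x$solubility)) "NA" else sprintf("%.3f", x$solubility)))
  invisible(x)
}

#' Build the protein graph from a contact map
#'
#' Entries of the raw contact map strictly below `threshold` are zeroed,
#' unit self-loops are added, and the adjacency is normalized. The default
#' (`threshold = 0`) keeps the full probability-weighted adjacency, using
#' every possible residue pair at its predicted contact probability.
#'
#' @param record A `protein_record`, or a raw L x L contact matrix.
#' @param node_features Optional L x C node-feature matrix to attach.
#' @param threshold Contact-probability threshold in `[0, 1)`.
#' @param normalization `"sym_degree"` for the symmetric degree scaling
#'   D^-1/2 (A + I) D^-1/2, `"row_stochastic"` for D^-1 (A + I), or
#'   `"none"`.
#' @return Object of class `protein_graph`: `adjacency` (normalized),
#'   `raw_contact`, `node_features`.
#' @export
#' @examples
#' g <- build_graph(matrix(c(0, 1, 1, 0), 2), threshold = 0)
#' g$adjacency # all entries 0.5
build_graph <- function(record, node_features = NULL, threshold = 0,
                        normalization = c("sym_degree", "row_stochastic",
                                          "none")) {
  normalization <- match.arg(normalization)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold >= 1) {
    stop("threshold must lie in [0, 1); a threshold of 1 would erase all contacts",
         call. = FALSE)
  }
  contact <- if (inherits(record, "protein_record")) record$contact
             else as.matrix(record)
  A <- (contact + t(contact)) / 2   # kill floating-point asymmetry
  diag(A) <- 0
  A[A < threshold] <- 0
  if (all(A == 0) && nrow(A) > 1L) {
    warning("all contacts removed by thresholding; proceeding with self-loops only",
            call. = FALSE)
  }
  diag(A) <- 1
  L <- nrow(A)
  adj <- switch(normalization,
    none = A,
    row_stochastic = A / rowSums(A),
    sym_degree = {
      dinv <- 1 / sqrt(rowSums(A))
      A * (dinv %o% dinv)
    })
  if (!is.null(node_features)) {
    node_features <- as.matrix(node_features)
    if (nrow(node_features) != L) {
      stop("node_features rows must equal the contact-map dimension", call. = FALSE)
    }
  }
  structure(list(adjacency = adj, raw_contact = contact,
                 node_features = node_features,
                 threshold = threshold, normalization = normalization),
            class = "protein_graph")
}

#' Read and write the two-column solubility label table
#'
#' Format: tab-separated, header `id<TAB>solubility`, one protein per line.
#'
#' @param path File path.
#' @return `read_labels`: data.frame with columns `id`, `solubility`.
#' @export
read_labels <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "numeric"))
  if (!identical(names(df), c("id", "solubility"))) {
    stop("labels file must have header 'id<TAB>solubility'", call. = FALSE)
  }
  if (any(!is.finite(df$solubility) | df$solubility < 0 | df$solubility > 1)) {
    stop("labels must lie in [0,1]", call. = FALSE)
  }
  df
}

#' @param labels data.frame with columns `id`, `solubility`.
#' @rdname read_labels
#' @export
write_labels <- function(labels, path) {
  utils::write.table(labels[, c("id", "solubility")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a dataset manifest (YAML or JSON)
#'
#' The manifest lists enabled blocks, block dimensions, the normalization
#' scheme and the contact threshold for a dataset directory.
#'
#' @param path Manifest path (`.yaml`/`.yml` or `.json`).
#' @return Named list of settings.
#' @export
read_manifest <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

#' Load a dataset directory in the package's on-disk dialect
#'
#' Expects `labels.tsv`, optionally `sequences.fasta`, and per protein one
#' `<id>.<BLOCK>.tsv` file per enabled block plus `<id>.contact.tsv`.
#' Missing files for enabled blocks are a hard error; blocks are disabled
#' via the manifest/`blocks` argument, never by absence.
#'
#' @param dir Dataset directory.
#' @param blocks Enabled block names; defaults to the manifest's `blocks`
#'   entry or all canonical blocks.
#' @param block_dims Named channel counts; defaults to the manifest or
#'   [default_block_dims()].
#' @return List of `protein_record` objects.
#' @export
load_dataset <- function(dir, blocks = NULL, block_dims = NULL) {
  manifest_path <- c(file.path(dir, "manifest.yaml"),
                     file.path(dir, "manifest.json"))
  manifest <- NULL
  for (mp in manifest_path) if (file.exists(mp)) manifest <- read_manifest(mp)
  if (is.null(block_dims)) {
    block_dims <- if (!is.null(manifest$block_dims))
      unlist(manifest$block_dims) else default_block_dims()
  }
  if (is.null(blocks)) {
    blocks <- if (!is.null(manifest$blocks)) unlist(manifest$blocks)
              else names(block_dims)
  }
  labels <- read_labels(file.path(dir, "labels.tsv"))
  seqs <- NULL
  fasta <- file.path(dir, "sequences.fasta")
  if (file.exists(fasta)) {
    fa <- seqinr::read.fasta(fasta, seqtype = "AA", as.string = TRUE)
    seqs <- setNames(toupper(vapply(fa, `[[`, character(1), 1L)), names(fa))
  }
  records <- lapply(seq_len(nrow(labels)), function(i) {
    id <- labels$id[i]
    bl <- lapply(blocks, function(b) {
      p <- file.path(dir, sprintf("%s.%s.tsv", id, b))
      if (!file.exists(p)) {
        stop(sprintf("missing feature file for protein '%s', block '%s': %s",
                     id, b, p), call. = FALSE)
      }
      load_feature_matrix(p, b, block_dims[[b]])$matrix
    })
    names(bl) <- blocks
    cpath <- file.path(dir, sprintf("%s.contact.tsv", id))
    if (!file.exists(cpath)) {
      stop(sprintf("missing contact map for protein '%s': %s", id, cpath),
           call. = FALSE)
    }
    contact <- as.matrix(utils::read.table(cpath, sep = "\t"))
    dimnames(contact) <- NULL
    protein_record(id, if (!is.null(seqs)) seqs[[id]] else NA_character_,
                   bl, contact, labels$solubility[i])
  })
  names(records) <- labels$id
  records
}
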