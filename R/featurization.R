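# Feature-matrix assembly and train-frozen preprocessing (correlated-feature
# removal at |r| >= 0.90, zero-variance removal, standardization).

#' Featurization configuration
#'
#' @param blocks structural blocks to compute: subset of `"2D"`, `"FP"`,
#'   `"COMP"`.
#' @param fp_bits circular-fingerprint length.
#' @param fp_radius circular-fingerprint radius in bonds.
#' @param correlation_cutoff Pearson |r| at or above which the later-scanned
#'   feature of a pair is dropped during preprocessing.
#' @return a `feature_config` list.
#' @export
feature_config <- function(blocks = c("2D", "FP", "COMP"), fp_bits = 1000,
                           fp_radius = 2, correlation_cutoff = 0.90) {
  structure(list(blocks = blocks, fp_bits = fp_bits, fp_radius = fp_radius,
                 correlation_cutoff = correlation_cutoff),
            class = "feature_config")
}

#' Inverse temperature feature
#'
#' The external feature carrying temperature into the models: by the Vogel
#' picture, log-viscosity is approximately linear in `1/(T - C)`, so `1/T`
#' is the natural temperature input.
#'
#' @param T_K temperature(s) in Kelvin; must be positive.
#' @return `1/T_K` in 1/K.
#' @export
inverse_temperature <- function(T_K) {
  if (any(!is.finite(T_K)) || any(T_K <= 0)) {
    stop_ctx("temperature must be positive and finite (Kelvin)")
  }
  1 / T_K
}

.new_feature_matrix <- function(values, block_tags, row_keys) {
  stopifnot(ncol(values) == length(block_tags))
  structure(list(values = values, feature_names = colnames(values),
                 block_tags = block_tags, row_keys = row_keys),
            class = "feature_matrix")
}

#' @method print feature_matrix
#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix: %d rows x %d features (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s:%d", names(table(x$block_tags)),
                            table(x$block_tags)), collapse = ", ")))
  invisible(x)
}

#' Assemble the full feature matrix for a curated dataset
#'
#' Structure features are computed once per unique compound and broadcast to
#' all of its records; inverse temperature is always appended as an external
#' (`EXT`) column; optional external blocks (e.g. MD descriptors) are joined
#' by (compound_id, temperature).
#'
#' @param dataset a `curated_dataset` (see [curate()]), or any data.frame
#'   with `smiles`, `temperature_K` and `compound_id` columns.
#' @param external_blocks optional data.frame with `compound_id`,
#'   `temperature_K` and numeric descriptor columns; must cover every row.
#' @param config a [feature_config()].
#' @param cache optional molecule cache.
#' @return a `feature_matrix` with named columns and block tags in
#'   `{2D, FP, COMP, EXT, MD}`.
#' @export
assemble_feature_matrix <- function(dataset, external_blocks = NULL,
                                    config = feature_config(), cache = NULL) {
  if (!"compound_id" %in% names(dataset)) {
    stop_ctx("dataset must carry compound_id (run curate() first)")
  }
  n <- nrow(dataset)
  if (is.null(cache)) cache <- molecule_cache()

  uniq <- !duplicated(dataset$compound_id)
  u_ids <- dataset$compound_id[uniq]
  u_smi <- dataset$smiles[uniq]
  mols <- cache(u_smi)

  struct <- NULL
  tags <- character(0)
  if (length(config$blocks) > 0) {
    rows <- lapply(seq_along(u_smi), function(i) {
      compute_structure_features(u_smi[i], config, mol = mols[[i]])
    })
    tags <- attr(rows[[1]], "block")
    struct <- do.call(rbind, lapply(rows, as.numeric))
    colnames(struct) <- names(rows[[1]])
    rownames(struct) <- u_ids
    struct <- struct[match(dataset$compound_id, u_ids), , drop = FALSE]
  } else {
    struct <- matrix(numeric(0), nrow = n, ncol = 0)
  }

  inv_t <- matrix(inverse_temperature(dataset$temperature_K), ncol = 1,
                  dimnames = list(NULL, "inv_temperature"))
  values <- cbind(struct, inv_t)
  tags <- c(tags, "EXT")

  if (!is.null(external_blocks)) {
    keycols <- c("compound_id", "temperature_K")
    if (!all(keycols %in% names(external_blocks))) {
      stop_ctx("external_blocks must have compound_id and temperature_K keys")
    }
    key_data <- paste(dataset$compound_id, signif(dataset$temperature_K, 10))
    key_ext <- paste(external_blocks$compound_id,
                     signif(external_blocks$temperature_K, 10))
    idx <- match(key_data, key_ext)
    if (anyNA(idx)) {
      stop_ctx("external block missing %d of %d (compound, temperature) rows",
               sum(is.na(idx)), n)
    }
    ext_cols <- setdiff(names(external_blocks), keycols)
    ext <- as.matrix(external_blocks[idx, ext_cols, drop = FALSE])
    rownames(ext) <- NULL
    values <- cbind(values, ext)
    tags <- c(tags, rep("MD", length(ext_cols)))
  }

  if (anyNA(values)) stop_ctx("feature matrix contains missing values")
  if (anyDuplicated(colnames(values))) stop_ctx("duplicate feature names")
  rownames(values) <- NULL
  .new_feature_matrix(values, tags,
                      data.frame(compound_id = dataset$compound_id,
                                 temperature_K = dataset$temperature_K,
                                 stringsAsFactors = FALSE))
}

#' Fit the train-only preprocessing transform
#'
#' In column order, a feature is dropped when its Pearson |r| with any
#' earlier *kept* feature is at or above the cutoff (keep-first greedy scan);
#' zero-variance features are then dropped; survivors get training means and
#' standard deviations for standardization. The transform is frozen:
#' [apply_preprocessor()] never refits.
#'
#' @param train a `feature_matrix` (training rows only).
#' @param correlation_cutoff Pearson |r| cutoff (default 0.90).
#' @return a `preprocess_transform`.
#' @export
fit_preprocessor <- function(train, correlation_cutoff = 0.90) {
  X <- train$values
  n <- nrow(X); p <- ncol(X)
  if (n < 2) stop_ctx("need at least 2 training rows to fit preprocessing")

  mu <- colMeans(X)
  sd_ <- apply(X, 2, stats::sd)
  const <- sd_ == 0 | !is.finite(sd_)

  # Pearson correlations via BLAS: scale then cross-product.
  Xs <- sweep(X, 2, mu, "-")
  denom <- sd_ * sqrt(n - 1)
  denom[const] <- 1
  Xs <- sweep(Xs, 2, denom, "/")
  C <- crossprod(Xs)  # |r| for non-constant pairs; ~0 rows/cols for constants
  C[const, ] <- 0
  C[, const] <- 0

  kept <- integer(0)
  dropped_corr <- integer(0)
  for (j in seq_len(p)) {
    if (!const[j] && length(kept) > 0 &&
        any(abs(C[j, kept]) >= correlation_cutoff - 1e-12)) {
      dropped_corr <- c(dropped_corr, j)
    } else {
      kept <- c(kept, j)
    }
  }
  dropped_const <- kept[const[kept]]
  kept <- kept[!const[kept]]
  if (length(kept) == 0) stop_ctx("preprocessing dropped every feature")

  structure(list(
    kept_feature_indices = kept,
    kept_feature_names = colnames(X)[kept],
    kept_block_tags = train$block_tags[kept],
    means = mu[kept],
    stds = sd_[kept],
    correlation_cutoff = correlation_cutoff,
    n_in = p,
    n_dropped_correlated = length(dropped_corr),
    n_dropped_constant = length(dropped_const),
    dropped_correlated = colnames(X)[dropped_corr],
    dropped_constant = colnames(X)[dropped_const]
  ), class = "preprocess_transform")
}

#' @method print preprocess_transform
#' @export
print.preprocess_transform <- function(x, ...) {
  cat(sprintf(
    "preprocess_transform: %d -> %d features (dropped %d correlated at |r|>=%.2f, %d constant)\n",
    x$n_in, length(x$kept_feature_indices), x$n_dropped_correlated,
    x$correlation_cutoff, x$n_dropped_constant))
  invisible(x)
}

#' Apply a frozen preprocessing transform
#'
#' Subsets to the kept features (matched by name) and standardizes with the
#' *training* means and standard deviations. Applying the transform twice is
#' not idempotent — it standardizes again with the same statistics — so it
#' must be applied exactly once per matrix.
#'
#' @param transform a `preprocess_transform` from [fit_preprocessor()].
#' @param matrix_in a `feature_matrix` containing all kept features.
#' @return a standardized `feature_matrix` restricted to kept features.
#' @export
apply_preprocessor <- function(transform, matrix_in) {
  X <- matrix_in$values
  missing <- setdiff(transform$kept_feature_names, colnames(X))
  if (length(missing) > 0) {
    stop_ctx("matrix lacks %d kept feature(s), e.g. %s", length(missing),
             missing[1])
  }
  X <- X[, transform$kept_feature_names, drop = FALSE]
  X <- sweep(X, 2, transform$means, "-")
  X <- sweep(X, 2, transform$stds, "/")
  .new_feature_matrix(X, transform$kept_block_tags, matrix_in$row_keys)
}
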