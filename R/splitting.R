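# Compound-disjoint resampling: out-of-sample train/test splits and grouped
# k-fold cross-validation. All rows of a compound stay on one side, so test
# metrics measure generalization to unseen compounds.

#' Compound-disjoint (out-of-sample) train/test split
#'
#' Compounds are shuffled by `seed`, then whole compounds are accumulated
#' into the training set until the training row count first reaches
#' `train_fraction` of all rows (slight overshoot allowed); the remaining
#' compounds form the test set.
#'
#' @param dataset a `curated_dataset` (or data.frame with `compound_id`).
#' @param train_fraction target fraction of rows in the training set.
#' @param seed integer seed for the compound shuffle.
#' @return a `split_plan`: list with `train_row_indices`, `test_row_indices`,
#'   `train_compounds`, `test_compounds`, `seed`, `achieved_train_fraction`.
#' @export
out_of_sample_split <- function(dataset, train_fraction = 0.8, seed = 0) {
  cid <- dataset$compound_id
  n <- length(cid)
  compounds <- unique(cid)
  if (length(compounds) < 2) {
    stop_ctx("cannot split: need at least 2 unique compounds")
  }
  shuffled <- with_seed(derive_seed(seed, 11), sample(compounds))
  rows_per <- table(cid)[shuffled]
  cum_rows <- cumsum(as.numeric(rows_per))
  n_train_compounds <- which(cum_rows >= train_fraction * n)[1]
  if (is.na(n_train_compounds)) n_train_compounds <- length(shuffled)
  n_train_compounds <- min(n_train_compounds, length(shuffled) - 1L)
  train_c <- shuffled[seq_len(n_train_compounds)]
  test_c <- setdiff(shuffled, train_c)
  train_idx <- which(cid %in% train_c)
  test_idx <- which(cid %in% test_c)
  structure(list(
    train_row_indices = train_idx,
    test_row_indices = test_idx,
    train_compounds = train_c,
    test_compounds = test_c,
    seed = seed,
    achieved_train_fraction = length(train_idx) / n
  ), class = "split_plan")
}

#' @method print split_plan
#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf(
    "split_plan (seed %d): %d train rows (%d compounds, %.1f%%), %d test rows (%d compounds)\n",
    x$seed, length(x$train_row_indices), length(x$train_compounds),
    100 * x$achieved_train_fraction, length(x$test_row_indices),
    length(x$test_compounds)))
  invisible(x)
}

#' Grouped k-fold cross-validation plans
#'
#' Partitions the training compounds into `k` disjoint validation sets,
#' balanced by row count: after a seeded shuffle, compounds are assigned
#' largest-first to the currently lightest fold. Every training row is
#' validated exactly once.
#'
#' @param compound_ids compound key per training row.
#' @param k number of folds.
#' @param seed integer seed.
#' @return list of `k` folds, each a list with `val_indices` (row positions
#'   within the input vector) and `val_compounds`.
#' @export
grouped_kfold <- function(compound_ids, k = 5, seed = 0) {
  compounds <- unique(compound_ids)
  if (length(compounds) < k) {
    stop_ctx("grouped %d-fold needs at least %d unique compounds (have %d)",
             k, k, length(compounds))
  }
  shuffled <- with_seed(derive_seed(seed, 23), sample(compounds))
  sizes <- as.numeric(table(compound_ids)[shuffled])
  ord <- order(-sizes)  # largest-first; seeded shuffle breaks ties
  fold_of <- integer(length(shuffled))
  load <- numeric(k)
  for (i in ord) {
    f <- which.min(load)
    fold_of[i] <- f
    load[f] <- load[f] + sizes[i]
  }
  lapply(seq_len(k), function(f) {
    vc <- shuffled[fold_of == f]
    list(val_indices = which(compound_ids %in% vc), val_compounds = vc)
  })
}
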