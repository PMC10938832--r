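# Metrics, the generalization-gap model score, the five-seed benchmark
# protocol, and the learning-curve experiment.

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot`. Negative values are possible (and reported as-is)
#' when predictions are worse than the mean of the observations.
#'
#' @param y_true observed values (not constant, length >= 2).
#' @param y_pred predicted values.
#' @return R-squared.
#' @export
r_squared <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop_ctx("length mismatch")
  if (length(y_true) < 2) stop_ctx("need at least 2 observations")
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) stop_ctx("R-squared undefined for constant y_true")
  1 - sum((y_true - y_pred)^2) / ss_tot
}

#' Root-mean-square error
#'
#' @param y_true observed values.
#' @param y_pred predicted values.
#' @return RMSE in the units of the inputs (log10 cP throughout the package).
#' @export
rmse <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop_ctx("length mismatch")
  sqrt(mean((y_true - y_pred)^2))
}

#' Model-selection score
#'
#' `Score_M = R2_test * (1 - |R2_cv - R2_test|)`: rewards models that are
#' accurate on the test set *and* show a small gap between cross-validation
#' and test accuracy; a large gap (overfitting or unstable generalization)
#' shrinks the score.
#'
#' @param r2_cv cross-validated R-squared (pooled left-out predictions).
#' @param r2_test test-set R-squared.
#' @return the score (same scale as R-squared).
#' @export
model_score <- function(r2_cv, r2_test) {
  r2_test * (1 - abs(r2_cv - r2_test))
}

#' Benchmark algorithm families under the compound-disjoint protocol
#'
#' For every seed: an out-of-sample 80:20 split is drawn; preprocessing is
#' fit on the training split only; every algorithm is tuned by grouped 5-fold
#' cross-validation (single fits per grid point), its cross-validation
#' metrics taken on the pooled left-out predictions of the winning grid
#' point; the winner is refit as a bagged ensemble on the full training split
#' and scored on the held-out test compounds. Results are aggregated over
#' seeds and ranked by mean [model_score()].
#'
#' @param dataset a `curated_dataset`.
#' @param algorithms character vector of family names.
#' @param config a [feature_config()].
#' @param seeds integer seeds, one benchmark repetition each (default 0:4).
#' @param external_blocks optional external descriptor data.frame (see
#'   [assemble_feature_matrix()]).
#' @param grids optional named list of per-family hyperparameter grids.
#' @param n_estimators bagged ensemble size (default 20).
#' @param train_fraction target training fraction (default 0.8).
#' @param k number of cross-validation folds (default 5).
#' @param feature_matrix optional pre-assembled `feature_matrix` for
#'   `dataset` (skips re-featurization).
#' @param keep_models if `TRUE`, fitted bagged models are returned
#'   (`models[[as.character(seed)]][[algorithm]]`).
#' @return a `benchmark_result`: `results` (per algorithm x seed metrics),
#'   `summary` (per-algorithm means, standard deviations, rank), `manifest`
#'   (replayable configuration), optionally `models`.
#' @export
run_benchmark <- function(dataset, algorithms = ALGORITHM_FAMILIES,
                          config = feature_config(), seeds = 0:4,
                          external_blocks = NULL, grids = NULL,
                          n_estimators = 20, train_fraction = 0.8, k = 5,
                          feature_matrix = NULL, keep_models = FALSE) {
  stopifnot(length(algorithms) >= 1)
  fm <- feature_matrix %||%
    assemble_feature_matrix(dataset, external_blocks, config)
  y <- dataset$log10_viscosity
  rows <- list()
  models <- list()

  for (seed in seeds) {
    plan <- out_of_sample_split(dataset, train_fraction, seed)
    tr <- plan$train_row_indices; te <- plan$test_row_indices
    pre <- fit_preprocessor(
      .subset_fm(fm, tr), correlation_cutoff = config$correlation_cutoff)
    Xtr <- apply_preprocessor(pre, .subset_fm(fm, tr))$values
    Xte <- apply_preprocessor(pre, .subset_fm(fm, te))$values
    folds <- grouped_kfold(dataset$compound_id[tr], k = k, seed = seed)
    seed_models <- list()

    for (alg in algorithms) {
      tuned <- tune_hyperparameters(alg, Xtr, y[tr], folds,
                                    grid = grids[[alg]], seed = seed)
      bag <- fit_bagged_ensemble(tuned$spec, Xtr, y[tr],
                                 n_estimators = n_estimators, seed = seed)
      pred_tr <- predict_with_uncertainty(bag, Xtr)$mean
      pred_te <- predict_with_uncertainty(bag, Xte)$mean
      r2_te <- r_squared(y[te], pred_te)
      rows[[length(rows) + 1]] <- data.frame(
        algorithm = alg, seed = seed,
        r2_cv = tuned$cv_r2, rmse_cv = tuned$cv_rmse,
        r2_train = r_squared(y[tr], pred_tr),
        rmse_train = rmse(y[tr], pred_tr),
        r2_test = r2_te, rmse_test = rmse(y[te], pred_te),
        score_m = model_score(tuned$cv_r2, r2_te),
        n_features = ncol(Xtr), n_train = length(tr), n_test = length(te),
        stringsAsFactors = FALSE)
      if (keep_models) {
        bag$preprocessor <- pre
        seed_models[[alg]] <- bag
      }
    }
    if (keep_models) models[[as.character(seed)]] <- seed_models
  }

  results <- do.call(rbind, rows)
  sd0 <- function(x) if (length(x) < 2) 0 else stats::sd(x)
  summary <- do.call(rbind, lapply(split(results, results$algorithm), function(d) {
    data.frame(
      algorithm = d$algorithm[1],
      mean_r2_cv = mean(d$r2_cv), sd_r2_cv = sd0(d$r2_cv),
      mean_rmse_cv = mean(d$rmse_cv), sd_rmse_cv = sd0(d$rmse_cv),
      mean_r2_test = mean(d$r2_test), sd_r2_test = sd0(d$r2_test),
      mean_rmse_test = mean(d$rmse_test), sd_rmse_test = sd0(d$rmse_test),
      mean_score_m = mean(d$score_m), sd_score_m = sd0(d$score_m),
      stringsAsFactors = FALSE)
  }))
  summary <- summary[order(-summary$mean_score_m), , drop = FALSE]
  summary$rank <- seq_len(nrow(summary))
  rownames(summary) <- NULL
  manifest <- list(algorithms = algorithms, seeds = seeds,
                   config = unclass(config), n_estimators = n_estimators,
                   train_fraction = train_fraction, k = k,
                   grids = grids)
  out <- list(results = results, summary = summary, manifest = manifest)
  if (keep_models) out$models <- models
  structure(out, class = "benchmark_result")
}

.subset_fm <- function(fm, idx) {
  .new_feature_matrix(fm$values[idx, , drop = FALSE], fm$block_tags,
                      fm$row_keys[idx, , drop = FALSE])
}

#' @method print benchmark_result
#' @export
print.benchmark_result <- function(x, ...) {
  cat("Benchmark (ranked by mean Score_M):\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf(
      "  %d. %-6s Score_M %.3f+-%.3f | R2 cv %.3f test %.3f | RMSE cv %.3f test %.3f\n",
      s$rank[i], s$algorithm[i], s$mean_score_m[i], s$sd_score_m[i],
      s$mean_r2_cv[i], s$mean_r2_test[i], s$mean_rmse_cv[i],
      s$mean_rmse_test[i]))
  }
  invisible(x)
}

#' Write benchmark outputs (CSV results, CSV summary, JSON manifest)
#'
#' @param benchmark a `benchmark_result`.
#' @param dir output directory.
#' @return invisibly, the written paths.
#' @export
write_benchmark <- function(benchmark, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(file.path(dir, "benchmark_results.csv"),
             file.path(dir, "benchmark_summary.csv"),
             file.path(dir, "benchmark_manifest.json"))
  utils::write.csv(benchmark$results, paths[1], row.names = FALSE)
  utils::write.csv(benchmark$summary, paths[2], row.names = FALSE)
  jsonlite::write_json(benchmark$manifest, paths[3], auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paths)
}

#' Replay a benchmark from its manifest
#'
#' Re-runs [run_benchmark()] with exactly the configuration recorded in a
#' manifest; with identical inputs the outputs replay bit-for-bit for
#' deterministic families.
#'
#' @param dataset the same `curated_dataset` the benchmark ran on.
#' @param manifest the `manifest` element of a `benchmark_result`, or a path
#'   to a written `benchmark_manifest.json`.
#' @return a `benchmark_result`.
#' @export
replay_benchmark <- function(dataset, manifest) {
  if (is.character(manifest)) {
    manifest <- jsonlite::read_json(manifest, simplifyVector = TRUE)
    manifest$seeds <- as.integer(manifest$seeds)
    if (!is.null(manifest$grids)) {
      manifest$grids <- lapply(manifest$grids, function(g) {
        lapply(seq_len(nrow(as.data.frame(g))), function(i)
          as.list(as.data.frame(g)[i, , drop = FALSE]))
      })
    }
  }
  cfg <- do.call(feature_config, manifest$config[
    intersect(names(manifest$config),
              names(formals(feature_config)))])
  run_benchmark(dataset, algorithms = manifest$algorithms, config = cfg,
                seeds = manifest$seeds, grids = manifest$grids,
                n_estimators = manifest$n_estimators,
                train_fraction = manifest$train_fraction, k = manifest$k)
}

#' Learning curves over featurization configurations
#'
#' For each of `seeds` splits: a fixed compound-disjoint 20% test set is
#' held out and nested training subsets are drawn compound-wise at each
#' requested size (smaller subsets are contained in larger ones within a
#' split). For every (configuration, size) a single estimator is fit (no
#' bagging; the curve is about data efficiency, and the seed spread supplies
#' the error bars) and scored on the fixed test set.
#'
#' @param dataset a `curated_dataset`.
#' @param feature_configs named list; each element is a list with `config`
#'   (a [feature_config()]) and optionally `external_blocks`.
#' @param train_sizes row counts at which to evaluate.
#' @param seeds integer seeds, one split each (default 0:19).
#' @param algorithm family used along the curve (default `"lgbm"`).
#' @param hyperparameters fixed hyperparameters for the curve fits.
#' @return a `learning_curve`: `curve` (per config x size x seed RMSE),
#'   `summary` (mean +- sd per config x size), `gaps` (percent change in
#'   mean RMSE between config pairs per size).
#' @export
run_learning_curve <- function(dataset, feature_configs, train_sizes,
                               seeds = 0:19, algorithm = "lgbm",
                               hyperparameters = list()) {
  stopifnot(length(feature_configs) >= 1, length(train_sizes) >= 1)
  y <- dataset$log10_viscosity
  fms <- lapply(feature_configs, function(fc)
    assemble_feature_matrix(dataset, fc$external_blocks,
                            fc$config %||% feature_config()))
  rows <- list()
  for (seed in seeds) {
    plan <- out_of_sample_split(dataset, 0.8, seed)
    tr_all <- plan$train_row_indices; te <- plan$test_row_indices
    # nested compound-wise subsets: a seeded compound order, cut at each size
    comp <- unique(dataset$compound_id[tr_all])
    comp <- with_seed(derive_seed(seed, 31), sample(comp))
    rows_per <- table(dataset$compound_id[tr_all])[comp]
    cum_rows <- cumsum(as.numeric(rows_per))
    for (size in sort(train_sizes)) {
      if (size > length(tr_all)) {
        stop_ctx("train size %d exceeds available %d training rows", size,
                 length(tr_all))
      }
      ncomp <- which(cum_rows >= size)[1]
      sub_comp <- comp[seq_len(ncomp)]
      tr <- tr_all[dataset$compound_id[tr_all] %in% sub_comp]
      for (cfg_name in names(feature_configs)) {
        fm <- fms[[cfg_name]]
        cfg <- feature_configs[[cfg_name]]$config %||% feature_config()
        pre <- fit_preprocessor(.subset_fm(fm, tr),
                                correlation_cutoff = cfg$correlation_cutoff)
        Xtr <- apply_preprocessor(pre, .subset_fm(fm, tr))$values
        Xte <- apply_preprocessor(pre, .subset_fm(fm, te))$values
        spec <- algorithm_spec(algorithm, hyperparameters)
        fit <- fit_single(spec, Xtr, y[tr], seed = derive_seed(seed, 37))
        pred <- predict_single(fit, Xte)
        rows[[length(rows) + 1]] <- data.frame(
          config = cfg_name, size = size, seed = seed,
          n_train_rows = length(tr), rmse_test = rmse(y[te], pred),
          stringsAsFactors = FALSE)
      }
    }
  }
  curve <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(
    split(curve, list(curve$config, curve$size)), function(d) {
      data.frame(config = d$config[1], size = d$size[1],
                 mean_rmse = mean(d$rmse_test), sd_rmse = stats::sd(d$rmse_test),
                 stringsAsFactors = FALSE)
    }))
  rownames(summary) <- NULL
  gaps <- NULL
  cfgs <- names(feature_configs)
  if (length(cfgs) >= 2) {
    pairs <- utils::combn(cfgs, 2, simplify = FALSE)
    gaps <- do.call(rbind, lapply(pairs, function(pr) {
      a <- summary[summary$config == pr[1], ]
      b <- summary[summary$config == pr[2], ]
      m <- merge(a, b, by = "size", suffixes = c("_a", "_b"))
      data.frame(config_a = pr[1], config_b = pr[2], size = m$size,
                 pct_change_rmse =
                   100 * (m$mean_rmse_b - m$mean_rmse_a) / m$mean_rmse_a,
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(curve = curve, summary = summary, gaps = gaps),
            class = "learning_curve")
}
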