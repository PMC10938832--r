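# End-to-end model bundle and the temperature-sweep prediction workflow:
# train once on a curated dataset, then predict viscosity curves with
# uncertainty over a temperature grid for new structures.

#' Train a viscosity model bundle
#'
#' Fits the complete pipeline on a curated dataset: featurization,
#' preprocessing (frozen), grouped-fold hyperparameter tuning and a bagged
#' ensemble on all rows. The returned bundle carries everything needed to
#' featurize and predict new (structure, temperature) pairs, including the
#' training temperature range for extrapolation flagging.
#'
#' @param dataset a `curated_dataset`.
#' @param algorithm family name (default `"lgbm"`).
#' @param config a [feature_config()].
#' @param seed integer seed.
#' @param external_blocks optional external descriptors for training rows.
#' @param grid optional hyperparameter grid; `NULL` uses the family default,
#'   `FALSE`-like empty list disables tuning in favor of family defaults.
#' @param n_estimators bagged ensemble size.
#' @param k tuning folds.
#' @return a `viscosity_model`.
#' @export
train_viscosity_model <- function(dataset, algorithm = "lgbm",
                                  config = feature_config(), seed = 0,
                                  external_blocks = NULL, grid = NULL,
                                  n_estimators = 20, k = 5) {
  fm <- assemble_feature_matrix(dataset, external_blocks, config)
  pre <- fit_preprocessor(fm, correlation_cutoff = config$correlation_cutoff)
  X <- apply_preprocessor(pre, fm)$values
  y <- dataset$log10_viscosity
  folds <- grouped_kfold(dataset$compound_id, k = k, seed = seed)
  tuned <- tune_hyperparameters(algorithm, X, y, folds, grid = grid,
                                seed = seed)
  bag <- fit_bagged_ensemble(tuned$spec, X, y, n_estimators = n_estimators,
                             seed = seed)
  structure(list(
    model = bag, preprocessor = pre, config = config,
    algorithm = algorithm, seed = seed,
    cv_r2 = tuned$cv_r2, cv_rmse = tuned$cv_rmse,
    uses_external = !is.null(external_blocks),
    external_names = if (!is.null(external_blocks)) {
      setdiff(names(external_blocks), c("compound_id", "temperature_K"))
    } else character(0),
    train_temperature_range = range(dataset$temperature_K)
  ), class = "viscosity_model")
}

#' @method print viscosity_model
#' @export
print.viscosity_model <- function(x, ...) {
  cat(sprintf(
    "viscosity_model: %s (seed %d), cv R2 %.3f, T range %.0f-%.0f K%s\n",
    x$algorithm, x$seed, x$cv_r2, x$train_temperature_range[1],
    x$train_temperature_range[2],
    if (x$uses_external) " [needs external descriptors]" else ""))
  invisible(x)
}

#' Predict viscosity curves over a temperature grid
#'
#' Featurizes every (structure, temperature) combination with the bundle's
#' configuration, applies the frozen preprocessing transform, and reports
#' the bagged mean with its confidence interval in log10 cP and in cP.
#' Temperatures outside the training range are flagged as extrapolation;
#' a per-structure warning is emitted when the predicted curve is not
#' monotone non-increasing in temperature (viscosity should fall as
#' temperature rises).
#'
#' @param model a `viscosity_model`.
#' @param structures SMILES vector.
#' @param T_grid temperatures in Kelvin.
#' @param external optional external-descriptor data.frame covering every
#'   (compound, temperature); required when the model was trained with
#'   external descriptors.
#' @param ci_level interval level (default 0.90).
#' @return data.frame with `structure`, `compound_id`, `temperature_K`,
#'   `log10_viscosity_pred`, `lower`, `upper`, `viscosity_cP_pred`,
#'   `extrapolated`, `monotone_warning`.
#' @export
predict_temperature_sweep <- function(model, structures, T_grid,
                                      external = NULL, ci_level = 0.90) {
  if (model$uses_external && is.null(external)) {
    stop_ctx("model was trained with external descriptors (%s); supply them",
             paste(model$external_names, collapse = ", "))
  }
  canon <- canonical_smiles(structures)
  if (anyNA(canon)) {
    stop_ctx("unparseable structure(s): %s",
             paste(structures[is.na(canon)], collapse = ", "))
  }
  grid <- expand.grid(si = seq_along(structures), T_K = T_grid)
  pseudo <- data.frame(
    smiles = structures[grid$si],
    temperature_K = grid$T_K,
    compound_id = canon[grid$si],
    stringsAsFactors = FALSE)
  fm <- assemble_feature_matrix(pseudo, external, model$config)
  X <- apply_preprocessor(model$preprocessor, fm)$values
  pred <- predict_with_uncertainty(model$model, X, ci_level = ci_level)

  out <- data.frame(
    structure = structures[grid$si],
    compound_id = canon[grid$si],
    temperature_K = grid$T_K,
    log10_viscosity_pred = pred$mean,
    lower = pred$lower, upper = pred$upper,
    viscosity_cP_pred = 10^pred$mean,
    extrapolated = grid$T_K < model$train_temperature_range[1] |
      grid$T_K > model$train_temperature_range[2],
    stringsAsFactors = FALSE)
  out <- out[order(out$compound_id, out$temperature_K), , drop = FALSE]
  rownames(out) <- NULL

  out$monotone_warning <- FALSE
  for (cid in unique(out$compound_id)) {
    idx <- which(out$compound_id == cid)
    if (any(diff(out$log10_viscosity_pred[idx]) > 1e-10)) {
      out$monotone_warning[idx] <- TRUE
      warning(sprintf(
        "predicted log-viscosity is not monotone non-increasing in T for %s",
        cid))
    }
  }
  out
}
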