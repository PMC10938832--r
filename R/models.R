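# The eight regression algorithm families, hyperparameter tuning on grouped
# folds, and seeded bagged ensembles with percentile prediction intervals.
#
# Families are fit through their established R implementations: nnet (MLP),
# e1071 (RBF-kernel SVR), ranger (random forest), glmnet (L1 linear),
# mixOmics (PLS), and xgboost. The three boosting flavors are realized as
# xgboost configurations: depthwise unregularized trees for classic gradient
# boosting, histogram + leaf-wise (lossguide) growth for the
# light-gradient-boosting style, and the regularized default for extreme
# gradient boosting.

ALGORITHM_FAMILIES <- c("mlp", "svr", "rf", "gbr", "lgbm", "xgb",
                        "lasso", "pls")

#' Algorithm specification
#'
#' @param family one of `"mlp"`, `"svr"`, `"rf"`, `"gbr"`, `"lgbm"`,
#'   `"xgb"`, `"lasso"`, `"pls"`.
#' @param hyperparameters named list of family-specific hyperparameters;
#'   missing entries take the family defaults.
#' @return an `algorithm_spec`.
#' @export
algorithm_spec <- function(family, hyperparameters = list()) {
  family <- match.arg(family, ALGORITHM_FAMILIES)
  hp <- utils::modifyList(.default_hyperparameters(family), hyperparameters)
  structure(list(family = family, hyperparameters = hp),
            class = "algorithm_spec")
}

.default_hyperparameters <- function(family) {
  switch(family,
    mlp = list(size = 16, decay = 0.05, maxit = 200),
    svr = list(cost = 10, epsilon = 0.1, gamma = NA),  # NA -> 1/p
    rf = list(num_trees = 300, mtry_frac = 0.33),
    gbr = list(nrounds = 300, eta = 0.05, max_depth = 3),
    lgbm = list(nrounds = 300, eta = 0.05, num_leaves = 31),
    xgb = list(nrounds = 300, eta = 0.05, max_depth = 6, lambda = 1),
    lasso = list(lambda = 1e-3),
    pls = list(ncomp = 5)
  )
}

#' Default hyperparameter grids
#'
#' Small documented grids over the knob that matters most per family; users
#' supply their own grids for wider searches.
#'
#' @return named list: per family, a list of hyperparameter lists.
#' @export
default_grids <- function() {
  list(
    mlp = list(list(size = 8, decay = 0.05), list(size = 16, decay = 0.05)),
    svr = list(list(cost = 1), list(cost = 10)),
    rf = list(list(mtry_frac = 0.2), list(mtry_frac = 0.5)),
    gbr = list(list(eta = 0.05), list(eta = 0.1)),
    lgbm = list(list(eta = 0.05), list(eta = 0.1)),
    xgb = list(list(eta = 0.05), list(eta = 0.1)),
    lasso = list(list(lambda = 1e-4), list(lambda = 1e-3),
                 list(lambda = 1e-2)),
    pls = list(list(ncomp = 2), list(ncomp = 5), list(ncomp = 10))
  )
}

# Fit one estimator of one family on an already-preprocessed matrix.
fit_single <- function(spec, X, y, seed = 0) {
  hp <- spec$hyperparameters
  n <- nrow(X); p <- ncol(X)
  fit <- switch(spec$family,
    mlp = with_seed(derive_seed(seed, 101), {
      nnet::nnet(x = X, y = y, size = hp$size, decay = hp$decay,
                 maxit = hp$maxit, linout = TRUE, trace = FALSE,
                 MaxNWts = (p + 2) * hp$size + hp$size + 10)
    }),
    svr = {
      gamma <- if (is.na(hp$gamma)) 1 / p else hp$gamma
      e1071::svm(x = X, y = y, type = "eps-regression", kernel = "radial",
                 cost = hp$cost, epsilon = hp$epsilon, gamma = gamma,
                 scale = FALSE)
    },
    rf = {
      mtry <- max(1L, floor(hp$mtry_frac * p))
      ranger::ranger(x = X, y = y, num.trees = hp$num_trees, mtry = mtry,
                     seed = derive_seed(seed, 102), num.threads = 1)
    },
    gbr = .fit_xgb(X, y, seed, nrounds = hp$nrounds, params = list(
      eta = hp$eta, max_depth = hp$max_depth, lambda = 0, alpha = 0,
      tree_method = "hist")),
    lgbm = .fit_xgb(X, y, seed, nrounds = hp$nrounds, params = list(
      eta = hp$eta, max_depth = 0, max_leaves = hp$num_leaves,
      grow_policy = "lossguide", tree_method = "hist", lambda = 1)),
    xgb = .fit_xgb(X, y, seed, nrounds = hp$nrounds, params = list(
      eta = hp$eta, max_depth = hp$max_depth, lambda = hp$lambda,
      tree_method = "hist")),
    lasso = glmnet::glmnet(x = X, y = y, alpha = 1, lambda = hp$lambda,
                           standardize = FALSE),
    pls = .fit_pls(X, y, ncomp = hp$ncomp)
  )
  structure(list(family = spec$family, fit = fit, hyperparameters = hp,
                 feature_names = colnames(X)),
            class = "single_estimator")
}

.fit_xgb <- function(X, y, seed, nrounds, params) {
  params <- c(params, list(objective = "reg:squarederror", nthread = 1,
                           seed = derive_seed(seed, 103)))
  dtrain <- xgboost::xgb.DMatrix(X, label = y)
  xgboost::xgb.train(params = params, data = dtrain, nrounds = nrounds,
                     verbose = 0)
}

.fit_pls <- function(X, y, ncomp) {
  if (!requireNamespace("mixOmics", quietly = TRUE)) {
    stop_ctx("the pls family requires the mixOmics package")
  }
  ncomp <- min(ncomp, nrow(X) - 1L, ncol(X))
  # drop constant columns within this resample; record for prediction
  sds <- apply(X, 2, stats::sd)
  keep <- which(sds > 0)
  fit <- mixOmics::pls(X[, keep, drop = FALSE], y, ncomp = ncomp,
                       mode = "regression")
  list(fit = fit, keep = keep)
}

predict_single <- function(est, X) {
  X <- X[, est$feature_names, drop = FALSE]
  out <- switch(est$family,
    mlp = as.numeric(stats::predict(est$fit, X)),
    svr = as.numeric(stats::predict(est$fit, X)),
    rf = stats::predict(est$fit, data = X, num.threads = 1)$predictions,
    gbr = ,
    lgbm = ,
    xgb = as.numeric(stats::predict(est$fit, xgboost::xgb.DMatrix(X))),
    lasso = as.numeric(stats::predict(est$fit, newx = X)),
    pls = {
      Xk <- X[, est$fit$keep, drop = FALSE]
      pr <- stats::predict(est$fit$fit, Xk)
      as.numeric(pr$predict[, 1, dim(pr$predict)[3]])
    }
  )
  unname(out)
}

#' Tune hyperparameters on grouped cross-validation folds
#'
#' Evaluates every grid point with single (un-bagged) fits on each fold and
#' returns the point maximizing mean left-out R-squared; ties are broken by
#' lower mean RMSE, then first-in-grid order. Pooled left-out predictions of
#' the winner are returned so cross-validation metrics can be computed
#' without refitting.
#'
#' @param family algorithm family name.
#' @param X preprocessed training matrix.
#' @param y training targets (log10 cP).
#' @param folds grouped folds from [grouped_kfold()] over the training rows.
#' @param grid list of hyperparameter lists; defaults to the family's entry
#'   in [default_grids()].
#' @param seed integer seed for stochastic families.
#' @return list with `spec` (the winning [algorithm_spec()]), `cv_r2` /
#'   `cv_rmse` (pooled left-out metrics of the winner), and
#'   `cv_predictions` (pooled left-out predictions, training-row order).
#' @export
tune_hyperparameters <- function(family, X, y, folds, grid = NULL, seed = 0) {
  if (is.null(grid)) grid <- default_grids()[[family]]
  if (length(grid) == 0) stop_ctx("empty hyperparameter grid")
  n <- nrow(X)
  best <- NULL
  for (g in seq_along(grid)) {
    spec <- algorithm_spec(family, grid[[g]])
    pred <- rep(NA_real_, n)
    ok <- TRUE
    for (f in seq_along(folds)) {
      val <- folds[[f]]$val_indices
      fit <- tryCatch(
        fit_single(spec, X[-val, , drop = FALSE], y[-val],
                   seed = derive_seed(seed, g, f)),
        error = function(e) NULL)
      if (is.null(fit)) { ok <- FALSE; break }
      pred[val] <- predict_single(fit, X[val, , drop = FALSE])
    }
    if (!ok) {
      warning(sprintf("grid point %d failed for family %s; skipped", g, family))
      next
    }
    fold_r2 <- vapply(folds, function(fd)
      r_squared(y[fd$val_indices], pred[fd$val_indices]), numeric(1))
    fold_rmse <- vapply(folds, function(fd)
      rmse(y[fd$val_indices], pred[fd$val_indices]), numeric(1))
    cand <- list(spec = spec, mean_r2 = mean(fold_r2),
                 mean_rmse = mean(fold_rmse),
                 cv_r2 = r_squared(y, pred), cv_rmse = rmse(y, pred),
                 cv_predictions = pred, grid_index = g)
    if (is.null(best) ||
        cand$mean_r2 > best$mean_r2 + 1e-12 ||
        (abs(cand$mean_r2 - best$mean_r2) <= 1e-12 &&
         cand$mean_rmse < best$mean_rmse - 1e-12)) {
      best <- cand
    }
  }
  if (is.null(best)) stop_ctx("every grid point failed for family %s", family)
  best
}

#' Fit a bagged ensemble
#'
#' Trains `n_estimators` estimators of one family, each on a seeded
#' with-replacement bootstrap resample of the training rows (resample size =
#' training size). Estimator seeds derive deterministically from the master
#' seed, so the whole ensemble replays exactly.
#'
#' @param spec an [algorithm_spec()].
#' @param X preprocessed training matrix.
#' @param y training targets.
#' @param n_estimators ensemble size (default 20).
#' @param seed master seed.
#' @return a `bagged_model`.
#' @export
fit_bagged_ensemble <- function(spec, X, y, n_estimators = 20, seed = 0) {
  n <- nrow(X)
  if (n < 2 || length(y) != n) stop_ctx("need X rows == length(y) >= 2")
  seeds <- vapply(seq_len(n_estimators), function(e) derive_seed(seed, 7, e),
                  integer(1))
  estimators <- vector("list", n_estimators)
  boot_indices <- vector("list", n_estimators)
  for (e in seq_len(n_estimators)) {
    idx <- with_seed(seeds[e], sample.int(n, n, replace = TRUE))
    boot_indices[[e]] <- idx
    est <- tryCatch(
      fit_single(spec, X[idx, , drop = FALSE], y[idx], seed = seeds[e]),
      error = function(err) stop_ctx("estimator %d (%s) failed: %s", e,
                                     spec$family, conditionMessage(err)))
    estimators[[e]] <- est
  }
  structure(list(estimators = estimators, bootstrap_seeds = seeds,
                 bootstrap_indices = boot_indices, spec = spec,
                 feature_names = colnames(X), n_train = n),
            class = "bagged_model")
}

#' @method print bagged_model
#' @export
print.bagged_model <- function(x, ...) {
  cat(sprintf("bagged_model: %d x %s estimators, %d features, %d train rows\n",
              length(x$estimators), x$spec$family, length(x$feature_names),
              x$n_train))
  invisible(x)
}

# Per-estimator prediction matrix (rows x estimators).
predict_matrix <- function(model, X) {
  vapply(model$estimators, function(est) predict_single(est, X),
         numeric(nrow(X)))
}

#' Predict with bagged uncertainty intervals
#'
#' The reported prediction is the arithmetic mean over the estimators; the
#' interval bounds are the lower and upper percentiles of the per-estimator
#' predictions at the requested confidence level (linear-interpolation
#' percentiles; 5th/95th for the default 90% level).
#'
#' @param model a `bagged_model`.
#' @param X preprocessed numeric matrix (or a `feature_matrix`).
#' @param ci_level confidence level in `[0, 1)` (default 0.90).
#' @return data.frame with `mean`, `lower`, `upper` (log10 cP).
#' @export
predict_with_uncertainty <- function(model, X, ci_level = 0.90) {
  if (inherits(X, "feature_matrix")) X <- X$values
  if (!all(model$feature_names %in% colnames(X))) {
    stop_ctx("prediction matrix lacks model features")
  }
  P <- predict_matrix(model, X[, model$feature_names, drop = FALSE])
  if (is.null(dim(P))) P <- matrix(P, nrow = nrow(X))
  alpha <- (1 - ci_level) / 2
  lo <- apply(P, 1, stats::quantile, probs = alpha, type = 7, names = FALSE)
  hi <- apply(P, 1, stats::quantile, probs = 1 - alpha, type = 7,
              names = FALSE)
  data.frame(mean = rowMeans(P), lower = lo, upper = hi)
}
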