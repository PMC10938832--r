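# Model-agnostic Shapley attribution: exact enumeration for small feature
# counts, a seeded permutation-sampling estimator for real models, and the
# aggregation convention Mean|SHAP| over (test instances x estimators) with
# signs from the Pearson correlation between Shapley and feature values.

# Coalition value: mean model output with out-of-coalition features replaced
# by background rows (interventional expectation over the background).
.coalition_matrix <- function(instance, background, in_coalition) {
  M <- background
  if (any(in_coalition)) {
    M[, in_coalition] <- matrix(instance[in_coalition], nrow(background),
                                sum(in_coalition), byrow = TRUE)
  }
  M
}

#' Exact Shapley values by subset enumeration
#'
#' Enumerates all feature coalitions (feasible up to ~15 features) and
#' computes exact interventional Shapley values of `predict_fn` at
#' `instance` against a background set. Satisfies the efficiency, dummy and
#' symmetry axioms exactly.
#'
#' @param predict_fn function taking a numeric matrix, returning predictions.
#' @param instance named numeric vector (one row of the model's input space).
#' @param background numeric matrix of background rows (same columns).
#' @param max_features guard on the enumeration size (default 15).
#' @return named numeric vector of Shapley values, one per feature.
#' @export
brute_force_shapley <- function(predict_fn, instance, background,
                                max_features = 15) {
  p <- length(instance)
  if (p > max_features) {
    stop_ctx("%d features exceeds the enumeration cap (%d); use sampled_shapley",
             p, max_features)
  }
  if (nrow(background) == 0) stop_ctx("background set is empty")
  n_sub <- 2^p
  # value of every coalition, indexed by bitmask + 1
  v <- numeric(n_sub)
  masks <- 0:(n_sub - 1)
  bits <- matrix(FALSE, n_sub, p)
  for (j in seq_len(p)) bits[, j] <- bitwAnd(masks, bitwShiftL(1L, j - 1L)) != 0
  big <- do.call(rbind, lapply(seq_len(n_sub), function(s)
    .coalition_matrix(instance, background, bits[s, ])))
  preds <- predict_fn(big)
  nb <- nrow(background)
  v <- vapply(seq_len(n_sub), function(s)
    mean(preds[((s - 1) * nb + 1):(s * nb)]), numeric(1))

  sizes <- rowSums(bits)
  # weight |S|! (p - |S| - 1)! / p!; only coalitions with |S| < p are used
  w <- numeric(n_sub)
  ok <- sizes < p
  w[ok] <- factorial(sizes[ok]) * factorial(p - sizes[ok] - 1) / factorial(p)
  phi <- numeric(p)
  for (j in seq_len(p)) {
    without <- which(!bits[, j])
    with_j <- without + 2^(j - 1)
    phi[j] <- sum(w[without] * (v[with_j] - v[without]))
  }
  names(phi) <- names(instance)
  phi
}

#' Permutation-sampling Shapley values
#'
#' Estimates the same interventional Shapley values as
#' [brute_force_shapley()] by averaging marginal contributions over seeded
#' random feature permutations. Cost is
#' `n_permutations * (p + 1) * nrow(background)` model evaluations per
#' instance, batched into one `predict_fn` call per (instance, permutation).
#'
#' @param predict_fn function taking a numeric matrix, returning predictions.
#' @param instances numeric matrix of rows to explain.
#' @param background numeric matrix of background rows.
#' @param n_permutations permutations per instance (default 50).
#' @param seed integer seed.
#' @return matrix of Shapley values, `nrow(instances)` x `ncol(instances)`.
#' @export
sampled_shapley <- function(predict_fn, instances, background,
                            n_permutations = 50, seed = 0) {
  if (is.null(dim(instances))) instances <- matrix(instances, nrow = 1)
  if (nrow(background) == 0) stop_ctx("background set is empty")
  if (n_permutations < 1) stop_ctx("need at least one permutation")
  p <- ncol(instances)
  nb <- nrow(background)
  phi <- matrix(0, nrow(instances), p, dimnames = list(NULL,
                                                       colnames(instances)))
  for (i in seq_len(nrow(instances))) {
    x <- instances[i, ]
    acc <- numeric(p)
    for (perm_i in seq_len(n_permutations)) {
      ord <- with_seed(derive_seed(seed, i, perm_i), sample.int(p))
      # stack of coalition matrices: empty, then cumulative prefixes of ord
      blocks <- vector("list", p + 1)
      mask <- logical(p)
      blocks[[1]] <- .coalition_matrix(x, background, mask)
      for (s in seq_len(p)) {
        mask[ord[s]] <- TRUE
        blocks[[s + 1]] <- .coalition_matrix(x, background, mask)
      }
      preds <- predict_fn(do.call(rbind, blocks))
      vals <- vapply(seq_len(p + 1), function(s)
        mean(preds[((s - 1) * nb + 1):(s * nb)]), numeric(1))
      acc[ord] <- acc[ord] + diff(vals)
    }
    phi[i, ] <- acc / n_permutations
  }
  phi
}

# Shapley matrices for every estimator of a bagged model on preprocessed
# test rows (instances explained against a background drawn from the same
# preprocessed test matrix, per the test-set attribution convention).
shapley_by_estimator <- function(model, X, background = NULL,
                                 n_permutations = 30, seed = 0,
                                 method = c("sampling", "brute")) {
  method <- match.arg(method)
  if (inherits(X, "feature_matrix")) X <- X$values
  X <- X[, model$feature_names, drop = FALSE]
  if (is.null(background)) background <- X
  lapply(seq_along(model$estimators), function(e) {
    est <- model$estimators[[e]]
    fn <- function(M) predict_single(est, M)
    if (method == "brute") {
      t(vapply(seq_len(nrow(X)), function(i)
        brute_force_shapley(fn, X[i, ], background),
        numeric(ncol(X))))
    } else {
      sampled_shapley(fn, X, background, n_permutations,
                      seed = derive_seed(seed, e))
    }
  })
}

#' Aggregate Shapley values into a feature-importance report
#'
#' Mean absolute Shapley value over (instances x estimators) per feature;
#' the uncertainty is the standard deviation over the per-estimator means;
#' the sign comes from the Pearson correlation between Shapley values and
#' feature values (pooled over instances and estimators); features
#' correlated with each top feature at |r| >= `correlation_cutoff` (over the
#' supplied feature values) are listed as its correlated group.
#'
#' @param shap_list list of per-estimator Shapley matrices
#'   (instances x features), as from `shapley_by_estimator()`.
#' @param feature_values numeric matrix of the explained instances' feature
#'   values (same columns).
#' @param top_k number of top features to report with correlated groups.
#' @param correlation_cutoff Pearson |r| for group membership (default 0.90).
#' @return an `attribution_result`: data.frame `importance` (feature,
#'   mean_abs_shap, sd_over_estimators, sign, pearson_r) sorted by
#'   importance with stable name order on ties, and `top` (top_k rows with a
#'   `correlated_group` list-column of named r values).
#' @export
aggregate_importance <- function(shap_list, feature_values, top_k = 5,
                                 correlation_cutoff = 0.90) {
  p <- ncol(feature_values)
  feats <- colnames(feature_values)
  per_est <- vapply(shap_list, function(S) colMeans(abs(S)), numeric(p))
  if (is.null(dim(per_est))) per_est <- matrix(per_est, nrow = p)
  mean_abs <- rowMeans(per_est)
  sd_est <- apply(per_est, 1, stats::sd)

  pooled_shap <- do.call(rbind, shap_list)
  pooled_feat <- do.call(rbind, rep(list(feature_values), length(shap_list)))
  r <- vapply(seq_len(p), function(j) {
    if (stats::sd(pooled_feat[, j]) == 0 || stats::sd(pooled_shap[, j]) == 0) {
      return(NA_real_)
    }
    stats::cor(pooled_shap[, j], pooled_feat[, j])
  }, numeric(1))
  sign_chr <- ifelse(is.na(r), "undefined", ifelse(r >= 0, "+", "-"))

  imp <- data.frame(feature = feats, mean_abs_shap = mean_abs,
                    sd_over_estimators = sd_est, sign = sign_chr,
                    pearson_r = r, stringsAsFactors = FALSE)
  imp <- imp[order(-imp$mean_abs_shap, imp$feature), , drop = FALSE]
  rownames(imp) <- NULL

  k <- min(top_k, nrow(imp))
  fc <- suppressWarnings(stats::cor(feature_values))
  groups <- lapply(seq_len(k), function(i) {
    j <- match(imp$feature[i], feats)
    rj <- fc[j, ]
    members <- which(abs(rj) >= correlation_cutoff & seq_len(p) != j &
                       !is.na(rj))
    stats::setNames(rj[members], feats[members])
  })
  top <- imp[seq_len(k), , drop = FALSE]
  top$correlated_group <- groups
  structure(list(importance = imp, top = top,
                 correlation_cutoff = correlation_cutoff),
            class = "attribution_result")
}

#' @method print attribution_result
#' @export
print.attribution_result <- function(x, ...) {
  cat("Feature attribution (Mean |SHAP|, sign from Pearson r):\n")
  t <- x$top
  for (i in seq_len(nrow(t))) {
    grp <- t$correlated_group[[i]]
    cat(sprintf("  %d. %-24s %s%.4g +- %.2g%s\n", i, t$feature[i],
                ifelse(t$sign[i] == "-", "-", "+"), t$mean_abs_shap[i],
                t$sd_over_estimators[i],
                if (length(grp) > 0) sprintf(" [%d correlated]", length(grp))
                else ""))
  }
  invisible(x)
}

#' Shapley feature importance for a bagged viscosity model
#'
#' Runs the sampling estimator per bagged estimator on (a subset of) the
#' test instances and aggregates with [aggregate_importance()].
#'
#' @param model a `bagged_model`.
#' @param X_test preprocessed test rows (`feature_matrix` or matrix).
#' @param n_instances number of test instances to explain (default up to 30,
#'   deterministic head of the test set).
#' @param n_background background rows drawn from the test set (default up
#'   to 20).
#' @param n_permutations sampling permutations per instance.
#' @param seed integer seed.
#' @param top_k top features to report.
#' @return an `attribution_result`.
#' @export
explain_model <- function(model, X_test, n_instances = 30, n_background = 20,
                          n_permutations = 20, seed = 0, top_k = 5) {
  if (inherits(X_test, "feature_matrix")) X_test <- X_test$values
  X_test <- X_test[, model$feature_names, drop = FALSE]
  ni <- min(n_instances, nrow(X_test))
  idx_i <- seq_len(ni)
  idx_b <- with_seed(derive_seed(seed, 41),
                     sample.int(nrow(X_test), min(n_background,
                                                  nrow(X_test))))
  shap_list <- shapley_by_estimator(
    model, X_test[idx_i, , drop = FALSE],
    background = X_test[idx_b, , drop = FALSE],
    n_permutations = n_permutations, seed = seed)
  aggregate_importance(shap_list, X_test[idx_i, , drop = FALSE],
                       top_k = top_k)
}
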