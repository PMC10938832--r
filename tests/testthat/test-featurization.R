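# Structure features, fingerprints, inverse temperature, matrix assembly
# and the train-frozen preprocessing transform.

test_that("structure features are deterministic and canonical-form invariant", {
  v1 <- compute_structure_features("CCO")
  v2 <- compute_structure_features("CCO")
  v3 <- compute_structure_features("OCC")
  expect_identical(v1, v2)
  expect_equal(as.numeric(v1), as.numeric(v3))
})

test_that("molecular weight feature steps by one CH2 between homologs", {
  eth <- compute_structure_features("CCO", feature_config(blocks = "2D"))
  met <- compute_structure_features("CO", feature_config(blocks = "2D"))
  expect_equal(eth[["D2_MW"]] - met[["D2_MW"]], 14.027, tolerance = 1e-3)
})

test_that("fingerprint block is sparse for ethane and respects config size", {
  mol <- viscQSPR:::parse_molecules("CC")[[1]]
  fp <- morgan_fingerprint(mol, nbits = 1000, radius = 2)
  expect_length(fp, 1000)
  # ethane has at most a handful of distinct circular environments
  expect_lte(sum(fp), 6)
  fp128 <- morgan_fingerprint(mol, nbits = 128, radius = 2)
  expect_length(fp128, 128)
})

test_that("distinct structures give distinct fingerprints, same structure same bits", {
  mols <- viscQSPR:::parse_molecules(c("CCO", "OCC", "CCCCO", "CC(C)O"))
  fps <- lapply(mols, morgan_fingerprint)
  expect_identical(fps[[1]], fps[[2]])
  expect_false(identical(fps[[1]], fps[[3]]))
  expect_false(identical(fps[[3]], fps[[4]]))
})

test_that("inverse temperature is 1/T with a positive-domain guard", {
  expect_equal(inverse_temperature(1), 1)
  expect_equal(inverse_temperature(298.15), 0.0033540, tolerance = 1e-4)
  out <- inverse_temperature(c(227, 300, 404))
  expect_true(all(diff(out) < 0))
  expect_error(inverse_temperature(0), "positive")
  expect_error(inverse_temperature(-10), "positive")
})

test_that("feature matrix has one row per record with broadcast structure blocks", {
  ds <- log_transform_viscosity(make_records(
    rep(c("CCO", "CCCC"), each = 3), rep(c(280, 300, 320), 2), rep(1, 6)))
  fm <- assemble_feature_matrix(ds)
  expect_equal(nrow(fm$values), 6)
  expect_equal(length(fm$feature_names), ncol(fm$values))
  expect_setequal(unique(fm$block_tags), c("2D", "FP", "COMP", "EXT"))
  # same compound: identical structural columns, different inverse T
  str_cols <- fm$block_tags != "EXT"
  expect_equal(fm$values[1, str_cols], fm$values[2, str_cols])
  expect_false(fm$values[1, "inv_temperature"] == fm$values[2, "inv_temperature"])
  expect_false(all(fm$values[1, str_cols] == fm$values[4, str_cols]))
})

test_that("external blocks join by compound and temperature and add columns", {
  ds <- log_transform_viscosity(make_records(
    rep(c("CCO", "CCCC"), each = 2), rep(c(280, 300), 2), rep(1, 4)))
  ext <- data.frame(compound_id = ds$compound_id,
                    temperature_K = ds$temperature_K)
  for (nm in paste0("MD_", 1:8)) ext[[nm]] <- rnorm(4)
  p0 <- ncol(assemble_feature_matrix(ds)$values)
  fm <- assemble_feature_matrix(ds, external_blocks = ext)
  expect_equal(ncol(fm$values), p0 + 8)
  expect_equal(sum(fm$block_tags == "MD"), 8)
  # strict policy: a missing row errors
  expect_error(assemble_feature_matrix(ds, external_blocks = ext[-1, ]),
               "missing")
})

test_that("preprocessor drops duplicated and constant columns", {
  set.seed(3)
  X <- cbind(a = rnorm(30), b = rnorm(30))
  X <- cbind(X, a_copy = X[, "a"], const = rep(2, 30))
  fm <- viscQSPR:::.new_feature_matrix(X, rep("2D", 4),
                                       data.frame(compound_id = letters[1:30 %% 5 + 1],
                                                  temperature_K = 1:30))
  pre <- fit_preprocessor(fm)
  expect_setequal(pre$kept_feature_names, c("a", "b"))
  expect_equal(pre$n_dropped_correlated, 1)
  expect_equal(pre$n_dropped_constant, 1)
  expect_equal(length(pre$kept_feature_indices) + pre$n_dropped_correlated +
                 pre$n_dropped_constant, pre$n_in)
})

test_that("greedy scan drops exactly the feature at or above the cutoff", {
  X <- correlated_columns(20, c(0.95, 0.80, 0.85))
  fm <- viscQSPR:::.new_feature_matrix(
    X, rep("2D", 4), data.frame(compound_id = letters[1:20 %% 4 + 1],
                                temperature_K = 1:20))
  pre <- fit_preprocessor(fm, correlation_cutoff = 0.90)
  expect_setequal(pre$kept_feature_names, c("c1", "c3", "c4"))
  expect_equal(pre$dropped_correlated, "c2")
})

test_that("apply standardizes training data to mean 0 sd 1 and never refits", {
  set.seed(9)
  X <- matrix(rnorm(200), 20, 10, dimnames = list(NULL, paste0("f", 1:10)))
  fm <- viscQSPR:::.new_feature_matrix(
    X, rep("2D", 10), data.frame(compound_id = letters[1:20 %% 4 + 1],
                                 temperature_K = 1:20))
  pre <- fit_preprocessor(fm)
  Z <- apply_preprocessor(pre, fm)$values
  expect_true(max(abs(colMeans(Z))) < 1e-10)
  expect_true(max(abs(apply(Z, 2, sd) - 1)) < 1e-10)

  # frozen statistics: one row transforms finitely
  one <- viscQSPR:::.new_feature_matrix(
    X[1, , drop = FALSE], rep("2D", 10),
    data.frame(compound_id = "a", temperature_K = 1))
  expect_true(all(is.finite(apply_preprocessor(pre, one)$values)))

  # applying twice standardizes again (documented non-idempotence)
  Z2 <- apply_preprocessor(pre, apply_preprocessor(pre, fm))$values
  expect_false(isTRUE(all.equal(Z, Z2)))

  # schema errors on missing kept features
  miss <- viscQSPR:::.new_feature_matrix(
    X[, 1:5], rep("2D", 5), fm$row_keys)
  expect_error(apply_preprocessor(pre, miss), "lacks")
})

test_that("no later-scanned kept pair correlates at or above the cutoff", {
  set.seed(11)
  base <- matrix(rnorm(60 * 30), 60, 30)
  extra <- base[, sample(30, 20, replace = TRUE)] +
    matrix(rnorm(60 * 20, sd = 0.1), 60, 20)
  X <- cbind(base, extra)
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  fm <- viscQSPR:::.new_feature_matrix(
    X, rep("2D", ncol(X)),
    data.frame(compound_id = letters[1:60 %% 6 + 1], temperature_K = 1:60))
  pre <- fit_preprocessor(fm, correlation_cutoff = 0.90)
  kept <- X[, pre$kept_feature_names, drop = FALSE]
  C <- cor(kept)
  # brute force: for every kept column, no earlier kept column reaches 0.90
  for (j in 2:ncol(kept)) {
    expect_true(all(abs(C[j, 1:(j - 1)]) < 0.90 + 1e-9))
  }
})

test_that("structure blocks never depend on temperature", {
  ds <- log_transform_viscosity(make_records(
    rep("CCOC(C)=O", 3), c(250, 300, 350), rep(1, 3)))
  fm <- assemble_feature_matrix(ds)
  str_cols <- fm$block_tags != "EXT"
  expect_equal(fm$values[1, str_cols], fm$values[2, str_cols])
  expect_equal(fm$values[2, str_cols], fm$values[3, str_cols])
})
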