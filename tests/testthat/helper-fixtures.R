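# Shared fixtures, memoized across test files so expensive synthetic
# datasets and models are built once per test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, builder(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# The curation fixture: a size-matched compound pool measured isoviscously,
# with injected violations at the documented 2/1/1-per-10-clean-rows ratio.
curation_fixture <- function(seed = 0) {
  memo(paste0("curation_", seed), function() {
    pool <- generate_compound_library(preset = "homologous_midsize")
    cfg <- synthetic_config(
      n_compounds = 30, compounds = pool[1:30], noise_sd = 0.005,
      viscosity_band = c(-0.5, 0.5),
      n_element_outliers = 30, n_range_outliers = 15,
      n_deviation_outliers = 15, seed = seed)
    generate_dataset(cfg)
  })
}

# Row identity key for comparing generated records with curated survivors.
record_keys <- function(df) {
  paste(df$smiles, signif(df$temperature_K, 10), signif(df$viscosity_cP, 10))
}

# The benchmark-scale dataset: 200 compounds x 5 temperatures at the default
# measurement noise, curated.
benchmark_dataset <- function() {
  memo("benchmark_ds", function() {
    gd <- generate_dataset(synthetic_config(n_compounds = 200, seed = 0))
    cur <- curate(gd$records)
    list(generated = gd, curated = cur$dataset, report = cur$report)
  })
}

# Small curated dataset for cheap pipeline tests.
small_dataset <- function() {
  memo("small_ds", function() {
    gd <- generate_dataset(synthetic_config(n_compounds = 25, seed = 1))
    curate(gd$records)$dataset
  })
}

# A 2D-only bagged model on a fixed split of the benchmark dataset, plus its
# preprocessed test matrix (shared by attribution and sweep tests).
model_2d_fixture <- function() {
  memo("model_2d", function() {
    ds <- benchmark_dataset()$curated
    cfg <- feature_config(blocks = "2D")
    fm <- assemble_feature_matrix(ds, config = cfg)
    plan <- out_of_sample_split(ds, 0.8, seed = 0)
    tr <- plan$train_row_indices
    te <- plan$test_row_indices
    pre <- fit_preprocessor(viscQSPR:::.subset_fm(fm, tr))
    Xtr <- apply_preprocessor(pre, viscQSPR:::.subset_fm(fm, tr))$values
    Xte <- apply_preprocessor(pre, viscQSPR:::.subset_fm(fm, te))$values
    bag <- fit_bagged_ensemble(algorithm_spec("lgbm"), Xtr,
                               ds$log10_viscosity[tr],
                               n_estimators = 20, seed = 0)
    list(model = bag, Xtr = Xtr, Xte = Xte, plan = plan, pre = pre,
         y = ds$log10_viscosity)
  })
}

# Raw records data.frame builder.
make_records <- function(smiles, temperature_K, viscosity_cP,
                         source = "test") {
  data.frame(smiles = smiles, temperature_K = temperature_K,
             viscosity_cP = viscosity_cP,
             source = rep_len(source, length(smiles)),
             stringsAsFactors = FALSE)
}

# Construct a matrix whose columns have exact sample correlations to the
# first column (Gram-Schmidt on orthogonalized noise).
correlated_columns <- function(n, r_targets, seed = 42) {
  set.seed(seed)
  z <- matrix(rnorm(n * (length(r_targets) + 1)), n)
  q <- qr.Q(qr(scale(z, scale = FALSE)))
  x1 <- q[, 1]
  cols <- cbind(x1, vapply(seq_along(r_targets), function(j) {
    r_targets[j] * x1 + sqrt(1 - r_targets[j]^2) * q[, j + 1]
  }, numeric(n)))
  colnames(cols) <- paste0("c", seq_len(ncol(cols)))
  cols
}
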