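# The synthetic Vogel-equation data generator: library grammar, parameter
# assignment, dataset statistics, outlier injection and surrogate
# descriptors.

test_that("compound library is deterministic, distinct and filter-clean", {
  lib1 <- generate_compound_library(40, seed = 3)
  lib2 <- generate_compound_library(40, seed = 3)
  lib3 <- generate_compound_library(40, seed = 4)
  expect_identical(lib1, lib2)
  expect_false(identical(lib1, lib3))
  canon <- canonical_smiles(lib1)
  expect_false(any(duplicated(canon)))
  out <- filter_structures(make_records(lib1, rep(300, 40), rep(1, 40)))
  expect_equal(nrow(out$removed), 0)
  expect_error(generate_compound_library(1e6), "grammar yields")
})

test_that("battery preset returns the six electrolyte solvents", {
  lib <- generate_compound_library(preset = "battery")
  expect_named(lib, c("MA", "EA", "MB", "MP", "DMC", "EMC"))
  expect_equal(canonical_smiles(lib[["MA"]]), canonical_smiles("COC(=O)C"))
  expect_equal(canonical_smiles(lib[["DMC"]]), canonical_smiles("COC(=O)OC"))
  expect_equal(canonical_smiles(lib[["EMC"]]), canonical_smiles("CCOC(=O)OC"))
})

test_that("Vogel parameters are reproducible and shift with homolog size", {
  p1 <- assign_vogel_parameters("CCOC(C)=O", seed = 7)
  p2 <- assign_vogel_parameters("CCOC(C)=O", seed = 7)
  expect_identical(p1, p2)
  # expected B grows from methyl to butyl ester across many seeds
  b_small <- vapply(1:100, function(s)
    assign_vogel_parameters("COC(C)=O", seed = s)$B, numeric(1))
  b_large <- vapply(1:100, function(s)
    assign_vogel_parameters("CCCCOC(C)=O", seed = s)$B, numeric(1))
  expect_gt(mean(b_large), mean(b_small))
  # C stays well below the coldest sampled temperature
  expect_lt(p1$C, 210)
})

test_that("noiseless data lies on its Vogel curve and refits recover it", {
  # wide clip range so no value is flattened against the instrument limits
  cfg <- synthetic_config(n_compounds = 5, noise_sd = 0, seed = 2,
                          clip_range_cP = c(1e-4, 1e4))
  gd <- generate_dataset(cfg)
  for (smi in unique(gd$records$smiles)) {
    rows <- gd$records$smiles == smi
    tr <- gd$truth[gd$truth$smiles == smi, ]
    expect_equal(log10(gd$records$viscosity_cP[rows]), tr$log10_mu_clean,
                 tolerance = 1e-12)
    # least-squares refit of (A, B, C) from a perturbed start lands back on
    # the generating values (Levenberg-Marquardt: robust at zero residual)
    fit <- minpack.lm::nlsLM(
      log10(viscosity_cP) ~ A + B / (temperature_K - C),
      data = gd$records[rows, ],
      start = list(A = tr$A[1] + 0.2, B = tr$B[1] * 1.3, C = tr$C[1] - 15))
    est <- coef(fit)
    expect_equal(unname(est["A"]), tr$A[1], tolerance = 1e-6)
    expect_equal(unname(est["B"]), tr$B[1], tolerance = 1e-4)
    expect_equal(unname(est["C"]), tr$C[1], tolerance = 1e-4)
  }
})

test_that("noiseless curves strictly decrease with temperature", {
  gd <- generate_dataset(synthetic_config(n_compounds = 10, noise_sd = 0,
                                          seed = 5,
                                          clip_range_cP = c(1e-4, 1e4)))
  for (smi in unique(gd$records$smiles)) {
    rows <- gd$records[gd$records$smiles == smi, ]
    rows <- rows[order(rows$temperature_K), ]
    expect_true(all(diff(rows$viscosity_cP) < 0))
  }
})

test_that("default configuration yields right-skewed log viscosity", {
  gd <- generate_dataset(synthetic_config(n_compounds = 100, seed = 0))
  x <- log10(gd$records$viscosity_cP)
  skew <- mean((x - mean(x))^3) / sd(x)^3
  expect_gt(skew, 0)
  expect_true(all(gd$records$viscosity_cP >= 0.10 - 1e-12))
  expect_true(all(gd$records$viscosity_cP <= 26.52 + 1e-12))
})

test_that("injected outliers are labeled and exactly recovered by curation", {
  fx <- curation_fixture(seed = 0)
  expect_equal(sum(fx$truth$type == "element"), 30)
  expect_equal(sum(fx$truth$type == "range"), 15)
  expect_equal(sum(fx$truth$type == "deviation"), 15)
  cur <- curate(fx$records)
  removed <- setdiff(record_keys(fx$records), record_keys(cur$dataset))
  expect_setequal(removed, record_keys(fx$records)[fx$truth$type != "clean"])
})

test_that("surrogate descriptors span the informativeness dial", {
  bd <- benchmark_dataset()
  ds <- bd$curated
  truth <- bd$generated$truth

  ext0 <- generate_surrogate_external_descriptors(ds, truth, 0, seed = 1)
  s <- truth$log10_mu_clean[match(
    paste(ds$smiles, signif(ds$temperature_K, 10)),
    paste(truth$smiles, signif(truth$temperature_K, 10)))]
  for (nm in paste0("MD_", c("density", "FV", "Rg", "SP", "SP_E", "SP_V",
                             "HV", "RMSD"))) {
    expect_lt(abs(cor(ext0[[nm]], s)), 0.1)
  }

  ext1 <- generate_surrogate_external_descriptors(ds, truth, 1, seed = 1)
  expect_gt(abs(cor(ext1$MD_HV, s, method = "spearman")), 0.95)
  # free-volume and mobility analogues anti-correlate with viscosity
  expect_lt(cor(ext1$MD_FV, s), -0.9)
  expect_lt(cor(ext1$MD_RMSD, s), -0.9)

  ext1b <- generate_surrogate_external_descriptors(ds, truth, 1, seed = 1)
  expect_identical(ext1, ext1b)
  expect_error(generate_surrogate_external_descriptors(ds, truth, 2), "0, 1")
})

test_that("toy trajectories carry correct analytic expectations", {
  d <- generate_toy_trajectory("dimer", list(d = 2))
  expect_equal(d$expected$MD_Rg, 1)
  tr <- generate_toy_trajectory("translate", list(step = 1, n_frames = 3))
  expect_equal(tr$expected$rmsd_per_frame, c(0, 1, 2))
  lat <- generate_toy_trajectory("lattice", list(m_side = 3, s = 4, r = 1.5))
  expect_equal(lat$expected$MD_FV, 100 * (1 - 4 / 3 * pi * 1.5^3 / 4^3))
  expect_error(generate_toy_trajectory("no_such_case"), "unknown")
})
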