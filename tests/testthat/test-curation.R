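# Dataset curation: reader, the three filters, log transform, and the
# composed curate() pipeline.

test_that("read_records parses well-formed rows and reports bad ones", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("smiles,temperature_K,viscosity_cP,source",
               "CCO,298.15,1.2,labA",
               "CCC,abc,0.9,labA",
               "CCCC,300,abc,labB",
               "CC,310,0.5,labB"), path)
  out <- read_records(path)
  expect_equal(nrow(out$records), 2)
  expect_equal(out$parse_report$line, c(3L, 4L))
  expect_match(out$parse_report$reason[1], "temperature")
  expect_match(out$parse_report$reason[2], "viscosity")
})

test_that("read_records converts Celsius to Kelvin at the boundary", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("structure,temp_C,visc", "CCO,25,1.2"), path)
  out <- read_records(path, column_map = list(
    structure = "structure", temperature = "temp_C", viscosity = "visc",
    temperature_unit = "C"))
  expect_equal(out$records$temperature_K, 298.15)
})

test_that("read_records errors on missing columns and all-bad files", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2"), path)
  expect_error(read_records(path), "structure")
  writeLines(c("smiles,temperature_K,viscosity_cP", "CCO,bad,bad"), path)
  expect_error(read_records(path), "no parseable rows")
})

test_that("structure filter keeps single-fragment organics over the allowed set", {
  recs <- make_records(
    c("CCO", "[Na+].[Cl-]", "O", "C[Ge](C)C", "not_a_smiles(("),
    rep(300, 5), rep(1, 5))
  out <- filter_structures(recs)
  expect_equal(out$records$smiles, "CCO")
  reasons <- setNames(out$removed$reason, out$removed$smiles)
  expect_equal(unname(reasons[["[Na+].[Cl-]"]]), "multiple_fragments")
  expect_equal(unname(reasons[["O"]]), "no_carbon")
  expect_match(unname(reasons[["C[Ge](C)C"]]), "disallowed_elements:Ge")
})

test_that("range filter matches the hand-computed Tukey fences", {
  # viscosities {1,2,3,4,100}: linear-interpolation quartiles Q1=2, Q3=4,
  # upper fence 4 + 1.5*2 = 7, so only the 100 goes
  recs <- make_records(rep("CCO", 5), rep(300, 5), c(1, 2, 3, 4, 100))
  out <- filter_range_outliers(recs)
  expect_equal(out$records$viscosity_cP, c(1, 2, 3, 4))
  expect_equal(out$removed$viscosity_cP, 100)
  expect_equal(out$removed$reason, "viscosity_range")
})

test_that("range filter agrees with a brute-force reimplementation", {
  set.seed(7)
  for (rep_i in 1:5) {
    n <- sample(20:100, 1)
    recs <- make_records(rep("CCO", n),
                         runif(n, 250, 400) + c(rep(0, n - 2), 300, -150),
                         exp(rnorm(n, 0, 1)))
    out <- filter_range_outliers(recs, k = 1.5)
    brute_keep <- function(x) {
      s <- sort(x)
      q1 <- unname(quantile(s, 0.25, type = 7))
      q3 <- unname(quantile(s, 0.75, type = 7))
      x >= q1 - 1.5 * (q3 - q1) & x <= q3 + 1.5 * (q3 - q1)
    }
    keep <- brute_keep(recs$viscosity_cP) & brute_keep(recs$temperature_K)
    expect_equal(out$records$viscosity_cP, recs$viscosity_cP[keep])
  }
})

test_that("range filter edge cases: identical values and single records", {
  same <- make_records(rep("CCO", 4), rep(300, 4), rep(2, 4))
  expect_equal(nrow(filter_range_outliers(same)$records), 4)
  one <- make_records("CCO", 300, 2)
  expect_equal(nrow(filter_range_outliers(one)$records), 1)
})

test_that("deviation filter drops the higher-temperature point of a violation", {
  recs <- make_records(rep("CCO", 2), c(300, 310), c(1.00, 1.05))
  out <- filter_positive_temperature_deviation(recs)
  expect_equal(out$records$temperature_K, 300)
  expect_equal(out$removed$temperature_K, 310)

  # strictly decreasing curves are untouched
  dec <- make_records(rep("CCO", 4), c(280, 300, 320, 340),
                      c(2.0, 1.5, 1.1, 0.8))
  expect_equal(nrow(filter_positive_temperature_deviation(dec)$records), 4)

  # the boundary is strict: exactly +0.02 cP survives
  edge <- make_records(rep("CCO", 2), c(300, 310), c(1.00, 1.02))
  expect_equal(nrow(filter_positive_temperature_deviation(edge)$records), 2)
})

test_that("deviation filter compares against the last retained point", {
  # after dropping the 310 K spike, 320 K is checked against 300 K
  recs <- make_records(rep("CCO", 3), c(300, 310, 320), c(1.00, 1.50, 1.01))
  out <- filter_positive_temperature_deviation(recs)
  expect_equal(out$records$temperature_K, c(300, 320))
  # and a run of spikes all fall to the same anchor
  recs2 <- make_records(rep("CCO", 4), c(300, 310, 320, 330),
                        c(1.00, 1.50, 1.40, 0.95))
  out2 <- filter_positive_temperature_deviation(recs2)
  expect_equal(out2$records$temperature_K, c(300, 330))
})

test_that("deviation filter separates compounds", {
  recs <- make_records(c("CCO", "CCC"), c(300, 310), c(1.00, 1.05))
  expect_equal(nrow(filter_positive_temperature_deviation(recs)$records), 2)
})

test_that("log transform is base 10 and keeps originals", {
  recs <- make_records(rep("CCO", 3), rep(300, 3), c(1, 0.10, 26.52))
  ds <- log_transform_viscosity(recs)
  expect_equal(ds$log10_viscosity, c(0, -1, log10(26.52)))
  expect_equal(ds$log10_viscosity[3], 1.4236, tolerance = 1e-4)
  expect_equal(ds$viscosity_cP, c(1, 0.10, 26.52))
  expect_error(log_transform_viscosity(
    make_records("CCO", 300, -1)), "non-positive")
})

test_that("compound ids equal canonical SMILES identity", {
  recs <- make_records(c("CCO", "OCC", "CCC"), rep(300, 3), rep(1, 3))
  ds <- log_transform_viscosity(recs)
  expect_equal(ds$compound_id[1], ds$compound_id[2])
  expect_false(ds$compound_id[1] == ds$compound_id[3])
})

test_that("curate removes exactly the injected violations on the fixture", {
  fx <- curation_fixture(seed = 0)
  cur <- curate(fx$records)
  removed_keys <- record_keys(fx$records)[
    !(record_keys(fx$records) %in% record_keys(cur$dataset))]
  flagged_keys <- record_keys(fx$records)[fx$truth$type != "clean"]
  expect_setequal(removed_keys, flagged_keys)
  expect_equal(cur$report$removed_by_structure_filter, 30)
  expect_equal(cur$report$removed_by_range_filter, 15)
  expect_equal(cur$report$removed_by_deviation_filter, 15)
  expect_equal(cur$report$counts_in - 60, cur$report$counts_out)
})

test_that("curate is idempotent on curated data and vacuous on empty input", {
  fx <- curation_fixture(seed = 0)
  first <- curate(fx$records)
  again <- curate(as.data.frame(first$dataset))
  expect_equal(nrow(again$dataset), nrow(first$dataset))
  expect_equal(again$report$counts_in, again$report$counts_out)

  empty <- curate(make_records(character(0), numeric(0), numeric(0)))
  expect_equal(empty$report$counts_in, 0)
  expect_equal(empty$report$counts_out, 0)
  expect_equal(nrow(empty$dataset), 0)
})

test_that("curation report arithmetic reconciles and counts shrink monotonically", {
  fx <- curation_fixture(seed = 0)
  r <- curate(fx$records)$report
  expect_equal(r$counts_in - r$removed_by_structure_filter -
                 r$removed_by_range_filter - r$removed_by_deviation_filter,
               r$counts_out)
  expect_true(all(c(r$removed_by_structure_filter, r$removed_by_range_filter,
                    r$removed_by_deviation_filter, r$counts_out) >= 0))
})

test_that("curated outputs round-trip through the CSV/JSON writers", {
  dir <- withr::local_tempdir()
  fx <- curation_fixture(seed = 0)
  cur <- curate(fx$records)
  paths <- write_curated(cur, dir)
  back <- utils::read.csv(paths[1])
  expect_equal(nrow(back), nrow(cur$dataset))
  rep_back <- jsonlite::read_json(paths[2], simplifyVector = TRUE)
  expect_equal(rep_back$counts_out, cur$report$counts_out)
})
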