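# MGF parsing and writing, result tables, ground truth, ingest filtering.

test_that("a minimal MGF block parses to one spectrum", {
  path <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c(
    "BEGIN IONS",
    "TITLE=spec_a",
    "PEPMASS=500.25 12345.6",
    "CHARGE=2+",
    "RTINSECONDS=63.2",
    "100.05 5.0",
    "250.2\t10.0",
    "900.9 2.0",
    "END IONS"
  ), path)
  sp <- read_mgf(path)
  expect_length(sp, 1)
  s <- sp[[1]]
  expect_identical(s$id, "spec_a")
  expect_equal(s$precursor_mz, 500.25)
  expect_identical(s$charge, 2L)
  expect_equal(s$retention_time, 63.2)
  expect_length(s$mz, 3)
  expect_identical(attr(sp, "skipped"), 0L)
})

test_that("records missing PEPMASS/CHARGE or with bad charge are skipped", {
  path <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c(
    "BEGIN IONS", "TITLE=no_charge", "PEPMASS=400.2", "100 1", "END IONS",
    "BEGIN IONS", "TITLE=ok", "PEPMASS=400.2", "CHARGE=3+", "100 1",
    "END IONS",
    "BEGIN IONS", "TITLE=charge9", "PEPMASS=400.2", "CHARGE=9+", "100 1",
    "END IONS"
  ), path)
  expect_warning(sp <- read_mgf(path), "skipped 2")
  expect_length(sp, 1)
  expect_identical(sp[[1]]$id, "ok")
  expect_identical(attr(sp, "skipped"), 2L)
})

test_that("charge dialects parse with sign and magnitude", {
  expect_identical(convnovo:::parse_mgf_charge("2+"), 2L)
  expect_identical(convnovo:::parse_mgf_charge("+3"), 3L)
  expect_identical(convnovo:::parse_mgf_charge("2"), 2L)
  expect_identical(convnovo:::parse_mgf_charge("2-"), -2L)
  expect_true(is.na(convnovo:::parse_mgf_charge("x")))
})

test_that("simulator-written MGF round-trips losslessly at 1e-6", {
  d <- simulate_hcd_dataset(10, simulator_config(), seed = 21)
  path <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(d$spectra, path)
  back <- read_mgf(path)
  expect_length(back, 10)
  for (i in seq_along(back)) {
    expect_equal(back[[i]]$mz, d$spectra[[i]]$mz, tolerance = 1e-6)
    expect_equal(back[[i]]$intensity, d$spectra[[i]]$intensity,
                 tolerance = 1e-4)
    expect_equal(back[[i]]$precursor_mz, d$spectra[[i]]$precursor_mz,
                 tolerance = 1e-6)
    expect_identical(back[[i]]$charge, d$spectra[[i]]$charge)
  }
})

test_that("spectrum construction sorts peaks and validates fields", {
  s <- spectrum("x", mz = c(300, 100, 200), intensity = c(1, 2, 3),
                precursor_mz = 400, charge = 2L)
  expect_identical(s$mz, c(100, 200, 300))
  expect_identical(s$intensity, c(2, 3, 1))
  expect_error(spectrum("x", 100, -1, 400, 2), "non-negative")
  expect_error(spectrum("x", 100, 1, -400, 2), "positive")
})

test_that("result tables round-trip through TSV at stated precision", {
  set.seed(9)
  n <- 100
  results <- data.frame(
    spectrum_id = sprintf("s%03d", 1:n),
    peptide = replicate(n, rand_peptide_str()),
    quality_score = runif(n),
    theoretical_mass = runif(n, 500, 3000),
    ppm_to_precursor = runif(n, 0, 50),
    rescued = sample(c(TRUE, FALSE), n, TRUE),
    passed_mass_filter = sample(c(TRUE, FALSE), n, TRUE),
    stringsAsFactors = FALSE
  )
  results$position_probs <- I(lapply(1:n, function(i) runif(8)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_results(results, path)
  back <- read_results(path)
  expect_identical(back$spectrum_id, results$spectrum_id)
  expect_identical(back$peptide, results$peptide)
  expect_equal(back$quality_score, results$quality_score, tolerance = 1e-5)
  expect_equal(back$theoretical_mass, results$theoretical_mass,
               tolerance = 1e-6)
  expect_identical(back$rescued, results$rescued)
  for (i in 1:n) {
    expect_equal(back$position_probs[[i]], results$position_probs[[i]],
                 tolerance = 1e-5)
  }
})

test_that("an empty result table writes a header-only file", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_results(convnovo:::predict_empty_results(), path)
  lines <- readLines(path)
  expect_length(lines, 1)
  expect_match(lines, "^spectrum_id\t")
  expect_identical(nrow(read_results(path)), 0L)
})

test_that("ground truth read drops invalid peptides with a count", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("s1\tPEPTIDE", sprintf("s2\t%s", strrep("A", 31)),
               "s3\tAXC", "s4\tGGAK"), path)
  expect_warning(tr <- read_ground_truth(path), "dropped 2")
  expect_equal(unname(tr), c("PEPTIDE", "GGAK"), ignore_attr = TRUE)
  expect_identical(names(tr), c("s1", "s4"))
})

test_that("ingest filtering drops bad charges and unlabelled spectra", {
  sp <- list(
    toy_spectrum(id = "a", charge = 2L),
    toy_spectrum(id = "b", charge = 2L),
    toy_spectrum(id = "c", charge = 2L)
  )
  truth <- c(a = "GGAK", c = strrep("A", 31))
  flt <- filter_spectra(sp, truth)
  expect_length(flt$spectra, 1)
  expect_identical(flt$spectra[[1]]$id, "a")
  expect_identical(attr(flt, "n_dropped_truth"), 2L)
})
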