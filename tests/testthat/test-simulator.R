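# Synthetic HCD spectrum generator: peptide draws, ladder fidelity,
# noise statistics, determinism, information-completeness.

clean_sim_config <- function(...) {
  simulator_config(
    ion_detect_prob = 1, b12_detect_prob = 1, frag2_detect_prob = 0,
    noise_lambda = 0, precursor_jitter_ppm = 0,
    tryptic_fraction = 0, charge_distribution = c("2" = 1), ...
  )
}

test_that("random peptides honour length range, alphabet and trypticity", {
  set.seed(2)
  cfg <- simulator_config(tryptic_fraction = 1, length_range = c(7L, 7L))
  peps <- replicate(200, random_peptide(cfg))
  expect_true(all(nchar(peps) == 7))
  expect_true(all(substr(peps, 7, 7) %in% c("K", "R")))
  cfg2 <- simulator_config(alphabet = c("G", "A"), tryptic_fraction = 0,
                           length_range = c(3L, 6L))
  peps2 <- replicate(200, random_peptide(cfg2))
  expect_true(all(grepl("^[GA]+$", peps2)))
  expect_true(all(nchar(peps2) %in% 3:6))
})

test_that("residue draws are uniform over the alphabet", {
  set.seed(8)
  cfg <- simulator_config(alphabet = c("G", "A", "S", "V"),
                          tryptic_fraction = 0, length_range = c(10L, 10L))
  peps <- replicate(2500, random_peptide(cfg))
  counts <- table(factor(unlist(strsplit(peps, "")),
                         levels = c("G", "A", "S", "V")))
  p <- chisq.test(counts)$p.value
  expect_gt(p, 1e-3)
})

test_that("with full detection and no noise the ladder is exact", {
  set.seed(12)
  cfg <- clean_sim_config()
  p <- "GGAVLK"
  s <- simulate_hcd_spectrum(p, cfg, id = "t")
  n <- nchar(p)
  theo <- sort(c(
    vapply(1:(n - 1), function(i) fragment_mz(p, "b", i, 1), numeric(1)),
    vapply(1:(n - 1), function(i) fragment_mz(p, "y", i, 1), numeric(1))
  ))
  expect_equal(s$mz, theo, tolerance = 1e-9)
  # complementary pairs conserve the precursor-derived constant
  M <- peptide_mono_mass(p)
  for (i in 1:(n - 1)) {
    b <- fragment_mz(p, "b", i, 1)
    y <- fragment_mz(p, "y", n - i, 1)
    expect_lt(abs(b + y - 2 * PROTON_MASS - M), 1e-9)
  }
  # without jitter, the precursor m/z inverts exactly
  expect_lt(abs(precursor_neutral_mass(s$precursor_mz, s$charge) - M), 1e-9)
})

test_that("precursor jitter stays within the configured ppm bound", {
  set.seed(3)
  cfg <- clean_sim_config()
  cfg$precursor_jitter_ppm <- 5
  for (r in 1:50) {
    p <- random_peptide(cfg)
    s <- simulate_hcd_spectrum(p, cfg)
    M <- peptide_mono_mass(p)
    expect_lte(ppm_difference(precursor_neutral_mass(s$precursor_mz, 2), M),
               5 + 1e-6)
  }
})

test_that("noise peak counts follow the configured Poisson mean", {
  set.seed(14)
  cfg <- simulator_config(ion_detect_prob = 0, b12_detect_prob = 0,
                          noise_lambda = 12, tryptic_fraction = 0,
                          charge_distribution = c("2" = 1))
  counts <- replicate(1000, {
    length(simulate_hcd_spectrum("GAVLSK", cfg)$mz)
  })
  expect_lt(abs(mean(counts) - 12), 4 * sqrt(12 / 1000))
})

test_that("dataset generation is byte-identical under a fixed seed", {
  f1 <- withr::local_tempfile(fileext = ".mgf")
  f2 <- withr::local_tempfile(fileext = ".mgf")
  t1 <- withr::local_tempfile(fileext = ".tsv")
  t2 <- withr::local_tempfile(fileext = ".tsv")
  simulate_hcd_dataset(25, simulator_config(), seed = 99, mgf_path = f1,
                       truth_path = t1)
  simulate_hcd_dataset(25, simulator_config(), seed = 99, mgf_path = f2,
                       truth_path = t2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(t1), readLines(t2))
  # and the files are re-readable and aligned
  sp <- read_mgf(f1)
  tr <- read_ground_truth(t1)
  expect_length(sp, 25)
  expect_identical(sort(names(tr)),
                   sort(vapply(sp, `[[`, character(1), "id")))
})

test_that("a clean synthetic spectrum is information-complete", {
  # the ladder reader (independent of the network path) must reconstruct
  # the peptide exactly, up to Leu/Ile, from a noiseless full ladder
  set.seed(27)
  cfg <- clean_sim_config()
  for (r in 1:50) {
    p <- random_peptide(cfg)
    s <- simulate_hcd_spectrum(p, cfg)
    got <- ladder_read_peptide(s)
    expect_false(is.na(got))
    expect_identical(gsub("I", "L", got), gsub("I", "L", p))
  }
})

test_that("doubly charged fragments appear only for 3+ precursors", {
  set.seed(31)
  cfg <- clean_sim_config()
  cfg$frag2_detect_prob <- 1
  p <- "GAVLSEK"
  s2 <- simulate_hcd_spectrum(p, cfg, charge = 2L)
  cfg3 <- cfg
  cfg3$charge_distribution <- c("3" = 1)
  s3 <- simulate_hcd_spectrum(p, cfg3, charge = 3L)
  expect_length(s3$mz, 2 * length(s2$mz))
  b3_2 <- fragment_mz(p, "b", 3, 2)
  expect_true(any(abs(s3$mz - b3_2) < 1e-9))
  expect_false(any(abs(s2$mz - b3_2) < 1e-9))
})
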