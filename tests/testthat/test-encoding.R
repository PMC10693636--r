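# Spectrum encoding: precursor removal, top-k retention, binning,
# channel stacking and the meta vector.

test_that("precursor-peak removal is inclusive on the window boundary", {
  w <- 1.5
  eps <- 1e-6
  s <- toy_spectrum(
    mz = c(498.75 - eps, 498.75 + eps, 500.25, 501.75 - eps, 501.75 + eps),
    intensity = rep(1, 5), precursor_mz = 500.25
  )
  out <- remove_precursor_peaks(s, window = w)
  expect_equal(out$mz, c(498.75 - eps, 501.75 + eps))
  # untouched when nothing is near the precursor
  s2 <- toy_spectrum(mz = c(100, 200), intensity = c(1, 1),
                     precursor_mz = 900)
  expect_identical(remove_precursor_peaks(s2, w)$mz, c(100, 200))
  expect_error(remove_precursor_peaks(s, 0), "positive")
})

test_that("top-k retention keeps the most intense peaks, ties to low m/z", {
  s <- toy_spectrum(mz = c(10, 20, 30, 40), intensity = c(5, 9, 9, 1),
                    precursor_mz = 600)
  expect_identical(retain_top_k(s, 10)$mz, s$mz) # k >= n is the identity
  expect_identical(retain_top_k(s, 1)$mz, 20)    # single max, lower m/z tie
  out <- retain_top_k(s, 3)
  expect_identical(out$mz, c(10, 20, 30))
  # brute-force oracle over random spectra
  set.seed(33)
  for (r in 1:30) {
    n <- sample(5:40, 1)
    mz <- sort(runif(n, 50, 1900))
    it <- sample(1:8, n, replace = TRUE) # many ties
    k <- sample(1:n, 1)
    keep <- sort(order(-it, mz)[seq_len(k)])
    s <- toy_spectrum(mz = mz, intensity = it, precursor_mz = 2500)
    out <- retain_top_k(s, k)
    expect_identical(out$mz, mz[keep])
    expect_identical(out$intensity, as.numeric(it[keep]))
  }
})

test_that("binning uses half-open 0.1 Th bins, max collision, unit max", {
  cfg <- encoding_config()
  s <- toy_spectrum(mz = 100.05, intensity = 5.0, precursor_mz = 900)
  v <- bin_and_normalize(s, cfg)
  expect_length(v, 20480L)
  expect_equal(v[1001], 1.0) # 0-based bin 1000
  expect_equal(sum(v), 1.0)
  # collision takes the maximum, then normalization
  s2 <- toy_spectrum(mz = c(100.01, 100.09, 300.0),
                     intensity = c(4, 6, 12), precursor_mz = 900)
  v2 <- bin_and_normalize(s2, cfg)
  expect_equal(v2[1001], 0.5)
  expect_equal(v2[3001], 1.0)
  # sum mode adds colliding peaks instead
  v3 <- bin_and_normalize(s2, cfg, collide = "sum")
  expect_equal(v3[1001], 10 / 12)
  # peaks at or above mz_max are discarded; empty spectra give zeros
  s4 <- toy_spectrum(mz = c(2000.0, 2500), intensity = c(1, 1),
                     precursor_mz = 900)
  expect_identical(bin_and_normalize(s4, cfg), numeric(20480))
  expect_identical(
    bin_and_normalize(toy_spectrum(mz = numeric(0), intensity = numeric(0),
                                   precursor_mz = 900), cfg),
    numeric(20480)
  )
})

test_that("binning pads from 20,000 to 20,480 with zeros", {
  cfg <- encoding_config()
  expect_identical(cfg$n_bins, 20000L)
  expect_identical(cfg$padded_length, 20480L)
  s <- toy_spectrum(mz = c(150.5, 1999.95), intensity = c(3, 8),
                    precursor_mz = 900)
  v <- bin_and_normalize(s, cfg)
  expect_identical(v[20001:20480], numeric(480))
  expect_equal(max(v), 1.0)
})

test_that("binning is invariant to the input peak order", {
  set.seed(4)
  mz <- runif(50, 0, 1999)
  it <- runif(50, 1, 100)
  o <- sample(50)
  a <- bin_and_normalize(toy_spectrum(mz = mz, intensity = it,
                                      precursor_mz = 2500))
  b <- bin_and_normalize(toy_spectrum(mz = mz[o], intensity = it[o],
                                      precursor_mz = 2500))
  expect_identical(a, b)
})

test_that("the input matrix stacks intensities, scaled m/z and reversals", {
  cfg <- encoding_config(bin_width = 2, mz_max = 1600, padded_length = 800L)
  v <- bin_and_normalize(toy_spectrum(mz = c(101, 900), intensity = c(2, 4),
                                      precursor_mz = 2000), cfg)
  m <- build_input_matrix(v, cfg)
  expect_identical(dim(m), c(800L, 4L))
  expect_identical(m[, 1], v)
  i <- seq_len(cfg$n_bins)
  expect_equal(m[i, 2], ((i - 1) + 0.5) * 2 / 1600 * 0.1)
  expect_identical(m[, 3], rev(m[, 1]))
  expect_identical(m[, 4], rev(m[, 2]))
  expect_identical(rev(rev(m[, 1])), m[, 1])
  # default geometry: 20,480 rows by 4 channels
  cfg0 <- encoding_config()
  m0 <- build_input_matrix(numeric(20480), cfg0)
  expect_identical(dim(m0), c(20480L, 4L))
})

test_that("the meta vector is charge one-hot, scaled m/z and NCE", {
  s <- toy_spectrum(precursor_mz = 500, charge = 2L)
  v <- build_meta_vector(s, encoding_config())
  expect_length(v, 10)
  expect_identical(v[1:8], c(0, 1, 0, 0, 0, 0, 0, 0))
  expect_equal(v[9], 0.25)
  expect_identical(v[10], 0)
  s8 <- toy_spectrum(precursor_mz = 1000, charge = 8L,
                     collision_energy = 27)
  v8 <- build_meta_vector(s8, encoding_config())
  expect_identical(v8[8], 1)
  expect_equal(v8[10], 0.27)
  s9 <- toy_spectrum(charge = 9L)
  expect_error(build_meta_vector(s9, encoding_config()), "charge")
})

test_that("encoding configuration enforces its geometric invariants", {
  expect_error(encoding_config(padded_length = 10000L), ">=")
  expect_error(encoding_config(bin_width = 0.1, mz_max = 2000,
                               padded_length = 20001L), "divisible")
})
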