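# Greedy decoding, quality scoring and precursor-mass rescue.

test_that("greedy decode reads residues up to the first end symbol", {
  dec <- greedy_decode(onehot_prob_matrix("ACK"))
  expect_identical(dec$peptide, "ACK")
  expect_identical(dec$position_probs, c(1, 1, 1))
  expect_false(dec$failed)
  expect_false(dec$truncated)
  # end symbol in the first column is a degenerate empty decode
  m <- matrix(1 / 23, 23, 32)
  m[convnovo:::CLASS_END, 1] <- 0.9
  dec2 <- greedy_decode(m)
  expect_identical(dec2$peptide, "")
  expect_true(dec2$failed)
  # a padding argmax before the end symbol is a decode failure
  m3 <- onehot_prob_matrix("ACK")
  m3[, 2] <- 0
  m3[convnovo:::CLASS_PAD, 2] <- 1
  expect_true(greedy_decode(m3)$failed)
  # no end symbol at all truncates at 30 residues
  m4 <- matrix(0, 23, 32)
  m4[1, ] <- 1
  dec4 <- greedy_decode(m4)
  expect_identical(nchar(dec4$peptide), 30L)
  expect_true(dec4$truncated)
})

test_that("greedy decode equals the brute-force argmax oracle", {
  set.seed(53)
  for (r in 1:100) {
    m <- random_prob_matrix()
    dec <- greedy_decode(m)
    # independent re-derivation with the stated lowest-index tie rule and
    # the truncation-at-30 convention
    residues <- character(0)
    probs <- numeric(0)
    for (pos in 1:32) {
      col <- m[, pos]
      cls <- which(col == max(col))[1]
      if (cls == 22) break
      if (cls >= 21) {
        residues <- character(0)
        probs <- numeric(0)
        break
      }
      if (length(residues) == 30) break
      residues <- c(residues, ALPHABET20[cls])
      probs <- c(probs, col[cls])
    }
    expect_identical(dec$peptide, paste(residues, collapse = ""))
    if (!dec$failed) expect_identical(dec$position_probs, probs)
  }
})

test_that("quality score is the product of residue probabilities", {
  expect_identical(quality_score(c(1, 1, 1)), 1)
  expect_identical(quality_score(c(0.5, 0.5)), 0.25)
  expect_identical(quality_score(numeric(0)), 0) # empty decode sentinel
  expect_identical(
    quality_score(greedy_decode(onehot_prob_matrix("GAVLK"))$position_probs),
    1
  )
})

test_that("rescue returns the optimal peptide when the mass matches", {
  p <- "GAVLK"
  m <- onehot_prob_matrix(p)
  dec <- greedy_decode(m)
  res <- precursor_mass_rescue(m, dec, peptide_mono_mass(p), 10)
  expect_identical(res$peptide, p)
  expect_false(res$rescued)
  expect_true(res$passed_mass_filter)
  expect_equal(res$quality_score, 1)
})

test_that("rescue substitutes the runner-up that fixes the mass", {
  truth <- "GAVLK"
  wrong <- "GGVLK" # decoded A -> G at position 2
  m <- onehot_prob_matrix(wrong, soft = 0.2)
  # make the truth residue the runner-up at position 2, and give position 1
  # a runner-up (W) whose substitution cannot fix the mass, so the matching
  # candidate is unique
  m[, 1] <- 0.01
  m[match("G", ALPHABET20), 1] <- 0.6
  m[match("W", ALPHABET20), 1] <- 0.3
  m[, 2] <- 0.01
  m[match("G", ALPHABET20), 2] <- 0.5
  m[match("A", ALPHABET20), 2] <- 0.3
  m <- sweep(m, 2, colSums(m), "/")
  dec <- greedy_decode(m)
  expect_identical(dec$peptide, wrong)
  precursor <- peptide_mono_mass(truth)
  res <- precursor_mass_rescue(m, dec, precursor, 10)
  expect_identical(res$peptide, truth)
  expect_true(res$rescued)
  expect_true(res$passed_mass_filter)
  expect_equal(res$quality_score,
               prod(replace(dec$position_probs, 2,
                            m[match("A", ALPHABET20), 2])),
               tolerance = 1e-12)
})

test_that("rescue equals the exhaustive single-substitution oracle", {
  set.seed(59)
  for (r in 1:100) {
    # crafted case: decode one peptide, ask for the mass of a variant
    n <- sample(4:12, 1)
    truth <- rand_peptide_str(n, n)
    decoded <- truth
    pos_wrong <- sample(n, 1)
    wrong_res <- sample(setdiff(ALPHABET20, substr(truth, pos_wrong,
                                                   pos_wrong)), 1)
    substr(decoded, pos_wrong, pos_wrong) <- wrong_res
    m <- onehot_prob_matrix(decoded, soft = 0.1)
    # plant each true residue as its column's runner-up
    for (i in seq_len(n)) {
      ri <- match(substr(truth, i, i), ALPHABET20)
      di <- match(substr(decoded, i, i), ALPHABET20)
      if (ri != di) {
        m[ri, i] <- m[di, i] * 0.6
        m <- sweep(m, 2, colSums(m), "/")
      }
    }
    dec <- greedy_decode(m)
    expect_identical(dec$peptide, decoded)
    precursor <- peptide_mono_mass(truth)
    res <- precursor_mass_rescue(m, dec, precursor, 10)
    if (ppm_difference(peptide_mono_mass(decoded), precursor) <= 10) {
      # decode already mass-consistent (e.g. an Ile/Leu swap): no rescue
      expect_identical(res$peptide, decoded)
      expect_false(res$rescued)
      next
    }

    # oracle: enumerate all n single-position runner-up substitutions in
    # scan order and take the first whose mass matches
    oracle <- NULL
    n_candidates <- 0L
    for (i in seq_len(n)) {
      col <- m[1:20, i]
      o <- order(-col)
      runner <- o[if (ALPHABET20[o[1]] == substr(decoded, i, i)) 2 else 1]
      cand <- decoded
      substr(cand, i, i) <- ALPHABET20[runner]
      n_candidates <- n_candidates + 1L
      if (ppm_difference(peptide_mono_mass(cand), precursor) <= 10 &&
          is.null(oracle)) {
        oracle <- cand
      }
    }
    expect_identical(n_candidates, n) # exactly L candidates explored
    if (is.null(oracle)) {
      expect_identical(res$peptide, decoded)
      expect_false(res$passed_mass_filter)
    } else {
      expect_identical(res$peptide, oracle)
      expect_true(res$rescued)
    }
  }
})

test_that("rescue reports failure flags when nothing matches", {
  p <- "GAVLK"
  m <- onehot_prob_matrix(p)
  res <- precursor_mass_rescue(m, greedy_decode(m),
                               peptide_mono_mass(p) + 500, 10)
  expect_identical(res$peptide, p)
  expect_false(res$rescued)
  expect_false(res$passed_mass_filter)
})
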