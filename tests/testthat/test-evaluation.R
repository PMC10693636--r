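# Evaluation metrics: residue equivalence, positional matching under the
# prefix-mass convention, accuracies, precision-coverage.

test_that("peptide correctness collapses Leu/Ile", {
  expect_true(peptide_correct("LKE", "IKE"))
  expect_true(peptide_correct("GAVIL", "GAVIL"))
  expect_false(peptide_correct("GAV", "GAVK")) # length mismatch
  expect_false(peptide_correct("GAV", "GAC"))
})

test_that("positional matching follows the prefix-mass convention", {
  expect_identical(positional_matches("GAVLK", "GAVLK"), 5L)
  expect_identical(positional_matches("ILE", "LLE"), 3L)
  expect_identical(positional_matches("WWWW", "GGGG"), 0L)
  expect_identical(positional_matches("", "GAVLK"), 0L)
  # a mass-preserving internal substitution (GG <-> N) re-synchronizes:
  # A[GG]K vs A[N]K share prefix masses at A and K
  expect_identical(positional_matches("ANK", "AGGK"), 2L)
  expect_identical(positional_matches("AGGK", "ANK"), 2L)
  # a mass-shifting substitution breaks the downstream frame only when the
  # masses stop agreeing; here V -> G shifts all later prefixes
  expect_identical(positional_matches("AGK", "AVK"), 1L)
  # index mode ignores masses entirely
  expect_identical(positional_matches("AGK", "AVK", mode = "index"), 2L)
  # complete correctness implies all residues match
  set.seed(73)
  for (r in 1:50) {
    p <- rand_peptide_str(3, 15)
    q <- chartr("I", "L", p)
    expect_identical(positional_matches(q, p), nchar(p))
  }
})

test_that("positional accuracy is the matched fraction of truth residues", {
  pred <- c("GAVLK", "GAK")
  truth <- c("GAVLK", "GAVLK")
  # 5 matches + 2 matches (G, A; K's prefix disagrees) over 10 residues
  expect_identical(positional_matches("GAK", "GAVLK"), 2L)
  expect_equal(positional_accuracy(pred, truth), 7 / 10)
  expect_equal(positional_accuracy(c("GAVLK", "GAVLK"), truth), 1.0)
  expect_equal(positional_accuracy(c("", ""), truth), 0.0)
})

test_that("the precursor filter restricts peptide accuracy as defined", {
  pred <- c("GAVLK", "GAVLK", "AAAAA", "GAVLK")
  truth <- c("GAVLK", "GAVLK", "GAVLK", "GAVLK")
  ppm <- c(2, 50, 3, 12)
  expect_equal(peptide_accuracy(pred, truth), 3 / 4)
  f <- filtered_peptide_accuracy(pred, truth, ppm, tol_ppm = 10)
  expect_equal(f$accuracy, 1 / 2) # rows 1 and 3 pass, one is correct
  expect_identical(f$n_filtered, 2L)
  # all pass -> equals the unfiltered accuracy
  f2 <- filtered_peptide_accuracy(pred, truth, rep(1, 4))
  expect_equal(f2$accuracy, peptide_accuracy(pred, truth))
  # nothing passes -> documented 0 with an explicit count
  f3 <- filtered_peptide_accuracy(pred, truth, rep(99, 4))
  expect_identical(f3$accuracy, 0)
  expect_identical(f3$n_filtered, 0L)
})

test_that("precision-coverage matches a brute-force recount", {
  set.seed(79)
  truth <- replicate(20, rand_peptide_str(4, 8))
  pred <- truth
  wrong <- sample(20, 8)
  pred[wrong] <- vapply(pred[wrong], function(p) {
    substr(p, 1, 1) <- setdiff(c("G", "W"), substr(p, 1, 1))[1]
    p
  }, character(1))
  scores <- runif(20)
  curve <- precision_coverage(pred, truth, scores)
  for (row in seq_len(nrow(curve))) {
    t <- curve$threshold[row]
    above <- which(scores >= t)
    ok <- sum(peptide_correct(pred[above], truth[above]))
    expect_equal(curve$coverage[row], ok / 20)
    expect_equal(curve$precision[row], ok / length(above))
    expect_identical(curve$n_above[row], length(above))
  }
  # coverage is non-increasing and above-threshold sets are nested
  expect_true(all(diff(curve$coverage) <= 1e-12))
  sets <- lapply(curve$threshold, function(t) which(scores >= t))
  for (i in seq_len(length(sets) - 1)) {
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
  }
  # degenerate thresholds
  lo <- precision_coverage(pred, truth, scores, thresholds = -1)
  expect_equal(lo$coverage, mean(peptide_correct(pred, truth)))
  hi <- precision_coverage(pred, truth, scores, thresholds = 2)
  expect_identical(hi$precision, 1)
  expect_identical(hi$n_above, 0L)
  expect_identical(hi$coverage, 0)
})

test_that("precision cutoffs are the smallest threshold reaching target", {
  truth <- rep("GAVLK", 6)
  pred <- c("GAVLK", "GAVLK", "GAVLK", "AAAAA", "AAAAA", "AAAAA")
  scores <- c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1)
  # perfectly separable: any threshold in (0.3, 0.7] reaches precision 1
  cut <- choose_cutoff_for_precision(pred, truth, scores, 1.0)
  expect_equal(cut, 0.7)
  expect_equal(choose_cutoff_for_precision(pred, truth, scores, 0), 0.1)
  un <- choose_cutoff_for_precision(rev(pred), truth, scores, 0.99)
  expect_true(is.na(un))
  expect_match(attr(un, "diagnostic"), "no cutoff")
})

test_that("the evaluation report composes all metrics", {
  truth <- c(a = "GAVLK", b = "GGAK", c = "LLEK")
  results <- data.frame(
    spectrum_id = c("a", "b", "c"),
    peptide = c("GAVLK", "GGAK", "IIEK"),
    quality_score = c(0.9, 0.5, 0.4),
    ppm_to_precursor = c(1, 30, 2),
    stringsAsFactors = FALSE
  )
  ev <- evaluate_denovo(results, truth)
  expect_s3_class(ev, "convnovo_eval")
  expect_identical(ev$n_spectra, 3L)
  expect_equal(ev$peptide_accuracy, 1.0) # I/L collapsed
  expect_equal(ev$positional_accuracy, 1.0)
  expect_identical(ev$n_filtered, 2L)
  expect_equal(ev$filtered_peptide_accuracy, 1.0)
  expect_true(all(c("threshold", "precision", "coverage") %in%
                    names(ev$precision_coverage)))
  expect_error(evaluate_denovo(results, truth[1:2]), "missing ground truth")
})
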