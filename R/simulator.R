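# Synthetic HCD spectrum simulator: b/y ion ladders with stochastic
# intensities, missing fragments, uniform noise peaks and precursor jitter.

#' Simulator configuration
#'
#' Parameters of the synthetic HCD spectrum generator. Defaults emulate
#' tryptic HCD data: mostly 2+/3+ precursors, b/y ladders with log-normal
#' intensities where y-series ions are drawn weaker than b-series ions,
#' strongly suppressed b1/b2 (and mildly suppressed b3) detection, a
#' Poisson number of uniform low-intensity noise peaks, and a few ppm of
#' precursor m/z jitter.
#'
#' @param alphabet Residue codes peptides are drawn from (default all 20).
#' @param length_range Integer `c(min, max)` peptide length, within 1..30
#'   (default `c(6, 25)`).
#' @param tryptic_fraction Probability that the C-terminal residue is forced
#'   to K or R (default 0.9).
#' @param charge_distribution Named numeric vector of precursor-charge
#'   probabilities (default `c("2" = 0.6, "3" = 0.4)`); must sum to 1.
#' @param ion_detect_prob Detection probability of an internal b/y fragment
#'   (default 0.95).
#' @param b12_detect_prob Detection probability for b1 and b2 (default 0.2);
#'   b3 uses the mean of this and `ion_detect_prob`.
#' @param frag2_detect_prob Detection probability of doubly charged fragment
#'   ions, emitted only for precursors of charge >= 3 (default 0.5).
#' @param b_log_mu,y_log_mu,log_sigma Log-normal intensity parameters
#'   (natural log scale) for b and y ions; y defaults below b.
#' @param noise_lambda Poisson mean of the number of uniform noise peaks
#'   (default 30).
#' @param noise_intensity_quantile Noise intensities are drawn uniformly
#'   between 0 and this quantile of the signal intensities (default 0.2).
#' @param precursor_jitter_ppm Standard deviation truncated at 3 sigma of
#'   the relative precursor m/z error, in ppm (default 5, must be <= 10).
#' @param mz_max Fragments beyond this m/z are not emitted (default 2000).
#' @return An object of class `"simulator_config"`.
#' @export
simulator_config <- function(alphabet = AA_RESIDUES,
                             length_range = c(6L, 25L),
                             tryptic_fraction = 0.9,
                             charge_distribution = c("2" = 0.6, "3" = 0.4),
                             ion_detect_prob = 0.95,
                             b12_detect_prob = 0.2,
                             frag2_detect_prob = 0.5,
                             b_log_mu = log(100), y_log_mu = log(60),
                             log_sigma = 0.8,
                             noise_lambda = 30,
                             noise_intensity_quantile = 0.2,
                             precursor_jitter_ppm = 5,
                             mz_max = 2000) {
  stopifnot(
    all(alphabet %in% AA_RESIDUES),
    length_range[1] >= 1, length_range[2] <= 30,
    length_range[1] <= length_range[2],
    tryptic_fraction >= 0, tryptic_fraction <= 1,
    abs(sum(charge_distribution) - 1) < 1e-8,
    ion_detect_prob >= 0, ion_detect_prob <= 1,
    precursor_jitter_ppm >= 0, precursor_jitter_ppm <= 10
  )
  structure(
    list(
      alphabet = alphabet,
      length_range = as.integer(length_range),
      tryptic_fraction = tryptic_fraction,
      charge_distribution = charge_distribution,
      ion_detect_prob = ion_detect_prob,
      b12_detect_prob = b12_detect_prob,
      frag2_detect_prob = frag2_detect_prob,
      b_log_mu = b_log_mu, y_log_mu = y_log_mu, log_sigma = log_sigma,
      noise_lambda = noise_lambda,
      noise_intensity_quantile = noise_intensity_quantile,
      precursor_jitter_ppm = precursor_jitter_ppm,
      mz_max = mz_max
    ),
    class = "simulator_config"
  )
}

#' Draw a random peptide
#'
#' Length uniform over the configured range, residues i.i.d. uniform over the
#' configured alphabet; with probability `tryptic_fraction` the C-terminal
#' residue is replaced by K or R (equiprobably).
#'
#' @param cfg A [simulator_config()].
#' @return A peptide string.
#' @export
random_peptide <- function(cfg = simulator_config()) {
  lo <- cfg$length_range[1]
  hi <- cfg$length_range[2]
  n <- lo + sample.int(hi - lo + 1L, 1L) - 1L
  r <- sample(cfg$alphabet, n, replace = TRUE)
  if (runif(1) < cfg$tryptic_fraction) {
    basic <- intersect(c("K", "R"), cfg$alphabet)
    if (length(basic) == 0L) basic <- c("K", "R")
    r[n] <- basic[sample.int(length(basic), 1L)]
  }
  paste(r, collapse = "")
}

#' Simulate one HCD spectrum for a peptide
#'
#' Emits singly charged b/y ladders (doubly charged fragments added for
#' precursors of charge >= 3), each fragment detected with its configured
#' probability and given a log-normal intensity (y drawn from a weaker
#' distribution than b; b1/b2 detection strongly reduced), plus a Poisson
#' number of uniform-m/z noise peaks at low intensity. The precursor m/z is
#' `(M + z * proton) / z` perturbed by the configured ppm jitter.
#'
#' @param sequence Peptide string.
#' @param cfg A [simulator_config()].
#' @param id Spectrum identifier.
#' @param charge Optional fixed precursor charge; drawn from
#'   `cfg$charge_distribution` when `NULL`.
#' @return A [spectrum()] with attributes `peptide` and `noise_mz`.
#' @export
simulate_hcd_spectrum <- function(sequence, cfg = simulator_config(),
                                  id = "sim", charge = NULL) {
  n <- nchar(sequence)
  if (is.null(charge)) {
    charge <- as.integer(sample(names(cfg$charge_distribution), 1L,
                                prob = cfg$charge_distribution))
  }
  mz <- numeric(0)
  it <- numeric(0)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      det_b <- if (i <= 2L) cfg$b12_detect_prob else if (i == 3L) {
        (cfg$b12_detect_prob + cfg$ion_detect_prob) / 2
      } else cfg$ion_detect_prob
      frag_charges <- if (charge >= 3L) c(1L, 2L) else 1L
      for (fz in frag_charges) {
        p_fz <- if (fz == 1L) 1 else cfg$frag2_detect_prob
        if (runif(1) < det_b * p_fz) {
          m <- fragment_mz(sequence, "b", i, fz)
          if (m < cfg$mz_max) {
            mz <- c(mz, m)
            it <- c(it, rlnorm(1, cfg$b_log_mu, cfg$log_sigma))
          }
        }
        if (runif(1) < cfg$ion_detect_prob * p_fz) {
          m <- fragment_mz(sequence, "y", n - i, fz)
          if (m < cfg$mz_max) {
            mz <- c(mz, m)
            it <- c(it, rlnorm(1, cfg$y_log_mu, cfg$log_sigma))
          }
        }
      }
    }
  }
  n_noise <- rpois(1, cfg$noise_lambda)
  if (n_noise > 0L) {
    cap <- if (length(it)) {
      quantile(it, cfg$noise_intensity_quantile, names = FALSE)
    } else 1
    mz <- c(mz, runif(n_noise, 0, cfg$mz_max))
    it <- c(it, runif(n_noise, 0, cap))
  }
  M <- peptide_mono_mass(sequence)
  pmz <- (M + charge * PROTON_MASS) / charge
  if (cfg$precursor_jitter_ppm > 0) {
    eps <- rnorm(1, 0, cfg$precursor_jitter_ppm / 3)
    eps <- max(min(eps, cfg$precursor_jitter_ppm), -cfg$precursor_jitter_ppm)
    pmz <- pmz * (1 + eps * 1e-6)
  }
  s <- spectrum(id = id, mz = mz, intensity = it,
                precursor_mz = pmz, charge = charge)
  attr(s, "peptide") <- sequence
  s
}

#' Generate a synthetic dataset
#'
#' Draws `n` random peptides and simulates one spectrum each; optionally
#' writes the spectra as MGF and the ground truth as a two-column TSV. The
#' whole draw is deterministic given the seed.
#'
#' @param n Number of spectra.
#' @param cfg A [simulator_config()].
#' @param seed Integer seed (`NULL` to use the current RNG state).
#' @param mgf_path,truth_path Optional output paths.
#' @return List with `spectra` (list of [spectrum()]) and `truth` (named
#'   character vector id -> peptide).
#' @export
simulate_hcd_dataset <- function(n, cfg = simulator_config(), seed = NULL,
                                 mgf_path = NULL, truth_path = NULL) {
  if (!is.null(seed)) set.seed(seed)
  spectra <- vector("list", n)
  truth <- character(n)
  ids <- sprintf("sim_%06d", seq_len(n))
  for (k in seq_len(n)) {
    p <- random_peptide(cfg)
    spectra[[k]] <- simulate_hcd_spectrum(p, cfg, id = ids[k])
    truth[k] <- p
  }
  names(truth) <- ids
  if (!is.null(mgf_path)) write_mgf(spectra, mgf_path)
  if (!is.null(truth_path)) write_ground_truth(truth, truth_path)
  list(spectra = spectra, truth = truth)
}

#' Read a peptide off a clean fragment ladder
#'
#' Reference decoder used to show the synthetic task is information-complete:
#' with all fragments detected and no noise, it reconstructs the peptide
#' from the singly charged b/y ion ladder by a depth-first prefix walk -- at
#' each step a residue is a viable extension if its b-ion or complementary
#' y-ion is observed, and the walk closes when the remaining mass equals a
#' single residue (which has no fragment ion of its own). Backtracking makes
#' the read robust to coincidental near-matches that derail a purely greedy
#' walk. It is deliberately independent of the neural network path.
#'
#' @param s A [spectrum()].
#' @param tol Peak-matching tolerance in Th (default 1e-4; the clean
#'   simulator emits exact theoretical masses, and a tight tolerance
#'   prevents coincidental matches from opening spurious search branches).
#' @return The reconstructed peptide string, or `NA` if no walk succeeds.
#' @export
ladder_read_peptide <- function(s, tol = 1e-4) {
  M <- precursor_neutral_mass(s$precursor_mz, s$charge)
  target <- M - WATER_MASS # total residue mass
  walk <- function(prefix, depth) {
    if (depth > MAX_PEPTIDE_LENGTH) return(NA_character_)
    remaining <- target - prefix
    hit <- which(abs(RESIDUE_MASS - remaining) < tol)
    if (length(hit)) return(names(RESIDUE_MASS)[hit[1]])
    for (r in AA_RESIDUES) {
      b <- prefix + RESIDUE_MASS[[r]] + PROTON_MASS
      y <- target - (prefix + RESIDUE_MASS[[r]]) + WATER_MASS + PROTON_MASS
      if (any(abs(s$mz - b) < tol) || any(abs(s$mz - y) < tol)) {
        rest <- walk(prefix + RESIDUE_MASS[[r]], depth + 1L)
        if (!is.na(rest)) return(paste0(r, rest))
      }
    }
    NA_character_
  }
  walk(0, 1L)
}
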