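# Turning a probability matrix into a peptide: greedy decoding, quality
# scoring and precursor-mass rescue.

#' Greedy decode of a probability matrix
#'
#' Scans the 32 positions left to right and emits the argmax class of each
#' column (ties broken by the lowest class index), stopping exclusively at
#' the first column whose argmax is the end symbol. An argmax of the start
#' or padding symbol before the end symbol is a decode failure. If no end
#' symbol appears within 31 positions the decode is truncated at 30
#' residues and flagged.
#'
#' @param prob_matrix `23 x 32` matrix; each column a distribution over the
#'   23 classes.
#' @return List with `peptide` (string, empty on failure),
#'   `position_probs` (probabilities of the emitted residues), `failed` and
#'   `truncated` flags.
#' @export
greedy_decode <- function(prob_matrix) {
  residues <- character(0)
  probs <- numeric(0)
  for (pos in seq_len(ncol(prob_matrix))) {
    cls <- which.max(prob_matrix[, pos]) # which.max takes the first maximum
    if (cls == CLASS_END) {
      return(list(peptide = paste(residues, collapse = ""),
                  position_probs = probs,
                  failed = length(residues) == 0L, truncated = FALSE))
    }
    if (cls %in% c(CLASS_START, CLASS_PAD)) {
      return(list(peptide = "", position_probs = numeric(0),
                  failed = TRUE, truncated = FALSE))
    }
    if (length(residues) == MAX_PEPTIDE_LENGTH) {
      return(list(peptide = paste(residues, collapse = ""),
                  position_probs = probs, failed = FALSE, truncated = TRUE))
    }
    residues <- c(residues, AA_RESIDUES[cls])
    probs <- c(probs, prob_matrix[cls, pos])
  }
  list(peptide = paste(residues, collapse = ""), position_probs = probs,
       failed = FALSE, truncated = TRUE)
}

#' Quality score of a decoded peptide
#'
#' The product of the probabilities of the decoded residues (the end
#' symbol's probability is excluded). An empty decode scores 0 by
#' convention.
#'
#' @param position_probs Numeric vector of per-residue probabilities.
#' @return Scalar in `[0, 1]`.
#' @export
quality_score <- function(position_probs) {
  if (length(position_probs) == 0L) return(0)
  prod(position_probs)
}

#' Precursor-mass rescue
#'
#' If the greedily decoded peptide's theoretical mass is within `tol_ppm` of
#' the experimental precursor neutral mass it is returned unchanged.
#' Otherwise each position in turn (left to right) is substituted with that
#' column's second most probable residue class; the first single-substitution
#' candidate whose mass matches the precursor within tolerance is returned
#' with the `rescued` flag set (and the quality score updated with the
#' substituted probability). If no candidate matches, the original peptide
#' is returned with `passed_mass_filter = FALSE`.
#'
#' @param prob_matrix `23 x 32` probability matrix.
#' @param decoded Result of [greedy_decode()] on `prob_matrix`.
#' @param precursor_neutral Experimental precursor neutral mass in Da.
#' @param tol_ppm Precursor tolerance in ppm (default 10).
#' @return A list (one sequencing result) with `peptide`, `position_probs`,
#'   `quality_score`, `theoretical_mass`, `ppm_to_precursor`, `rescued`,
#'   `passed_mass_filter`, `failed`, `truncated`.
#' @export
precursor_mass_rescue <- function(prob_matrix, decoded, precursor_neutral,
                                  tol_ppm = 10) {
  finish <- function(peptide, probs, rescued) {
    mass <- if (nzchar(peptide)) peptide_mono_mass(peptide) else NA_real_
    ppm <- if (is.na(mass)) Inf else ppm_difference(mass, precursor_neutral)
    list(
      peptide = peptide, position_probs = probs,
      quality_score = quality_score(probs),
      theoretical_mass = mass, ppm_to_precursor = ppm,
      rescued = rescued, passed_mass_filter = is.finite(ppm) & ppm <= tol_ppm,
      failed = decoded$failed, truncated = decoded$truncated
    )
  }
  if (decoded$failed || !nzchar(decoded$peptide)) {
    return(finish(decoded$peptide, decoded$position_probs, FALSE))
  }
  base <- finish(decoded$peptide, decoded$position_probs, FALSE)
  if (base$passed_mass_filter) return(base)
  r <- peptide_residues(decoded$peptide)
  base_mass <- base$theoretical_mass
  for (pos in seq_along(r)) {
    col <- prob_matrix[seq_len(20L), pos] # substitutions stay within residues
    o <- order(-col)
    runner <- o[if (AA_RESIDUES[o[1]] == r[pos]) 2L else 1L]
    cand_mass <- base_mass - RESIDUE_MASS[[r[pos]]] + RESIDUE_MASS[[runner]]
    if (ppm_difference(cand_mass, precursor_neutral) <= tol_ppm) {
      cand <- r
      cand[pos] <- AA_RESIDUES[runner]
      probs <- decoded$position_probs
      probs[pos] <- col[runner]
      return(finish(paste(cand, collapse = ""), probs, TRUE))
    }
  }
  base
}

# Decode + rescue for one spectrum's probability matrix.
sequence_one <- function(prob_matrix, precursor_mz, charge, tol_ppm = 10) {
  dec <- greedy_decode(prob_matrix)
  precursor_mass_rescue(prob_matrix, dec,
                        precursor_neutral_mass(precursor_mz, charge), tol_ppm)
}
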