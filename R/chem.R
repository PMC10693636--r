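# Amino-acid alphabet, monoisotopic mass arithmetic and ppm comparisons.
# All masses are monoisotopic and in Daltons.

#' @rdname mass_constants
#' @export
PROTON_MASS <- 1.0072765

#' Mass constants
#'
#' Monoisotopic mass of a proton and of water, used throughout for fragment
#' and precursor mass arithmetic.
#'
#' @name mass_constants
#' @export
WATER_MASS <- 18.0105646

# Monoisotopic residue masses of the 20 standard amino acids (Da),
# unmodified side chains (Cys carries no fixed modification by default).
RESIDUE_MASS <- c(
  A = 71.03711, C = 103.00919, D = 115.02694, E = 129.04259,
  F = 147.06841, G = 57.02146, H = 137.05891, I = 113.08406,
  K = 128.09496, L = 113.08406, M = 131.04049, N = 114.04293,
  P = 97.05276, Q = 128.05858, R = 156.10111, S = 87.03203,
  T = 101.04768, V = 99.06841, W = 186.07931, Y = 163.06333
)

# Class alphabet: 20 residues then START, END, PAD -> 23 classes.
AA_RESIDUES <- names(RESIDUE_MASS)
AA_SPECIALS <- c("<s>", "<e>", "_")
AA_CLASSES <- c(AA_RESIDUES, AA_SPECIALS)
CLASS_START <- 21L
CLASS_END <- 22L
CLASS_PAD <- 23L
N_CLASSES <- 23L
MAX_PEPTIDE_LENGTH <- 30L
OUTPUT_POSITIONS <- 32L

#' The amino-acid class alphabet
#'
#' Returns the ordered class alphabet used by the decoder: the 20 standard
#' one-letter residue codes followed by the three special symbols (start,
#' end, padding), 23 classes in total. Residue classes 1..20 carry their
#' monoisotopic masses; specials have mass zero.
#'
#' @return A list with `residues`, `specials`, `classes`, `residue_mass`,
#'   and the 1-based class indices of the specials.
#' @export
#' @examples
#' aa_alphabet()$residue_mass[["G"]]
aa_alphabet <- function() {
  list(
    residues = AA_RESIDUES,
    specials = AA_SPECIALS,
    classes = AA_CLASSES,
    residue_mass = RESIDUE_MASS,
    start_class = CLASS_START,
    end_class = CLASS_END,
    pad_class = CLASS_PAD
  )
}

#' Validate a peptide string
#'
#' A valid peptide is a non-empty string over the 20 standard residue codes
#' with length at most 30 (the decoder's positional capacity).
#'
#' @param sequence Character vector of peptide strings.
#' @param max_length Maximum allowed length (default 30).
#' @return Logical vector.
#' @export
is_valid_peptide <- function(sequence, max_length = MAX_PEPTIDE_LENGTH) {
  nzchar(sequence) &
    nchar(sequence) <= max_length &
    !grepl(sprintf("[^%s]", paste(AA_RESIDUES, collapse = "")), sequence)
}

peptide_residues <- function(sequence) {
  strsplit(sequence, "", fixed = TRUE)[[1]]
}

#' Monoisotopic peptide mass
#'
#' Sum of residue masses plus one water (the neutral, uncharged peptide).
#' The empty string is treated as zero residues and returns the mass of
#' water; this degenerate case is used internally for prefix arithmetic.
#'
#' @param sequence Character vector of peptide strings over the standard
#'   20-letter alphabet.
#' @return Numeric vector of monoisotopic masses in Da.
#' @export
#' @examples
#' peptide_mono_mass("G") # 75.03203
peptide_mono_mass <- function(sequence) {
  vapply(sequence, function(s) {
    if (!nzchar(s)) return(WATER_MASS)
    r <- peptide_residues(s)
    m <- RESIDUE_MASS[r]
    if (anyNA(m)) {
      stop("invalid peptide: unknown residue code in ", sQuote(s))
    }
    sum(m) + WATER_MASS
  }, numeric(1), USE.NAMES = FALSE)
}

#' Neutral precursor mass from m/z and charge
#'
#' `charge * (precursor_mz - proton)`: removes the charge-carrying protons
#' from the measured mass-to-charge ratio.
#'
#' @param precursor_mz Precursor m/z in Thomson; must be positive.
#' @param charge Integer charge state in 1..8.
#' @return Neutral monoisotopic mass in Da.
#' @export
precursor_neutral_mass <- function(precursor_mz, charge) {
  if (any(precursor_mz <= 0)) stop("precursor m/z must be positive")
  if (any(charge < 1 | charge > 8 | charge != round(charge))) {
    stop("charge must be an integer in [1, 8]")
  }
  charge * (precursor_mz - PROTON_MASS)
}

#' Parts-per-million mass difference
#'
#' `|m1 - m2| / m2 * 1e6`, with `m2` the reference mass (here, conventionally
#' the experimental precursor neutral mass).
#'
#' @param m1,m2 Masses in Da; `m2` must be positive.
#' @return Non-negative ppm difference.
#' @export
ppm_difference <- function(m1, m2) {
  if (any(m2 <= 0)) stop("reference mass must be positive")
  abs(m1 - m2) / m2 * 1e6
}

#' Theoretical fragment ion m/z
#'
#' m/z of a b- or y-ion of a peptide. For a fragment of charge z,
#' `b_i = (sum of first i residues + z * proton) / z` and
#' `y_j = (sum of last j residues + water + z * proton) / z`, so
#' complementary singly charged pairs satisfy
#' `b_i + y_{n-i} = M + 2 * proton`.
#'
#' @param sequence Peptide string.
#' @param ion_type `"b"` or `"y"`.
#' @param index Fragment index, 1..(length - 1).
#' @param frag_charge Fragment charge, >= 1 (default 1).
#' @return Fragment m/z in Thomson.
#' @export
fragment_mz <- function(sequence, ion_type = c("b", "y"), index, frag_charge = 1L) {
  ion_type <- match.arg(ion_type)
  r <- peptide_residues(sequence)
  n <- length(r)
  if (any(index < 1 | index > n - 1)) {
    stop("fragment index must be in [1, length - 1]")
  }
  if (frag_charge < 1) stop("fragment charge must be >= 1")
  m <- RESIDUE_MASS[r]
  if (anyNA(m)) stop("invalid peptide: unknown residue code")
  cum <- cumsum(m)
  neutral <- if (ion_type == "b") {
    cum[index]
  } else {
    cum[n] - cum[n - index] + WATER_MASS
  }
  unname((neutral + frag_charge * PROTON_MASS) / frag_charge)
}

#' Leu/Ile-collapsed residue equivalence
#'
#' Leucine and isoleucine are isomeric and indistinguishable by fragment
#' mass, so all accuracy metrics treat them as equal.
#'
#' @param a,b Single residue codes (vectorized).
#' @return Logical vector.
#' @export
residues_equivalent <- function(a, b) {
  a == b | (a %in% c("I", "L") & b %in% c("I", "L"))
}

# Canonicalize I -> L for string-level comparisons under the equivalence.
collapse_il <- function(sequence) {
  gsub("I", "L", sequence, fixed = TRUE)
}
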