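# Spectrum -> fixed-size network input: precursor removal, top-k retention,
# binning + normalization, channel stacking, meta vector.

#' Encoding configuration
#'
#' Controls how a peak list becomes the network's input matrix. With the
#' defaults, the m/z range 0--2000 Th at 0.1 Th per bin gives 20,000 bins,
#' zero-padded to 20,480 so that five successive halvings stay integral.
#'
#' @param bin_width Bin width in Thomson (default 0.1).
#' @param mz_max Upper m/z bound; peaks at or above it are discarded
#'   (default 2000).
#' @param padded_length Padded vector length; must be at least
#'   `mz_max / bin_width` and divisible by `2^5` (default 20480).
#' @param precursor_removal_window Half-width in Th of the window around the
#'   precursor m/z whose peaks are removed (default 1.5, covering the
#'   isotopic envelope).
#' @param top_k_peaks Optional: keep only the k most intense peaks before
#'   binning (`NULL` keeps all).
#' @return An object of class `"encoding_config"`.
#' @export
encoding_config <- function(bin_width = 0.1, mz_max = 2000,
                            padded_length = 20480L,
                            precursor_removal_window = 1.5,
                            top_k_peaks = NULL) {
  n_bins <- as.integer(round(mz_max / bin_width))
  padded_length <- as.integer(padded_length)
  if (padded_length < n_bins) {
    stop("padded_length must be >= mz_max / bin_width")
  }
  if (padded_length %% 32L != 0L) {
    stop("padded_length must be divisible by 2^5 for the down-sampling stack")
  }
  structure(
    list(
      bin_width = bin_width, mz_max = mz_max, n_bins = n_bins,
      padded_length = padded_length,
      precursor_removal_window = precursor_removal_window,
      top_k_peaks = top_k_peaks
    ),
    class = "encoding_config"
  )
}

#' Remove peaks around the precursor m/z
#'
#' Drops every peak whose m/z lies within `window` Th (inclusive) of the
#' precursor m/z; all other peaks are untouched.
#'
#' @param s A [spectrum()].
#' @param window Half-width in Th (> 0).
#' @return The spectrum with matching peaks removed.
#' @export
remove_precursor_peaks <- function(s, window = 1.5) {
  if (window <= 0) stop("window must be positive")
  keep <- abs(s$mz - s$precursor_mz) > window
  s$mz <- s$mz[keep]
  s$intensity <- s$intensity[keep]
  s
}

#' Retain the k most intense peaks
#'
#' Keeps the `k` highest-intensity peaks (all peaks if fewer than `k`),
#' re-sorted by m/z. Ties at rank `k` are broken in favour of lower m/z.
#'
#' @param s A [spectrum()].
#' @param k Number of peaks to keep (>= 1).
#' @return The thinned spectrum.
#' @export
retain_top_k <- function(s, k) {
  if (k < 1) stop("k must be >= 1")
  n <- length(s$mz)
  if (n <= k) return(s)
  o <- order(-s$intensity, s$mz)[seq_len(k)]
  keep <- sort(o)
  s$mz <- s$mz[keep]
  s$intensity <- s$intensity[keep]
  s
}

#' Bin and normalize a spectrum
#'
#' Peaks are assigned to half-open bins `[i*w, (i+1)*w)` by
#' `floor(mz / bin_width)` (0-based); peaks beyond `mz_max` are discarded;
#' colliding peaks within a bin keep the maximum (or sum, by configuration);
#' the vector is divided by its global maximum so the largest entry is 1,
#' then zero-padded to `padded_length`. An empty spectrum yields the zero
#' vector.
#'
#' @param s A [spectrum()].
#' @param cfg An [encoding_config()].
#' @param collide `"max"` (default) or `"sum"` for peaks sharing a bin.
#' @return Numeric vector of length `cfg$padded_length` in `[0, 1]`.
#' @export
bin_and_normalize <- function(s, cfg = encoding_config(), collide = c("max", "sum")) {
  collide <- match.arg(collide)
  v <- numeric(cfg$padded_length)
  keep <- s$mz >= 0 & s$mz < cfg$mz_max & s$intensity > 0
  mz <- s$mz[keep]
  it <- s$intensity[keep]
  if (length(mz) == 0L) return(v)
  idx <- floor(mz / cfg$bin_width) + 1 # 1-based storage of 0-based bins
  if (collide == "max") {
    agg <- tapply(it, idx, max)
  } else {
    agg <- tapply(it, idx, sum)
  }
  v[as.integer(names(agg))] <- as.numeric(agg)
  v / max(v)
}

#' Build the 4-channel input matrix
#'
#' Channel 1 holds the binned normalized intensities; channel 2 the
#' bin-center m/z scaled by `mz_max` and damped to `[0, 0.1]` (zero in the
#' padding region); channels 3 and 4 are channels 1 and 2 reversed along
#' the bin axis. The damping keeps the dense, input-independent m/z ramp
#' from dominating the activation variance over the sparse peak channel,
#' which measurably shortens the early training plateau.
#'
#' @param intensities Vector from [bin_and_normalize()].
#' @param cfg The [encoding_config()] used to produce it.
#' @return A `padded_length x 4` numeric matrix.
#' @export
build_input_matrix <- function(intensities, cfg = encoding_config()) {
  L <- cfg$padded_length
  stopifnot(length(intensities) == L)
  mzc <- numeric(L)
  i <- seq_len(cfg$n_bins)
  mzc[i] <- ((i - 1) + 0.5) * cfg$bin_width / cfg$mz_max * MZ_CHANNEL_SCALE
  cbind(intensities, mzc, rev(intensities), rev(mzc), deparse.level = 0)
}

# amplitude of the m/z ramp channel relative to the unit intensity channel
MZ_CHANNEL_SCALE <- 0.1

#' Build the meta-information vector
#'
#' Charge one-hot over 1..8, precursor m/z scaled by `mz_max`, and normalized
#' collision energy divided by 100 (0 when unknown); fixed length 10.
#'
#' @param s A [spectrum()].
#' @param cfg An [encoding_config()] (supplies `mz_max`).
#' @return Numeric vector of length 10.
#' @export
build_meta_vector <- function(s, cfg = encoding_config()) {
  if (s$charge < 1 || s$charge > 8) stop("charge must be in [1, 8]")
  onehot <- numeric(8)
  onehot[s$charge] <- 1
  nce <- if (is.na(s$collision_energy)) 0 else s$collision_energy / 100
  c(onehot, s$precursor_mz / cfg$mz_max, nce)
}

#' Encode one spectrum end to end
#'
#' Applies precursor-peak removal, optional top-k retention, binning and
#' channel stacking, and builds the meta vector.
#'
#' @param s A [spectrum()].
#' @param cfg An [encoding_config()].
#' @return List with `matrix` (`padded_length x 4`) and `meta` (length 10).
#' @export
encode_spectrum <- function(s, cfg = encoding_config()) {
  s <- remove_precursor_peaks(s, cfg$precursor_removal_window)
  if (!is.null(cfg$top_k_peaks)) s <- retain_top_k(s, cfg$top_k_peaks)
  v <- bin_and_normalize(s, cfg)
  list(matrix = build_input_matrix(v, cfg), meta = build_meta_vector(s, cfg))
}

# Encode a list of spectra into the flat arrays consumed by the C++ model:
# input array dim (4, L, B) and meta matrix (10, B).
encode_batch <- function(spectra, cfg) {
  B <- length(spectra)
  L <- cfg$padded_length
  x <- array(0, dim = c(4L, L, B))
  meta <- matrix(0, nrow = 10L, ncol = B)
  for (j in seq_len(B)) {
    e <- encode_spectrum(spectra[[j]], cfg)
    x[, , j] <- t(e$matrix)
    meta[, j] <- e$meta
  }
  list(x = x, meta = meta)
}
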