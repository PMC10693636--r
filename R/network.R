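# Model configuration, weight initialization and forward interface to the
# compiled network.

#' Model configuration
#'
#' Architecture of the dilated-convolution sequencing network: five TCN
#' blocks whose channel widths grow by roughly 1.5x while max pooling halves
#' the resolution between blocks, a bottom-up fusion branch pooling every
#' block's output to the 32 decoder steps, a sigmoid-transformed
#' meta-information vector broadcast to every step, and a per-position
#' softmax decoder over 23 classes.
#'
#' Each TCN block holds `n_layers` dilated levels (dilation 1, 2, ...,
#' 2^(n_layers-1)); a level is two symmetric (non-causal) convolutions of
#' width `kernel` with layer normalization and ReLU, wrapped in a residual
#' connection, so one block's receptive field is
#' `1 + 2 * (kernel - 1) * (2^n_layers - 1)` bins (see [receptive_field()]).
#'
#' @param padded_length Input vector length; must be divisible by `2^5`
#'   (default 20480).
#' @param n_blocks Number of TCN blocks (default 5).
#' @param n_layers Dilated levels per block (default 5).
#' @param kernel Convolution kernel width (default 5).
#' @param channels Channel plan per block (default
#'   `c(192, 288, 384, 576, 768)` scaled by `scale`).
#' @param scale Uniform multiplier on the channel plan for desk-scale
#'   models; 1 reproduces the full plan (default 1).
#' @param fusion_width Channel width of the fused feature tensor (default:
#'   last entry of the scaled channel plan).
#' @param meta_hidden Width of the transformed meta vector (default 32).
#' @param output_positions Decoder positions (default 32; must be at least
#'   the maximum peptide length + 2).
#' @param output_classes Decoder classes (default 23).
#' @return An object of class `"convnovo_model_config"`.
#' @export
convnovo_model_config <- function(padded_length = 20480L,
                                  n_blocks = 5L, n_layers = 5L, kernel = 5L,
                                  channels = c(192L, 288L, 384L, 576L, 768L),
                                  scale = 1,
                                  fusion_width = NULL,
                                  meta_hidden = 32L,
                                  output_positions = 32L,
                                  output_classes = 23L) {
  channels <- as.integer(pmax(2L, round(channels * scale)))
  if (length(channels) != n_blocks) {
    stop("channels must have one entry per block")
  }
  if (padded_length %% 2^n_blocks != 0) {
    stop("padded_length must be divisible by 2^n_blocks")
  }
  if (output_positions < MAX_PEPTIDE_LENGTH + 2L) {
    stop("output_positions must be at least max peptide length + 2")
  }
  if (is.null(fusion_width)) fusion_width <- channels[n_blocks]
  structure(
    list(
      padded_length = as.integer(padded_length),
      n_blocks = as.integer(n_blocks),
      n_layers = as.integer(n_layers),
      kernel = as.integer(kernel),
      channels = channels,
      fusion_width = as.integer(fusion_width),
      fusion_kernel = 9L,
      fusion_dilation2 = 3L,
      meta_hidden = as.integer(meta_hidden),
      output_positions = as.integer(output_positions),
      output_classes = as.integer(output_classes)
    ),
    class = "convnovo_model_config"
  )
}

#' Receptive field of a TCN block
#'
#' `1 + 2 * (kernel_size - 1) * (2^n - 1)` input bins, for a block of `n`
#' dilated levels of two width-`kernel_size` convolutions each, with
#' dilation doubling per level.
#'
#' @param kernel_size Convolution kernel width (>= 1).
#' @param n_layers Number of dilated levels (>= 1).
#' @return Receptive field in bins.
#' @export
#' @examples
#' receptive_field(3, 1) # 5
receptive_field <- function(kernel_size, n_layers) {
  stopifnot(kernel_size >= 1, n_layers >= 1)
  1 + 2 * (kernel_size - 1) * (2^n_layers - 1)
}

#' Empirical receptive-field probe
#'
#' Builds the convolution topology of one TCN block (two convolutions per
#' dilated level plus the residual connection) with unit weights and linear
#' activations, places a unit gradient at the centre output position, and
#' returns the number of input positions receiving nonzero gradient.
#'
#' @inheritParams receptive_field
#' @param length Probe signal length (default: comfortably larger than the
#'   theoretical receptive field).
#' @return Width of the nonzero gradient support in bins.
#' @export
receptive_field_probe <- function(kernel_size, n_layers, length = NULL) {
  rf <- receptive_field(kernel_size, n_layers)
  if (is.null(length)) length <- as.integer(2 * rf + 64)
  cn_rf_probe(as.integer(kernel_size), as.integer(n_layers), as.integer(length))
}

# Create a compiled model handle with freshly initialized weights.
# He-normal for weights (sd = sqrt(2 / fan_in)), zeros for biases,
# ones/zeros for layer-norm gain/bias. The second convolution of every
# residual level starts at zero so each block is the identity at
# initialization, which keeps early signal propagation clean through the
# deep stack. Uses the current R RNG state.
init_model <- function(mcfg) {
  handle <- cn_create(unclass(mcfg))
  mf <- cn_param_manifest(handle)
  weights <- vector("list", length(mf$name))
  names(weights) <- mf$name
  for (i in seq_along(mf$name)) {
    nr <- mf$nrow[i]
    nc <- mf$ncol[i]
    weights[[i]] <- switch(mf$kind[i],
      weight = matrix(rnorm(nr * nc, sd = sqrt(2 / nc)), nr, nc),
      bias = matrix(0, nr, nc),
      ln_gain = matrix(1, nr, nc),
      ln_bias = matrix(0, nr, nc)
    )
    if (grepl("_c1_W$", mf$name[i])) weights[[i]][] <- 0
  }
  cn_set_weights(handle, weights)
  handle
}

# Rebuild a handle from a saved weight list.
restore_model <- function(mcfg, weights) {
  handle <- cn_create(unclass(mcfg))
  cn_set_weights(handle, weights)
  handle
}

# softmax over the class dimension of a (classes x positions x B) logits array
softmax_classes <- function(logits) {
  d <- dim(logits)
  m <- matrix(logits, nrow = d[1])
  cmax <- m[cbind(max.col(t(m), ties.method = "first"), seq_len(ncol(m)))]
  m <- exp(sweep(m, 2, cmax))
  m <- sweep(m, 2, colSums(m), "/")
  dim(m) <- d
  m
}

# Forward pass on a list of spectra; returns list of probability matrices
# (23 x 32) and raw aux-head logits.
forward_spectra <- function(handle, spectra, ecfg, batch_size = 16L,
                            training = FALSE) {
  n <- length(spectra)
  probs <- vector("list", n)
  aux <- NULL
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    enc <- encode_batch(spectra[idx], ecfg)
    out <- cn_forward(handle, enc$x, enc$meta, training)
    p <- softmax_classes(out$logits)
    for (j in seq_along(idx)) probs[[idx[j]]] <- p[, , j]
  }
  probs
}
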