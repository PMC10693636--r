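# Shared fixtures: small spectra, random peptides and probability matrices
# built in code at test time.

ALPHABET20 <- aa_alphabet()$residues

rand_peptide_str <- function(min_len = 5, max_len = 15,
                             alphabet = ALPHABET20) {
  n <- min_len + sample.int(max_len - min_len + 1L, 1L) - 1L
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

toy_spectrum <- function(id = "s1",
                         mz = c(100.05, 250.2, 900.9),
                         intensity = c(5, 10, 2),
                         precursor_mz = 500.25, charge = 2L, ...) {
  spectrum(id = id, mz = mz, intensity = intensity,
           precursor_mz = precursor_mz, charge = charge, ...)
}

# probability matrix with the given class sequence one-hot (residue classes
# then END), PAD after; optionally softened towards uniform
onehot_prob_matrix <- function(peptide, soft = 0) {
  cls <- convnovo:::encode_target_classes(peptide)
  m <- matrix(soft / 23, nrow = 23, ncol = 32)
  for (p in seq_len(32)) m[cls[p], p] <- m[cls[p], p] + (1 - soft)
  m
}

random_prob_matrix <- function() {
  m <- matrix(rexp(23 * 32), nrow = 23)
  sweep(m, 2, colSums(m), "/")
}

# a fast micro model configuration used by training smoke tests
micro_configs <- function(seed = 11L, epochs = 2L) {
  cfg <- desk_configs(seed = seed, epochs = epochs)
  cfg$model <- convnovo_model_config(
    padded_length = 800L, channels = c(4L, 6L, 8L, 12L, 16L),
    n_layers = 2L, kernel = 3L, meta_hidden = 8L
  )
  cfg$training <- convnovo_training_config(epochs = epochs, seed = seed)
  cfg
}

# a config file keeping the smoke chain small and fast
write_smoke_config <- function(path) {
  jsonlite::write_json(list(
    simulator = list(
      alphabet = c("G", "A", "S", "V", "L", "E", "F", "R"),
      length_range = c(6, 10), tryptic_fraction = 0.5,
      charge_distribution = list(`2` = 1),
      ion_detect_prob = 0.95, b12_detect_prob = 0.5,
      noise_lambda = 5, precursor_jitter_ppm = 2, mz_max = 1600
    ),
    encoding = list(bin_width = 2, mz_max = 1600, padded_length = 800),
    model = list(channels = c(4, 6, 8, 12, 16), n_layers = 2, kernel = 3,
                 meta_hidden = 8),
    training = list(epochs = 1, batch_size = 16)
  ), path, auto_unbox = TRUE)
  path
}
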