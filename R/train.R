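# Model fitting: peptide-disjoint splitting, the training loop, and the
# "convnovo" fitted-model class.

#' Training configuration
#'
#' @param epochs Number of training epochs (default 50).
#' @param batch_size Spectra per optimization step (default 32).
#' @param learning_rate Optimizer learning rate (default 0.02, paired with
#'   the rectified-Adam optimizer whose warmup tempers early steps).
#' @param optimizer `"radam"` (default) or `"adam"`.
#' @param mae_weight Weight `c` of the expected-mass MAE term; keep small
#'   enough that `c * MAE` stays at or below 10% of the total loss
#'   (default 1e-4, chosen so the early-training mass term respects the cap).
#' @param aux_weights Named weights of the five auxiliary tasks (see
#'   [default_aux_weights()]).
#' @param val_fraction Fraction of peptides held out for epoch selection
#'   (default 0.1); ignored when validation data are supplied directly.
#' @param dropout Inverted-dropout probability on the flattened feature
#'   input of the decoder head during training (default 0.3); regularizes
#'   the wide head against memorizing training peptides.
#' @param weight_decay Decoupled weight decay on weight matrices
#'   (default 1e-4).
#' @param augment Re-simulate measurement variability each epoch: every
#'   training spectrum gets independent peak dropout and log-normal
#'   intensity jitter before encoding (default TRUE). The spectra and their
#'   peptides are unchanged; only the nuisance variation is resampled, which
#'   pushes the model towards the fragment-ladder signal rather than
#'   idiosyncrasies of individual training spectra.
#' @param peak_dropout Per-peak drop probability under augmentation
#'   (default 0.1).
#' @param intensity_jitter Log-scale standard deviation of the multiplicative
#'   intensity jitter under augmentation (default 0.3).
#' @param seed Integer seed driving all randomness (weight initialization,
#'   splits, batch order, dropout, augmentation).
#' @return An object of class `"convnovo_training_config"`.
#' @export
convnovo_training_config <- function(epochs = 50L, batch_size = 32L,
                                     learning_rate = 0.02,
                                     optimizer = c("radam", "adam"),
                                     mae_weight = 1e-4,
                                     aux_weights = default_aux_weights(),
                                     val_fraction = 0.1,
                                     dropout = 0.3,
                                     weight_decay = 1e-4,
                                     augment = TRUE,
                                     peak_dropout = 0.1,
                                     intensity_jitter = 0.3,
                                     seed = 1L) {
  optimizer <- match.arg(optimizer)
  stopifnot(mae_weight >= 0, all(aux_weights >= 0),
            dropout >= 0, dropout < 1, weight_decay >= 0)
  structure(
    list(
      epochs = as.integer(epochs), batch_size = as.integer(batch_size),
      learning_rate = learning_rate, optimizer = optimizer,
      mae_weight = mae_weight, aux_weights = aux_weights,
      val_fraction = val_fraction,
      dropout = dropout, weight_decay = weight_decay,
      augment = isTRUE(augment), peak_dropout = peak_dropout,
      intensity_jitter = intensity_jitter,
      seed = as.integer(seed)
    ),
    class = "convnovo_training_config"
  )
}

# resample the nuisance variation of a spectrum: drop peaks, jitter
# intensities (the peak set and peptide identity stay those of the input)
augment_spectrum <- function(s, peak_dropout, intensity_jitter) {
  n <- length(s$mz)
  if (n == 0L) return(s)
  keep <- runif(n) >= peak_dropout
  if (!any(keep)) keep[sample.int(n, 1L)] <- TRUE
  s$mz <- s$mz[keep]
  s$intensity <- s$intensity[keep] *
    exp(rnorm(sum(keep), 0, intensity_jitter))
  s
}

#' Peptide-disjoint data split
#'
#' Partitions spectra so that no peptide occurs in more than one split: all
#' spectra of a peptide travel together. Peptide groups are shuffled
#' deterministically under the seed and assigned by cumulative spectrum
#' count against the requested fractions.
#'
#' @param peptides Character vector, one peptide per spectrum.
#' @param fractions Numeric vector of split fractions summing to 1 (named
#'   or not), e.g. `c(train = 0.956, val = 0.018, test = 0.025)`.
#' @param seed Integer seed.
#' @return List of integer index vectors, one per fraction.
#' @export
split_by_peptide <- function(peptides, fractions, seed = 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8)
  groups <- split(seq_along(peptides), peptides)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  groups <- groups[sample.int(length(groups))]
  sizes <- lengths(groups)
  cum <- cumsum(sizes) / length(peptides)
  edge <- cumsum(fractions)
  assignment <- findInterval(cum, edge, left.open = TRUE) + 1L
  assignment <- pmin(assignment, length(fractions))
  out <- lapply(seq_along(fractions), function(k) {
    sort(unlist(groups[assignment == k], use.names = FALSE))
  })
  names(out) <- names(fractions)
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Fit a de novo sequencing model
#'
#' Trains the dilated-convolution network on spectra with known peptides.
#' Training minimizes the masked cross-entropy on non-padding positions plus
#' a small expected-mass MAE term and the weighted auxiliary-task losses,
#' with the rectified-Adam optimizer. The validation split is peptide
#' disjoint from the training split; the returned model carries the weights
#' of the epoch with the best validation positional accuracy (the average
#' argmax accuracy on non-padding positions).
#'
#' @param spectra List of [spectrum()] objects.
#' @param truth Named character vector mapping spectrum id to peptide;
#'   spectra without a valid ground-truth peptide (or with charge outside
#'   1..8) are dropped with a message.
#' @param model A [convnovo_model_config()]; its `padded_length` must match
#'   `encoding$padded_length`.
#' @param encoding An [encoding_config()].
#' @param training A [convnovo_training_config()].
#' @param validation Optional list(spectra, truth) to use as the validation
#'   set instead of an internal split.
#' @param verbose Print per-epoch progress (default TRUE).
#' @return An object of class `"convnovo"`; see [predict.convnovo()].
#' @export
convnovo <- function(spectra, truth,
                     model = convnovo_model_config(),
                     encoding = encoding_config(),
                     training = convnovo_training_config(),
                     validation = NULL, verbose = TRUE) {
  if (model$padded_length != encoding$padded_length) {
    stop("model and encoding padded_length disagree")
  }
  flt <- filter_spectra(spectra, truth)
  spectra <- flt$spectra
  truth <- flt$truth
  n_dropped <- attr(flt, "n_dropped_charge") + attr(flt, "n_dropped_truth")
  if (n_dropped > 0 && verbose) {
    message(sprintf("dropped %d spectra at ingest filtering", n_dropped))
  }
  if (length(spectra) < 2L) stop("not enough labelled spectra to train on")

  set.seed(training$seed)
  if (is.null(validation)) {
    idx <- split_by_peptide(
      as.character(truth),
      c(train = 1 - training$val_fraction, val = training$val_fraction),
      seed = training$seed
    )
    val <- list(spectra = spectra[idx$val], truth = truth[idx$val])
    spectra <- spectra[idx$train]
    truth <- truth[idx$train]
  } else {
    val <- filter_spectra(validation$spectra, validation$truth)
  }

  handle <- init_model(model)
  n_train <- length(spectra)
  bs <- training$batch_size

  # pre-encode the validation spectra once; training spectra are encoded
  # per epoch when augmentation is on
  enc_train <- if (training$augment) NULL else encode_batch(spectra, encoding)
  enc_val <- encode_batch(val$spectra, encoding)
  target_cls <- vapply(truth, encode_target_classes, integer(OUTPUT_POSITIONS))
  val_cls <- vapply(val$truth, encode_target_classes, integer(OUTPUT_POSITIONS))
  aux_tgt <- batch_aux_targets(as.character(truth))
  true_mass <- peptide_mono_mass(as.character(truth))

  history <- data.frame()
  best <- list(acc = -Inf, epoch = NA_integer_, weights = NULL)
  for (epoch in seq_len(training$epochs)) {
    ord <- sample.int(n_train)
    if (training$augment) {
      enc_epoch <- encode_batch(
        lapply(spectra, augment_spectrum,
               peak_dropout = training$peak_dropout,
               intensity_jitter = training$intensity_jitter),
        encoding
      )
    } else {
      enc_epoch <- enc_train
    }
    ep <- c(ce = 0, mae = 0, aux = 0, total = 0)
    n_batches <- 0L
    for (start in seq(1L, n_train, by = bs)) {
      take <- ord[start:min(start + bs - 1L, n_train)]
      out <- cn_forward(handle, enc_epoch$x[, , take, drop = FALSE],
                        enc_epoch$meta[, take, drop = FALSE], TRUE,
                        training$dropout)
      probs <- softmax_classes(out$logits)

      main <- batch_main_stats(probs, target_cls[, take, drop = FALSE],
                               true_mass[take], training$mae_weight)
      auxb <- batch_aux_stats(out, aux_tgt, take, training$aux_weights)
      tot <- total_loss(main$ce, main$mae, auxb$losses, training$mae_weight,
                        training$aux_weights, warn = n_batches == 0L)
      if (!is.finite(tot)) {
        stop(sprintf("training diverged (non-finite loss) at epoch %d", epoch))
      }

      cn_zero_grad(handle)
      cn_backward(handle, main$grad, auxb$grads$tryptic, auxb$grads$length,
                  auxb$grads$presence, auxb$grads$comp, auxb$grads$pairs,
                  FALSE)
      cn_step(handle, training$learning_rate, training$optimizer,
              training$weight_decay)

      ep <- ep + c(main$ce, main$mae,
                   sum(training$aux_weights[names(auxb$losses)] * auxb$losses),
                   tot)
      n_batches <- n_batches + 1L
    }
    ep <- ep / n_batches
    val_acc <- positional_argmax_accuracy(handle, enc_val, val_cls, bs)
    history <- rbind(history, data.frame(
      epoch = epoch, masked_ce = ep["ce"], mass_mae = ep["mae"],
      aux = ep["aux"], total = ep["total"], val_accuracy = val_acc,
      row.names = NULL
    ))
    if (verbose) {
      message(sprintf(
        "epoch %d/%d  ce %.4f  mae %.2f  aux %.4f  val_acc %.4f",
        epoch, training$epochs, ep["ce"], ep["mae"], ep["aux"], val_acc
      ))
    }
    if (val_acc > best$acc) {
      best <- list(acc = val_acc, epoch = epoch,
                   weights = cn_get_weights(handle))
    }
  }
  cn_free_cache(handle)

  structure(
    list(
      weights = best$weights,
      model_config = model,
      encoding_config = encoding,
      training_config = training,
      history = history,
      best_epoch = best$epoch,
      n_params = cn_n_params(handle),
      n_train = n_train,
      n_val = length(val$spectra),
      call = match.call()
    ),
    class = "convnovo"
  )
}

# average argmax accuracy on non-padding positions over an encoded set
positional_argmax_accuracy <- function(handle, enc, target_cls, batch_size) {
  n <- dim(enc$x)[3]
  if (n == 0L) return(NA_real_)
  acc <- numeric(n)
  for (start in seq(1L, n, by = batch_size)) {
    take <- start:min(start + batch_size - 1L, n)
    out <- cn_forward(handle, enc$x[, , take, drop = FALSE],
                      enc$meta[, take, drop = FALSE], FALSE)
    lg <- matrix(out$logits, nrow = N_CLASSES)
    pred_flat <- max.col(t(lg), ties.method = "first")
    cls_flat <- as.vector(target_cls[, take, drop = FALSE])
    keep <- cls_flat != CLASS_PAD
    sample_of_col <- rep(seq_along(take), each = OUTPUT_POSITIONS)
    hits <- rowsum(as.numeric(pred_flat == cls_flat & keep),
                   sample_of_col)
    tot <- rowsum(as.numeric(keep), sample_of_col)
    acc[take] <- as.vector(hits) / as.vector(tot)
  }
  mean(acc)
}
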