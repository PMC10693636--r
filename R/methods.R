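# S3 methods for the fitted "convnovo" model and checkpoint I/O.

#' Sequence spectra with a fitted model
#'
#' Runs the network forward on each spectrum, greedily decodes the
#' probability matrix, applies the precursor-mass rescue and computes the
#' quality score.
#'
#' @param object A fitted [convnovo()] model.
#' @param spectra List of [spectrum()] objects (`newdata` in `predict`
#'   terms).
#' @param tol_ppm Precursor mass tolerance for the rescue and mass filter
#'   (default 10 ppm).
#' @param batch_size Forward batch size (default 16).
#' @param ... Unused.
#' @return A data frame with one row per spectrum: `spectrum_id`,
#'   `peptide`, `quality_score`, `theoretical_mass`, `ppm_to_precursor`,
#'   `rescued`, `passed_mass_filter`, `failed`, `truncated`, and
#'   `position_probs` (a list column of per-residue probabilities).
#' @export
predict.convnovo <- function(object, spectra, tol_ppm = 10, batch_size = 16L,
                             ...) {
  handle <- restore_model(object$model_config, object$weights)
  probs <- forward_spectra(handle, spectra, object$encoding_config,
                           batch_size = batch_size)
  results <- lapply(seq_along(spectra), function(i) {
    s <- spectra[[i]]
    sequence_one(probs[[i]], s$precursor_mz, s$charge, tol_ppm)
  })
  out <- do.call(rbind, lapply(seq_along(spectra), function(i) {
    res <- results[[i]]
    data.frame(
      spectrum_id = spectra[[i]]$id, peptide = res$peptide,
      quality_score = res$quality_score,
      theoretical_mass = res$theoretical_mass,
      ppm_to_precursor = res$ppm_to_precursor,
      rescued = res$rescued, passed_mass_filter = res$passed_mass_filter,
      failed = res$failed, truncated = res$truncated,
      stringsAsFactors = FALSE
    )
  }))
  out$position_probs <- I(lapply(results, `[[`, "position_probs"))
  attr(out, "prob_matrices") <- probs
  out
}

#' @export
print.convnovo <- function(x, ...) {
  cat("De novo peptide sequencing model (dilated convolutional network)\n")
  cat(sprintf("  input: %d bins x 4 channels; output: %d x %d probability matrix\n",
              x$model_config$padded_length, x$model_config$output_classes,
              x$model_config$output_positions))
  cat(sprintf("  channels: [%s]; %s parameters\n",
              paste(x$model_config$channels, collapse = ", "),
              format(x$n_params, big.mark = ",")))
  cat(sprintf("  trained %d epochs on %d spectra (best epoch %d, val accuracy %.4f)\n",
              nrow(x$history), x$n_train, x$best_epoch,
              max(x$history$val_accuracy)))
  invisible(x)
}

#' @export
summary.convnovo <- function(object, ...) {
  cat("Call:\n  ")
  print(object$call)
  cat("\n")
  print(object)
  cat("\nTraining history (last 5 epochs):\n")
  print(utils::tail(object$history, 5), row.names = FALSE)
  invisible(object)
}

#' @export
coef.convnovo <- function(object, ...) {
  object$weights
}

#' Plot training curves
#'
#' Training loss and validation positional accuracy per epoch, with the
#' selected best epoch marked.
#'
#' @param x A fitted [convnovo()] model.
#' @param ... Passed to [plot()].
#' @export
plot.convnovo <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mar = c(4, 4, 2, 4))
  on.exit(graphics::par(op))
  plot(h$epoch, h$total, type = "b", pch = 16, xlab = "epoch",
       ylab = "training loss", main = "convnovo training", ...)
  graphics::par(new = TRUE)
  plot(h$epoch, h$val_accuracy, type = "b", pch = 1, col = "red3",
       axes = FALSE, xlab = "", ylab = "", ylim = c(0, 1))
  axis(4, col.axis = "red3")
  graphics::mtext("validation positional accuracy", side = 4, line = 2.5,
                  col = "red3")
  graphics::abline(v = x$best_epoch, lty = 3)
  invisible(x)
}

#' Save / load a fitted model
#'
#' The checkpoint is an RDS file with the weights and configurations, plus a
#' human-readable JSON sidecar (`<path>.json`) describing the model
#' configuration and training provenance.
#'
#' @param object A fitted [convnovo()] model.
#' @param path Checkpoint path (e.g. `model.rds`).
#' @return `path` invisibly (`save_convnovo`); the model
#'   (`load_convnovo`).
#' @export
save_convnovo <- function(object, path) {
  saveRDS(object, path)
  sidecar <- list(
    model_config = unclass(object$model_config),
    encoding_config = unclass(object$encoding_config),
    training_config = unclass(object$training_config),
    best_epoch = object$best_epoch,
    n_params = object$n_params,
    n_train = object$n_train
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_convnovo
#' @export
load_convnovo <- function(path) {
  object <- readRDS(path)
  if (!inherits(object, "convnovo")) stop("not a convnovo checkpoint: ", path)
  object
}

#' Write the training log as CSV
#' @param object A fitted [convnovo()] model.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_train_log <- function(object, path) {
  utils::write.csv(object$history, path, row.names = FALSE)
  invisible(path)
}
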