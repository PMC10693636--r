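# Evaluation metrics: positional and peptide-level accuracy with Leu/Ile
# equivalence, precursor-ppm filtering, precision-coverage curves, and the
# peak-retention experiment.

#' Peptide-level correctness
#'
#' A prediction is completely correct when it has the truth's length and
#' every residue matches under Leu/Ile equivalence.
#'
#' @param pred,truth Peptide strings (vectorized).
#' @return Logical vector.
#' @export
peptide_correct <- function(pred, truth) {
  collapse_il(pred) == collapse_il(truth)
}

#' Matched residues under the prefix-mass convention
#'
#' Counts predicted residues that match a ground-truth residue both in
#' identity (Leu/Ile collapsed) and in position, where position agreement
#' means the residues' N-terminal prefix masses agree within `mass_tol`.
#' The two sequences are walked in parallel: when the current prefix masses
#' agree within tolerance the residue pair is compared, otherwise the
#' sequence with the smaller prefix mass advances. A mass-preserving
#' internal substitution therefore de-synchronizes only locally and
#' downstream residues match again. Plain positional index matching is
#' available with `mode = "index"`.
#'
#' @param pred,truth Peptide strings.
#' @param mass_tol Prefix-mass agreement tolerance in Da (default 0.5, the
#'   convention of the tools this metric is shared with).
#' @param mode `"prefix_mass"` (default) or `"index"`.
#' @return Number of matched predicted residues.
#' @export
positional_matches <- function(pred, truth, mass_tol = 0.5,
                               mode = c("prefix_mass", "index")) {
  mode <- match.arg(mode)
  if (!nzchar(pred) || !nzchar(truth)) return(0L)
  rp <- peptide_residues(pred)
  rt <- peptide_residues(truth)
  if (mode == "index") {
    n <- min(length(rp), length(rt))
    return(sum(residues_equivalent(rp[seq_len(n)], rt[seq_len(n)])))
  }
  pp <- cumsum(RESIDUE_MASS[rp])
  pt <- cumsum(RESIDUE_MASS[rt])
  i <- 1L
  j <- 1L
  matched <- 0L
  while (i <= length(rp) && j <= length(rt)) {
    start_p <- if (i == 1L) 0 else pp[i - 1L]
    start_t <- if (j == 1L) 0 else pt[j - 1L]
    if (abs(start_p - start_t) <= mass_tol) {
      if (residues_equivalent(rp[i], rt[j])) matched <- matched + 1L
      i <- i + 1L
      j <- j + 1L
    } else if (start_p < start_t) {
      i <- i + 1L
    } else {
      j <- j + 1L
    }
  }
  matched
}

#' Positional accuracy over an evaluation set
#'
#' Total matched residues (see [positional_matches()]) divided by the total
#' number of ground-truth residues.
#'
#' @param pred,truth Character vectors of equal length (predictions may be
#'   empty strings for failed decodes).
#' @param ... Passed to [positional_matches()].
#' @return Scalar in `[0, 1]`.
#' @export
positional_accuracy <- function(pred, truth, ...) {
  matched <- sum(mapply(positional_matches, pred, truth, MoreArgs = list(...)))
  matched / sum(nchar(truth))
}

#' Peptide accuracy with and without the precursor-mass filter
#'
#' `filtered_peptide_accuracy` restricts the peptide-level accuracy to
#' results whose theoretical mass is within `tol_ppm` of the precursor
#' (removing the apparently wrong identifications); when nothing passes the
#' filter the accuracy is reported as 0 with `n_filtered = 0`.
#'
#' @param pred,truth Character vectors of equal length.
#' @param ppm Numeric vector of precursor ppm differences aligned with
#'   `pred`.
#' @param tol_ppm Filter tolerance (default 10).
#' @return `peptide_accuracy`: scalar. `filtered_peptide_accuracy`: list
#'   with `accuracy`, `n_filtered`, `n_total`.
#' @export
peptide_accuracy <- function(pred, truth) {
  mean(peptide_correct(pred, truth))
}

#' @rdname peptide_accuracy
#' @export
filtered_peptide_accuracy <- function(pred, truth, ppm, tol_ppm = 10) {
  keep <- is.finite(ppm) & ppm <= tol_ppm
  if (!any(keep)) {
    return(list(accuracy = 0, n_filtered = 0L, n_total = length(pred)))
  }
  list(
    accuracy = mean(peptide_correct(pred[keep], truth[keep])),
    n_filtered = sum(keep), n_total = length(pred)
  )
}

#' Precision-coverage curve
#'
#' For each quality-score threshold `t`: coverage is the fraction of ground
#' truth peptides covered by correct results with score at least `t`
#' (correct above-threshold results over all `N` truths), and precision is
#' the fraction of correct results among all results with score at least
#' `t`. With no results above a threshold, precision is reported as 1 with
#' `n_above = 0`.
#'
#' @param pred,truth Character vectors of equal length.
#' @param scores Quality scores aligned with `pred`.
#' @param thresholds Score thresholds; default: the sorted unique scores.
#' @return Data frame `(threshold, precision, coverage, n_above)`, sorted
#'   by threshold.
#' @export
precision_coverage <- function(pred, truth, scores, thresholds = NULL) {
  correct <- peptide_correct(pred, truth)
  if (is.null(thresholds)) thresholds <- sort(unique(scores))
  thresholds <- sort(thresholds)
  rows <- lapply(thresholds, function(t) {
    above <- scores >= t
    n_above <- sum(above)
    data.frame(
      threshold = t,
      precision = if (n_above == 0L) 1 else sum(correct & above) / n_above,
      coverage = sum(correct & above) / length(truth),
      n_above = n_above
    )
  })
  do.call(rbind, rows)
}

#' Smallest cutoff reaching a target precision
#'
#' Returns the smallest quality-score threshold whose precision is at least
#' `target_precision` (with at least one result above it). If no threshold
#' reaches the target, `NA` is returned with a diagnostic attribute.
#'
#' @inheritParams precision_coverage
#' @param target_precision Required precision in `[0, 1]`.
#' @return Scalar threshold, or `NA` if unreachable.
#' @export
choose_cutoff_for_precision <- function(pred, truth, scores,
                                        target_precision) {
  curve <- precision_coverage(pred, truth, scores)
  ok <- curve$precision >= target_precision & curve$n_above > 0L
  if (!any(ok)) {
    out <- NA_real_
    attr(out, "diagnostic") <- sprintf(
      "no cutoff reaches precision %.3f (max attainable %.3f)",
      target_precision, max(curve$precision[curve$n_above > 0L], 0)
    )
    return(out)
  }
  min(curve$threshold[ok])
}

#' Full evaluation report
#'
#' Composes the package's metrics over a result table and ground truth:
#' positional accuracy, peptide accuracy, filtered peptide accuracy,
#' precision-coverage curve, and accuracy broken down by peptide length.
#'
#' @param results Data frame from [predict.convnovo()] or [read_results()].
#' @param truth Named character vector (spectrum id to peptide).
#' @param tol_ppm Precursor filter tolerance (default 10).
#' @param thresholds Optional precision-coverage thresholds.
#' @return A list of class `"convnovo_eval"` with the metric fields.
#' @export
evaluate_denovo <- function(results, truth, tol_ppm = 10, thresholds = NULL) {
  tr <- truth[results$spectrum_id]
  if (anyNA(tr)) stop("missing ground truth for some spectra")
  tr <- as.character(tr)
  pred <- results$peptide
  filt <- filtered_peptide_accuracy(pred, tr, results$ppm_to_precursor,
                                    tol_ppm)
  by_len <- tapply(
    seq_along(tr), nchar(tr),
    function(ii) positional_accuracy(pred[ii], tr[ii])
  )
  structure(
    list(
      n_spectra = length(pred),
      positional_accuracy = positional_accuracy(pred, tr),
      peptide_accuracy = peptide_accuracy(pred, tr),
      filtered_peptide_accuracy = filt$accuracy,
      n_filtered = filt$n_filtered,
      precision_coverage = precision_coverage(pred, tr,
                                              results$quality_score,
                                              thresholds),
      by_length = by_len
    ),
    class = "convnovo_eval"
  )
}

#' @export
print.convnovo_eval <- function(x, ...) {
  cat(sprintf("De novo sequencing evaluation over %d spectra\n", x$n_spectra))
  cat(sprintf("  positional accuracy:        %.4f\n", x$positional_accuracy))
  cat(sprintf("  peptide accuracy:           %.4f\n", x$peptide_accuracy))
  cat(sprintf("  filtered peptide accuracy:  %.4f  (n = %d passing 10 ppm)\n",
              x$filtered_peptide_accuracy, x$n_filtered))
  invisible(x)
}

#' Peak-retention experiment
#'
#' Re-encodes the spectra keeping only the `k` most intense peaks for each
#' `k` in `k_list`, re-decodes with the fitted model, and tabulates the
#' accuracies (an `Inf` entry in `k_list` keeps all peaks).
#'
#' @param object A fitted [convnovo()] model.
#' @param spectra List of [spectrum()] objects.
#' @param truth Named character vector.
#' @param k_list Integer vector of retained-peak counts.
#' @param ... Passed to [predict.convnovo()].
#' @return Data frame `(k, positional_accuracy, peptide_accuracy)`.
#' @export
peak_retention_experiment <- function(object, spectra, truth,
                                      k_list = c(5, 10, 20, 50, Inf), ...) {
  rows <- lapply(k_list, function(k) {
    obj <- object
    if (is.finite(k)) obj$encoding_config$top_k_peaks <- as.integer(k)
    res <- predict(obj, spectra, ...)
    tr <- as.character(truth[res$spectrum_id])
    data.frame(
      k = k,
      positional_accuracy = positional_accuracy(res$peptide, tr),
      peptide_accuracy = peptide_accuracy(res$peptide, tr)
    )
  })
  do.call(rbind, rows)
}
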