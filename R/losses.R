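# Training losses: masked cross-entropy, precursor-mass MAE, auxiliary
# multitask losses, and their gradients with respect to head logits.

# Encode a peptide as decoder class indices over the 32 positions:
# residues 1..len, END at len+1, PAD beyond. START is reserved and never a
# target.
encode_target_classes <- function(sequence, n_pos = OUTPUT_POSITIONS) {
  r <- peptide_residues(sequence)
  cls <- match(r, AA_RESIDUES)
  if (anyNA(cls)) stop("invalid peptide: unknown residue code")
  out <- rep(CLASS_PAD, n_pos)
  out[seq_along(cls)] <- cls
  out[length(cls) + 1L] <- CLASS_END
  out
}

#' Auxiliary multitask targets for a peptide
#'
#' The five auxiliary prediction targets trained next to the main sequencing
#' head: whether the peptide is tryptic (C-terminal K/R), its length (a
#' 30-class label), the presence of each of the 20 residues, its
#' length-normalized amino-acid composition, and the 400 indicator variables
#' of adjacent residue pairs.
#'
#' @param sequence Peptide string.
#' @return List with `tryptic` (0/1), `length` (integer), `presence` (20
#'   0/1), `composition` (20 counts), `pairs` (400 0/1, row-major over
#'   ordered pairs `(first, second)` in alphabet order).
#' @export
auxiliary_targets <- function(sequence) {
  r <- peptide_residues(sequence)
  n <- length(r)
  comp <- as.numeric(table(factor(r, levels = AA_RESIDUES)))
  pairs <- numeric(400)
  if (n >= 2L) {
    a <- match(r[-n], AA_RESIDUES)
    b <- match(r[-1], AA_RESIDUES)
    pairs[(a - 1L) * 20L + b] <- 1
  }
  list(
    tryptic = as.numeric(r[n] %in% c("K", "R")),
    length = n,
    presence = as.numeric(comp > 0),
    composition = comp,
    pairs = pairs
  )
}

#' Masked cross-entropy loss
#'
#' Mean over the non-padding positions (the residues plus the end symbol) of
#' the negative log probability of the target class. Zero if and only if the
#' matrix is one-hot correct on those positions.
#'
#' @param prob_matrix `23 x 32` probability matrix (columns sum to 1).
#' @param sequence Target peptide string.
#' @return Non-negative scalar loss.
#' @export
masked_ce_loss <- function(prob_matrix, sequence) {
  cls <- encode_target_classes(sequence, ncol(prob_matrix))
  keep <- which(cls != CLASS_PAD)
  p <- prob_matrix[cbind(cls[keep], keep)]
  mean(-log(pmax(p, 1e-12)))
}

#' Expected-mass MAE loss
#'
#' Absolute difference between the expected peptide mass under the predicted
#' per-position class distributions and the true peptide mass. The expected
#' mass is `sum over positions and classes of p * residue_mass` (specials
#' carry mass zero) plus water, which makes the loss differentiable in the
#' probabilities.
#'
#' @param prob_matrix `23 x 32` probability matrix.
#' @param true_mass True peptide monoisotopic mass in Da.
#' @return Non-negative loss in Da.
#' @export
mass_mae_loss <- function(prob_matrix, true_mass) {
  abs(expected_peptide_mass(prob_matrix) - true_mass)
}

class_mass_vector <- function() {
  c(RESIDUE_MASS, 0, 0, 0) # START, END, PAD are massless
}

expected_peptide_mass <- function(prob_matrix) {
  sum(class_mass_vector() * rowSums(prob_matrix)) + WATER_MASS
}

#' Auxiliary losses
#'
#' Binary cross-entropy for the tryptic, residue-presence and adjacent-pair
#' heads (means over units), categorical cross-entropy over 30 classes for
#' the length head, and mean squared error on the length-normalized
#' composition. All inputs are head probabilities (the training loop applies
#' sigmoid/softmax to the raw head outputs first).
#'
#' @param predictions List with `tryptic`, `length` (30 probabilities),
#'   `presence`, `composition` (length-normalized), `pairs`.
#' @param targets List from [auxiliary_targets()].
#' @return Named numeric vector of per-task losses (all >= 0).
#' @export
auxiliary_losses <- function(predictions, targets) {
  bce <- function(p, y) {
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    mean(-(y * log(p) + (1 - y) * log(1 - p)))
  }
  len_p <- pmax(predictions$length, 1e-12)
  c(
    tryptic = bce(predictions$tryptic, targets$tryptic),
    length = -log(len_p[targets$length]),
    presence = bce(predictions$presence, targets$presence),
    composition = mean((predictions$composition -
                          targets$composition / targets$length)^2),
    pairs = bce(predictions$pairs, targets$pairs)
  )
}

#' Total training loss
#'
#' `masked_ce + c * MAE + sum of weighted auxiliary losses`. The mass term's
#' weight `c` should be small enough that `c * MAE` stays at or below 10% of
#' the total; a warning is emitted when a logged batch violates this.
#'
#' @param masked_ce Masked cross-entropy value.
#' @param mae Mass MAE value (Da).
#' @param aux Named vector of auxiliary losses (may be zero-length).
#' @param mae_weight The weight `c`.
#' @param aux_weights Named weights matching `aux`.
#' @param warn Emit the 10%-cap warning (default FALSE; the training loop
#'   enables it on logged batches).
#' @return Scalar total loss.
#' @export
total_loss <- function(masked_ce, mae, aux = numeric(0),
                       mae_weight = 1e-4,
                       aux_weights = default_aux_weights(), warn = FALSE) {
  aux_term <- if (length(aux)) sum(aux_weights[names(aux)] * aux) else 0
  tot <- masked_ce + mae_weight * mae + aux_term
  if (warn && tot > 0 && mae_weight * mae > 0.10 * tot) {
    warning(sprintf(
      "mass term c*MAE (%.4g) exceeds 10%% of total loss (%.4g); consider lowering mae_weight",
      mae_weight * mae, tot
    ))
  }
  tot
}

#' @rdname total_loss
#' @export
default_aux_weights <- function() {
  c(tryptic = 0.05, length = 0.2, presence = 0.2, composition = 0.2,
    pairs = 0.2)
}

# ---------------------------------------------------------------------------
# gradients w.r.t. head logits for one batch (used by the training loop)

# Main-head gradient: d(masked_ce + c * MAE)/dlogits for a batch.
# probs: (23 x 32 x B) softmax output; sequences: character vector;
# true_mass: numeric vector. Returns array (23 x 32 x B), averaged over the
# batch.
main_head_gradient <- function(probs, sequences, true_mass, mae_weight) {
  d <- dim(probs)
  B <- d[3]
  grad <- array(0, dim = d)
  mass_vec <- class_mass_vector()
  for (s in seq_len(B)) {
    cls <- encode_target_classes(sequences[s], d[2])
    keep <- which(cls != CLASS_PAD)
    p <- probs[, , s]
    # cross-entropy through softmax: (p - onehot) / n_nonpad on kept columns
    g <- matrix(0, d[1], d[2])
    g[, keep] <- p[, keep] / length(keep)
    g[cbind(cls[keep], keep)] <- g[cbind(cls[keep], keep)] - 1 / length(keep)
    # mass MAE through softmax: sign * J_softmax^T mass_vec on all columns
    sgn <- sign(expected_peptide_mass(p) - true_mass[s])
    if (sgn != 0 && mae_weight > 0) {
      inner <- colSums(p * mass_vec) # per-position expected mass
      gm <- p * (mass_vec - rep(inner, each = d[1]))
      g <- g + mae_weight * sgn * gm
    }
    grad[, , s] <- g / B
  }
  grad
}

# ---------------------------------------------------------------------------
# batched (whole-batch, vectorized) loss/gradient computations used by the
# training loop; the scalar functions above remain the reference definitions

# precompute all auxiliary target matrices for a peptide vector
batch_aux_targets <- function(sequences) {
  n <- length(sequences)
  tgt <- lapply(sequences, auxiliary_targets)
  list(
    tryptic = vapply(tgt, `[[`, numeric(1), "tryptic"),
    length = vapply(tgt, `[[`, numeric(1), "length"),
    presence = vapply(tgt, `[[`, numeric(20), "presence"),
    comp_norm = vapply(tgt, function(t) t$composition / t$length,
                       numeric(20)),
    pairs = vapply(tgt, `[[`, numeric(400), "pairs")
  )
}

# masked-CE + mass-MAE values and the main-head logit gradient for a batch
batch_main_stats <- function(probs, cls_mat, true_mass, mae_weight) {
  d <- dim(probs)
  B <- d[3]
  P <- matrix(probs, nrow = d[1]) # classes x (positions*B)
  cls_flat <- as.vector(cls_mat)
  keep <- cls_flat != CLASS_PAD
  col_id <- seq_len(d[2] * B)
  sample_of_col <- rep(seq_len(B), each = d[2])
  n_nonpad <- as.vector(rowsum(as.numeric(keep), sample_of_col))

  pick <- P[cbind(cls_flat[keep], col_id[keep])]
  ce_per <- as.vector(rowsum(-log(pmax(pick, 1e-12)),
                             sample_of_col[keep])) / n_nonpad
  mass_vec <- class_mass_vector()
  em_col <- colSums(P * mass_vec) # expected mass per (position, sample)
  em <- as.vector(rowsum(em_col, sample_of_col)) + WATER_MASS
  mae_per <- abs(em - true_mass)

  # gradient w.r.t. logits: CE through softmax on non-pad columns, plus the
  # signed mass term through the softmax Jacobian on all columns
  scale_col <- ifelse(keep, 1 / n_nonpad[sample_of_col], 0)
  G <- sweep(P, 2, scale_col, "*")
  idx <- cbind(cls_flat[keep], col_id[keep])
  G[idx] <- G[idx] - 1 / n_nonpad[sample_of_col[keep]]
  if (mae_weight > 0) {
    sgn_col <- sign(em - true_mass)[sample_of_col]
    GM <- P * (mass_vec - rep(em_col, each = d[1]))
    G <- G + mae_weight * sweep(GM, 2, sgn_col, "*")
  }
  G <- G / B
  dim(G) <- d
  list(ce = mean(ce_per), mae = mean(mae_per), grad = G)
}

# auxiliary losses (means over the batch) and head-logit gradients
batch_aux_stats <- function(out, tgt, take, aux_weights) {
  B <- length(take)
  sig <- function(x) 1 / (1 + exp(-x))
  clamp <- function(p) pmin(pmax(p, 1e-12), 1 - 1e-12)
  bce_mean <- function(p, y) mean(-(y * log(clamp(p)) +
                                      (1 - y) * log(1 - clamp(p))))
  y_tr <- tgt$tryptic[take]
  y_len <- tgt$length[take]
  y_pres <- tgt$presence[, take, drop = FALSE]
  y_comp <- tgt$comp_norm[, take, drop = FALSE]
  y_pairs <- tgt$pairs[, take, drop = FALSE]

  p_tr <- sig(out$aux_tryptic)
  e_len <- exp(sweep(out$aux_length, 2, apply(out$aux_length, 2, max)))
  p_len <- sweep(e_len, 2, colSums(e_len), "/")
  p_pres <- sig(out$aux_presence)
  p_pairs <- sig(out$aux_pairs)

  losses <- c(
    tryptic = bce_mean(p_tr, rbind(y_tr)),
    length = mean(-log(pmax(p_len[cbind(y_len, seq_len(B))], 1e-12))),
    presence = bce_mean(p_pres, y_pres),
    composition = mean((out$aux_comp - y_comp)^2),
    pairs = bce_mean(p_pairs, y_pairs)
  )

  onehot_len <- matrix(0, 30, B)
  onehot_len[cbind(y_len, seq_len(B))] <- 1
  grads <- list(
    tryptic = aux_weights[["tryptic"]] * (p_tr - rbind(y_tr)) / B,
    length = aux_weights[["length"]] * (p_len - onehot_len) / B,
    presence = aux_weights[["presence"]] * (p_pres - y_pres) / (20 * B),
    comp = aux_weights[["composition"]] * 2 * (out$aux_comp - y_comp) /
      (20 * B),
    pairs = aux_weights[["pairs"]] * (p_pairs - y_pairs) / (400 * B)
  )
  list(losses = losses, grads = grads)
}
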