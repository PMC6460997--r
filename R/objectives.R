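# Training objectives and evaluation metrics for voxel-wise segmentation.
# All losses operate on a probability field: per-voxel class probabilities q
# (X, Y, Z, K) against one-hot ground truth p of the same shape.

PROB_EPS <- 1e-7   # clipping floor applied before any logarithm

#' Construct a probability field
#'
#' @param q Numeric array (X, Y, Z, K) of per-voxel class probabilities;
#'   rows must sum to 1 within 1e-5.
#' @param p One-hot ground-truth array of the same shape.
#' @return Object of class `probability_field` with voxel count `N`.
#' @export
probability_field <- function(q, p) {
  dq <- dim(q)
  if (!identical(dq, dim(p))) stop("q and p must share shape")
  if (length(dq) != 4L) stop("expected a 4-D (X,Y,Z,K) array")
  if (any(q < -1e-8) || any(q > 1 + 1e-8)) stop("q outside [0,1]")
  qm <- q; dim(qm) <- c(prod(dq[1:3]), dq[4])
  if (max(abs(rowSums(qm) - 1)) > 1e-5) stop("q rows must sum to 1")
  pm <- p; dim(pm) <- c(prod(dq[1:3]), dq[4])
  if (!all(pm %in% c(0, 1)) || any(rowSums(pm) != 1))
    stop("p must be exactly one-hot")
  structure(list(q = q, p = p, N = prod(dq[1:3]), K = dq[4]),
            class = "probability_field")
}

#' One-hot encode a label grid
#'
#' @param labels Integer 3-D array with values in 0..(classes-1).
#' @param classes Number of classes.
#' @return Numeric array (X, Y, Z, classes).
#' @export
one_hot <- function(labels, classes = 4L) {
  d <- dim(labels)
  out <- array(0, dim = c(d, classes))
  lm <- as.vector(labels)
  out[cbind(arrayInd(seq_along(lm), d), lm + 1L)] <- 1
  out
}

#' Per-class weights for the weighted cross-entropy
#'
#' Defaults to (1, 1, 2, 1) for (background, edema, non-enhancing,
#' enhancing): the non-enhancing class is the rarest and is up-weighted.
#'
#' @param w Positive numeric vector, one weight per class.
#' @return Object of class `class_weights`.
#' @export
class_weights <- function(w = c(1, 1, 2, 1)) {
  if (any(w <= 0)) stop("class weights must be positive")
  structure(as.numeric(w), class = "class_weights")
}

#' Voxel-wise confusion counts between two binary masks
#'
#' @param pred_mask,true_mask Logical/0-1 arrays of the same shape.
#' @return List with integers TP, FP, FN, TN summing to the voxel count.
#' @export
confusion_counts <- function(pred_mask, true_mask) {
  if (!identical(dim(pred_mask), dim(true_mask)) ||
      length(pred_mask) != length(true_mask))
    stop("mask shapes differ")
  p <- as.logical(pred_mask); t <- as.logical(true_mask)
  list(TP = sum(p & t), FP = sum(p & !t), FN = sum(!p & t), TN = sum(!p & !t))
}

#' Dice similarity coefficient
#'
#' DSC = 2TP / (FP + 2TP + FN). When both masks are empty the score is 1
#' by convention (benign cases with no enhancing tumor would otherwise be
#' undefined).
#'
#' @inheritParams confusion_counts
#' @return Numeric in [0, 1].
#' @export
dice_score <- function(pred_mask, true_mask) {
  cc <- confusion_counts(pred_mask, true_mask)
  denom <- cc$FP + 2 * cc$TP + cc$FN
  if (denom == 0) return(1)
  2 * cc$TP / denom
}

clip_q <- function(q) pmin(pmax(q, PROB_EPS), 1)

#' Categorical cross-entropy
#'
#' -(1/N) sum over voxels and classes of p * log(q), with q clipped to
#' [1e-7, 1] before the logarithm; N is the voxel count.
#'
#' @param field A [probability_field()].
#' @return Non-negative scalar.
#' @export
cross_entropy <- function(field) {
  -sum(field$p * log(clip_q(field$q))) / field$N
}

#' Weighted categorical cross-entropy
#'
#' Cross-entropy with a per-class factor w_k inside the class sum, used to
#' up-weight rare tumor classes.
#'
#' @param field A [probability_field()].
#' @param weights A [class_weights()] of length K.
#' @return Non-negative scalar.
#' @export
weighted_cross_entropy <- function(field, weights = class_weights()) {
  if (length(weights) != field$K) stop("need one weight per class")
  wb <- rep(as.numeric(weights), each = field$N)
  -sum(wb * field$p * log(clip_q(field$q))) / field$N
}

#' Multiclass focal loss
#'
#' -sum p (1-q)^gamma log(q) / sum p, concentrating the objective on
#' low-confidence voxels; for one-hot truth the denominator equals N.
#'
#' @param field A [probability_field()].
#' @param gamma Focusing exponent, default 2.
#' @return Non-negative scalar.
#' @export
focal_loss <- function(field, gamma = 2) {
  stopifnot(gamma >= 0)
  qc <- clip_q(field$q)
  -sum(field$p * (1 - qc)^gamma * log(qc)) / sum(field$p)
}

#' Soft Dice loss
#'
#' Canonical mode: 1 - 2 * sum(p*q) / (sum(p) + sum(q) + eps), summing over
#' all voxels and classes (background included by default). The `as_printed`
#' mode additionally scales the overlap fraction by 1/N; it is retained for
#' fidelity but makes the loss nearly constant at realistic N, so canonical
#' is the default.
#'
#' @param field A [probability_field()].
#' @param mode `"canonical"` or `"as_printed"`.
#' @param epsilon Denominator stabilizer, default 1e-5.
#' @param exclude_background Drop class 1 (background) from the sums.
#' @return Scalar in [0, 1] (canonical mode).
#' @export
dice_loss <- function(field, mode = c("canonical", "as_printed"),
                      epsilon = 1e-5, exclude_background = FALSE) {
  mode <- match.arg(mode)
  p <- field$p; q <- field$q
  if (exclude_background) {
    p <- p[, , , -1, drop = FALSE]
    q <- q[, , , -1, drop = FALSE]
  }
  overlap <- 2 * sum(p * q) / (sum(p) + sum(q) + epsilon)
  if (mode == "as_printed") overlap <- overlap / field$N
  1 - overlap
}

# --- gradients (w.r.t. q) used by the trainer ---------------------------

loss_grad <- function(field, loss = c("ce", "wce", "focal", "dice"),
                      weights = class_weights(), gamma = 2,
                      epsilon = 1e-5, exclude_background = FALSE) {
  loss <- match.arg(loss)
  p <- field$p
  qc <- clip_q(field$q)
  switch(loss,
    ce = -p / qc / field$N,
    wce = {
      wb <- rep(as.numeric(weights), each = field$N)
      dim(wb) <- dim(p)
      -wb * p / qc / field$N
    },
    focal = {
      # d/dq [ p (1-q)^g log q ] = p [ -g (1-q)^(g-1) log q + (1-q)^g / q ]
      inner <- -gamma * (1 - qc)^(gamma - 1) * log(qc) + (1 - qc)^gamma / qc
      -p * inner / sum(p)
    },
    dice = {
      keep <- array(1, dim = dim(p))
      if (exclude_background) keep[, , , 1] <- 0
      S <- sum(keep * p * field$q)
      P <- sum(keep * p); Q <- sum(keep * field$q)
      den <- P + Q + epsilon
      -keep * (2 * p / den - 2 * S / den^2)
    })
}

#' Per-class Dice evaluation of a predicted segmentation
#'
#' One-vs-rest Dice for each tumor class (1 = edema, 2 = non-enhancing,
#' 3 = enhancing) with the both-empty convention scoring 1.
#'
#' @param pred,truth [label_volume()]s (or bare integer arrays) of one shape.
#' @return Named numeric vector of length 3.
#' @export
evaluate_case <- function(pred, truth) {
  pg <- if (inherits(pred, "label_volume")) pred$labels else pred
  tg <- if (inherits(truth, "label_volume")) truth$labels else truth
  if (!identical(dim(pg), dim(tg))) stop("shapes differ")
  out <- vapply(1:3, function(k) dice_score(pg == k, tg == k), numeric(1))
  names(out) <- c("edema", "non_enhancing", "enhancing")
  out
}
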