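# Training objective (class-weighted smoothed cross-entropy + uncertainty
# calibration) and evaluation metrics. The abnormal class (label 1) is the
# positive class throughout.

#' Inverse-frequency class weights
#'
#' Weights proportional to the inverse class frequency of the given labels,
#' normalized to mean 1. Intended to be computed on the pre-oversampling
#' training set.
#'
#' @param labels 0/1 vector.
#' @return numeric length-2 vector `c(w0, w1)`.
#' @export
class_weights_from_labels <- function(labels) {
  n <- c(sum(labels == 0), sum(labels == 1))
  if (any(n == 0)) return(c(1, 1))
  w <- sum(n) / (2 * n)
  w / mean(w)
}

#' Binary cross-entropy with class weights and label smoothing
#'
#' With label smoothing `s`, targets become `(1 - s) * y + s / 2`; with unit
#' weights and `s = 0` this is the plain mean of
#' `-[y log p + (1 - y) log(1 - p)]`. Probabilities are clipped to
#' `[eps, 1 - eps]`.
#'
#' @param pred_prob predicted probability of the abnormal class, in `[0, 1]`.
#' @param label 0/1 labels.
#' @param class_weights length-2 weights `c(w0, w1)`.
#' @param label_smoothing smoothing factor in `[0, 1)`.
#' @param eps clipping guard.
#' @return nonnegative scalar (weighted batch mean).
#' @export
cross_entropy <- function(pred_prob, label, class_weights = c(1, 1),
                          label_smoothing = 0, eps = 1e-7) {
  p <- clamp(pred_prob, eps, 1 - eps)
  t <- (1 - label_smoothing) * label + label_smoothing / 2
  w <- class_weights[label + 1]
  mean(w * -(t * log(p) + (1 - t) * log(1 - p)))
}

#' Pixel-wise classification error map
#'
#' `E(i, j) = |yhat(i, j) - y|` for the local probability map against the
#' tile's global label.
#'
#' @param local_prob matrix of local probabilities in `[0, 1]`.
#' @param label scalar 0/1.
#' @return matrix of the same shape, entries in `[0, 1]`.
#' @export
error_map <- function(local_prob, label) {
  stopifnot(label %in% c(0, 1))
  abs(local_prob - label)
}

minmax_norm <- function(x) {
  r <- range(x)
  if (r[2] - r[1] < 1e-12) return(NULL)
  (x - r[1]) / (r[2] - r[1])
}

#' Uncertainty-calibration loss between a U map and an E map
#'
#' Pearson (default): `1 - cor(U, E)` in `[0, 2]`. Spearman: `1 - rank
#' correlation`. MSE: mean squared difference of the min-max-normalized
#' maps. Maps with zero variance contribute the neutral value 1 (pearson /
#' spearman) or 0 contribution per constant map (mse) and are flagged via
#' the `"degenerate"` attribute.
#'
#' @param u uncertainty map (matrix), already resized to `e`'s resolution.
#' @param e error map (matrix) of the same shape.
#' @param metric one of `"pearson"`, `"spearman"`, `"mse"`.
#' @return scalar loss with logical attribute `degenerate`.
#' @export
ual_loss <- function(u, e, metric = c("pearson", "spearman", "mse")) {
  metric <- match.arg(metric)
  if (!identical(dim(u), dim(e))) stop("U and E must have the same shape")
  uu <- as.numeric(u); ee <- as.numeric(e)
  degen <- stats::sd(uu) < 1e-12 || stats::sd(ee) < 1e-12
  val <- switch(metric,
    pearson = if (degen) 1 else 1 - stats::cor(uu, ee),
    spearman = if (degen) 1 else 1 - stats::cor(uu, ee, method = "spearman"),
    mse = {
      un <- minmax_norm(uu); en <- minmax_norm(ee)
      if (is.null(un)) un <- rep(0, length(uu))
      if (is.null(en)) en <- rep(0, length(ee))
      mean((un - en)^2)
    }
  )
  structure(val, degenerate = degen)
}

#' Combine the classification and calibration losses
#'
#' `total = cel + gamma * ual` with balance factor `gamma` (default 0.1).
#'
#' @param cel cross-entropy term.
#' @param ual calibration term.
#' @param gamma nonnegative balance factor.
#' @return list (class `loss_breakdown`): `cel`, `ual`, `gamma`, `total`.
#' @export
total_loss <- function(cel, ual, gamma = 0.1) {
  stopifnot(gamma >= 0)
  structure(list(cel = as.numeric(cel), ual = as.numeric(ual),
                 gamma = gamma,
                 total = as.numeric(cel) + gamma * as.numeric(ual)),
            class = "loss_breakdown")
}

#' Confusion counts for binary predictions
#'
#' Abnormal (1) is the positive class.
#'
#' @param pred_labels,true_labels equal-length 0/1 vectors.
#' @return list: TP, TN, FP, FN.
#' @export
confusion <- function(pred_labels, true_labels) {
  if (length(pred_labels) == 0L) stop("empty input")
  stopifnot(length(pred_labels) == length(true_labels))
  list(TP = sum(pred_labels == 1 & true_labels == 1),
       TN = sum(pred_labels == 0 & true_labels == 0),
       FP = sum(pred_labels == 1 & true_labels == 0),
       FN = sum(pred_labels == 0 & true_labels == 1))
}

ratio0 <- function(num, den) {
  if (den == 0) structure(0, flagged = TRUE) else num / den
}

#' Classification metrics from confusion counts
#'
#' Accuracy, precision, recall and F1; ratios with a zero denominator
#' return 0 carrying the attribute `flagged = TRUE` instead of erroring.
#'
#' @param counts list from [confusion()].
#' @name classification_metrics
#' @export
accuracy <- function(counts) {
  with(counts, ratio0(TP + TN, TP + TN + FP + FN))
}

#' @rdname classification_metrics
#' @export
precision <- function(counts) with(counts, ratio0(TP, TP + FP))

#' @rdname classification_metrics
#' @export
recall <- function(counts) with(counts, ratio0(TP, TP + FN))

#' @rdname classification_metrics
#' @export
f1_score <- function(counts) {
  p <- precision(counts); r <- recall(counts)
  if (p + r == 0) structure(0, flagged = TRUE) else 2 * p * r / (p + r)
}

#' Area under the ROC curve (rank statistic)
#'
#' The probability that a randomly chosen positive outscores a randomly
#' chosen negative, ties counted half (normalized Mann-Whitney U).
#'
#' @param scores numeric scores (higher = more abnormal).
#' @param labels 0/1 labels, both classes present.
#' @return value in `[0, 1]`.
#' @export
auc_roc <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
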