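# Integration of the two stages and performance evaluation.

#' Adjust second-stage scores by the first-stage protein score
#'
#' When the protein score is below 0.4 the protein is unlikely to be a
#' glycoprotein, so all its sequon scores are reduced by 20% (x0.8); above
#' 0.8 they are increased by 10% (x1.1, capped at 1); otherwise (including
#' scores exactly at a boundary, or an undefined first stage) they are
#' unchanged. `additive = TRUE` applies -0.2 / +0.1 on the probability scale
#' instead, clamped to [0, 1].
#'
#' @param stage2_scores Numeric vector of sequon scores in `[0, 1]`.
#' @param stage1_score Single protein score in `[0, 1]`, or `NA`.
#' @param lower,upper First-stage thresholds (defaults 0.4, 0.8).
#' @param down,up Adjustment factors (defaults 0.8, 1.1).
#' @param additive Use additive adjustment instead of multiplicative.
#' @return Adjusted final scores in `[0, 1]`.
#' @export
adjust_scores <- function(stage2_scores, stage1_score,
                          lower = 0.4, upper = 0.8,
                          down = 0.8, up = 1.1, additive = FALSE) {
  stopifnot(all(stage2_scores >= 0 & stage2_scores <= 1))
  if (is.na(stage1_score)) return(stage2_scores)
  out <- stage2_scores
  if (additive) {
    if (stage1_score < lower) out <- out - (1 - down)
    else if (stage1_score > upper) out <- out + (up - 1)
  } else {
    if (stage1_score < lower) out <- out * down
    else if (stage1_score > upper) out <- out * up
  }
  pmin(1, pmax(0, out))
}

#' Tally a binary confusion matrix
#'
#' @param calls Logical (or 0/1) predicted calls.
#' @param labels Logical (or 0/1 or `"positive"`/`"negative"`) true labels.
#' @return A `confusion_matrix`: list with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(calls, labels) {
  calls <- as.logical(calls)
  lab <- .as_binary_label2(labels)
  if (length(calls) != length(lab)) stop("calls and labels differ in length")
  structure(list(tp = sum(calls & lab), fp = sum(calls & !lab),
                 tn = sum(!calls & !lab), fn = sum(!calls & lab)),
            class = "confusion_matrix")
}

.as_binary_label2 <- function(labels) {
  if (is.character(labels) || is.factor(labels)) .as_binary_label(labels)
  else as.logical(labels)
}

#' Build a confusion matrix from raw cell counts
#'
#' @param tp,fp,tn,fn Non-negative integer cell counts.
#' @return A `confusion_matrix`.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn),
            class = "confusion_matrix")
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, with the
#' convention that a zero denominator factor gives 0.
#'
#' @param cm A `confusion_matrix`.
#' @return MCC in `[-1, 1]`.
#' @export
mcc <- function(cm) {
  with(cm, {
    d <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
    if (d == 0) 0 else (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(d)
  })
}

#' The five standard binary-classification measures
#'
#' Accuracy, precision, sensitivity, specificity and MCC from a confusion
#' matrix. Precision/sensitivity/specificity with an empty denominator are
#' `NA`; MCC follows the zero convention of [mcc()].
#'
#' @param cm A `confusion_matrix`.
#' @return Named list with `accuracy`, `precision`, `sensitivity`,
#'   `specificity`, `mcc`.
#' @export
metrics <- function(cm) {
  n <- with(cm, tp + tn + fp + fn)
  if (n == 0) stop("empty confusion matrix")
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  with(cm, list(
    accuracy = (tp + tn) / n,
    precision = safe_div(tp, tp + fp),
    sensitivity = safe_div(tp, tp + fn),
    specificity = safe_div(tn, tn + fp),
    mcc = mcc(cm)))
}

#' ROC curve over a fixed cutoff grid, with trapezoidal AUC
#'
#' Sensitivity and 1 - specificity are evaluated at `n_cutoffs` evenly
#' spaced cutoffs in `[0, 1]` (a prediction is positive when score >=
#' cutoff); the curve is anchored at (0, 0) and the AUC computed by the
#' trapezoidal rule.
#'
#' @param scores Numeric scores in `[0, 1]`.
#' @param labels Binary labels, both classes present.
#' @param n_cutoffs Number of cutoffs (default 1000).
#' @return List with `curve` (data.frame `cutoff`, `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, labels, n_cutoffs = 1000L) {
  lab <- .as_binary_label2(labels)
  if (all(lab) || !any(lab)) stop("ROC requires both classes")
  cutoffs <- seq(0, 1, length.out = n_cutoffs)
  tpr <- vapply(cutoffs, function(t) mean(scores[lab] >= t), numeric(1))
  fpr <- vapply(cutoffs, function(t) mean(scores[!lab] >= t), numeric(1))
  curve <- data.frame(cutoff = cutoffs, fpr = fpr, tpr = tpr)
  # integrate in increasing-fpr order, anchored at (0,0)
  o <- order(fpr, tpr)
  xf <- c(0, fpr[o]); yf <- c(0, tpr[o])
  auc <- sum(diff(xf) * (head(yf, -1) + yf[-1]) / 2)
  list(curve = curve, auc = auc)
}
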