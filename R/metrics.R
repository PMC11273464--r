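## Classification metrics: confusion counts, the standard binary rates
## ACC = (TP+TN)/(TP+TN+FP+FN), PR = TP/(TP+FP), TPR = TP/(TP+FN),
## FS = 2TP/(2TP+FP+FN), TNR = TN/(TN+FP), FPR = FP/(FP+TN);
## prevalence-weighted one-vs-rest aggregation for multi-class labels; and
## rank-based ROC / trapezoidal precision-recall curve areas.

#' Confusion counts of binary predictions
#'
#' @param y_true,y_pred Equal-length binary vectors (0/1, logical, or the
#'   same two class values with 1/TRUE/positive meaning "positive").
#' @return A `confusion_counts` list with fields `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop_fmll("y_true and y_pred lengths differ (%d vs %d)",
              length(y_true), length(y_pred))
  if (!length(y_true)) stop_fmll("empty outcome vectors")
  t <- as.integer(as.logical(as.numeric(y_true)))
  p <- as.integer(as.logical(as.numeric(y_pred)))
  structure(list(TP = sum(t == 1 & p == 1), TN = sum(t == 0 & p == 0),
                 FP = sum(t == 0 & p == 1), FN = sum(t == 1 & p == 0)),
            class = "confusion_counts")
}

ratio0 <- function(num, den, what) {
  if (den == 0) {
    warning(sprintf("%s undefined (zero denominator); returning 0", what),
            call. = FALSE)
    return(0)
  }
  num / den
}

#' Binary classification rates from confusion counts
#'
#' Evaluates accuracy, precision, recall (TPR), F-score, TNR and FPR from
#' TP/TN/FP/FN. A ratio with zero denominator is reported as 0 with a
#' warning, keeping reports total.
#'
#' @param c A [confusion_counts()] object.
#' @return A named list: `accuracy` (fraction), `precision`, `recall`,
#'   `f_score`, `tnr`, `fpr`.
#' @export
binary_metrics <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  total <- c$TP + c$TN + c$FP + c$FN
  if (total == 0) stop_fmll("empty confusion counts")
  list(accuracy = (c$TP + c$TN) / total,
       precision = ratio0(c$TP, c$TP + c$FP, "precision"),
       recall = ratio0(c$TP, c$TP + c$FN, "recall"),
       f_score = ratio0(2 * c$TP, 2 * c$TP + c$FP + c$FN, "F-score"),
       tnr = ratio0(c$TN, c$TN + c$FP, "TNR"),
       fpr = ratio0(c$FP, c$FP + c$TN, "FPR"))
}

#' Multi-class rates by prevalence-weighted one-vs-rest averaging
#'
#' Accuracy is the fraction of exactly correct predictions; precision,
#' recall, F-score, TNR and FPR are computed one-vs-rest per class and
#' averaged with class-prevalence weights (classes absent from `y_true` get
#' weight 0).
#'
#' @param y_true,y_pred Equal-length class-value vectors.
#' @param classes Ordered class inventory.
#' @return A named list as in [binary_metrics()].
#' @export
multiclass_metrics <- function(y_true, y_pred, classes) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred))
    stop_fmll("y_true and y_pred lengths differ")
  bad <- setdiff(unique(c(y_true, y_pred)), classes)
  if (length(bad))
    stop_fmll("value(s) outside declared classes: %s", paste(bad, collapse = ", "))
  w <- vapply(classes, function(cl) mean(y_true == cl), 0)
  per <- lapply(classes, function(cl)
    binary_metrics(confusion_counts(y_true == cl, y_pred == cl)))
  wmean <- function(field) sum(w * vapply(per, `[[`, 0, field))
  list(accuracy = mean(y_true == y_pred),
       precision = wmean("precision"), recall = wmean("recall"),
       f_score = wmean("f_score"), tnr = wmean("tnr"), fpr = wmean("fpr"))
}

#' Area under the ROC curve (rank formulation)
#'
#' Computed as the Mann-Whitney probability
#' P(score_pos > score_neg) + P(tie)/2, identical to the trapezoidal area
#' under the tie-grouped ROC curve.
#'
#' @param y_true Binary outcomes (both classes present).
#' @param scores Positive-class scores.
#' @return Area in `[0, 1]`.
#' @export
roc_auc <- function(y_true, scores) {
  t <- as.logical(as.numeric(y_true))
  if (length(t) != length(scores)) stop_fmll("length mismatch")
  n1 <- sum(t); n0 <- sum(!t)
  if (n1 == 0 || n0 == 0) stop_fmll("roc_auc needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[t]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Descending-score sweep with tied scores grouped; the area is the
#' trapezoidal integral of precision over recall through the swept points,
#' anchored at recall 0 with the first point's precision.
#'
#' @param y_true Binary outcomes (at least one positive).
#' @param scores Positive-class scores.
#' @return Area in `[0, 1]`.
#' @export
prc_auc <- function(y_true, scores) {
  t <- as.logical(as.numeric(y_true))
  if (length(t) != length(scores)) stop_fmll("length mismatch")
  P <- sum(t)
  if (P == 0) stop_fmll("prc_auc needs at least one positive")
  ord <- order(scores, decreasing = TRUE)
  ts <- t[ord]; ss <- scores[ord]
  grp_end <- cumsum(rle(ss)$lengths)
  tp <- cumsum(ts)[grp_end]
  np <- grp_end
  recall <- tp / P
  precision <- tp / np
  rec <- c(0, recall)
  prec <- c(precision[1L], precision)
  sum(diff(rec) * (utils::head(prec, -1L) + utils::tail(prec, -1L)) / 2)
}

## weighted one-vs-rest curve areas for a multi-class label
multiclass_auc <- function(y_true, prob, classes, fun) {
  w <- vapply(classes, function(cl) mean(y_true == cl), 0)
  aucs <- vapply(classes, function(cl) {
    if (w[cl] == 0 || w[cl] == 1) return(NA_real_)
    fun(y_true == cl, prob[, cl])
  }, 0)
  ok <- !is.na(aucs)
  if (!any(ok)) return(0)
  sum(w[ok] * aucs[ok]) / sum(w[ok])
}
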