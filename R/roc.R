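# ROC analysis and cutoff-based test characteristics.
#
# Classification convention throughout: a patient is called positive
# (predicted to die) when score >= cutoff. Published integer cutoffs match
# this >=-thresholding arithmetic.

#' Receiver operating characteristic curve
#'
#' Builds the ROC curve of a score against a binary outcome over all
#' distinct observed thresholds (ties grouped), under the "positive iff
#' score >= threshold" convention, and computes the area under the curve by
#' the trapezoidal rule. With ties handled this way the AUC equals the
#' normalised Mann-Whitney U statistic of positives versus negatives (ties
#' counted half), i.e. the probability that a random non-survivor outscores
#' a random survivor.
#'
#' @param scores numeric score per patient.
#' @param outcomes binary outcome (see [fit_univariate_logistic()] for
#'   accepted encodings; died/1/TRUE is the positive class).
#' @return object of class `roc_curve`: `thresholds` (descending, starting
#'   at `Inf`), `tpr`, `fpr`, `auc`, `n_pos`, `n_neg`.
#' @examples
#' roc_curve(c(1, 2, 3, 4), c(0, 1, 0, 1))$auc  # 0.75
#' @export
roc_curve <- function(scores, outcomes) {
  y <- coerce_binary_outcome(outcomes)
  x <- as.numeric(scores)
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos == 0L || n_neg == 0L) {
    validation_error("both outcome classes must be present")
  }
  thr <- c(Inf, sort(unique(x), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(x >= t & y == 1) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(x >= t & y == 0) / n_neg, numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc,
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d thresholds, %d positives / %d negatives, AUC = %.4f\n",
              length(x$thresholds), x$n_pos, x$n_neg, x$auc))
  invisible(x)
}

#' Optimal cutoff by the Youden index
#'
#' Selects the threshold maximising Youden's J = sensitivity + specificity
#' - 1 over the finite thresholds of a ROC curve. Ties on J are broken
#' toward higher specificity (then toward the higher threshold), so an
#' uninformative curve resolves to the most conservative cutoff.
#'
#' @param curve a [roc_curve()].
#' @return the selected cutoff (a score value); classify positive when
#'   `score >= cutoff`.
#' @examples
#' optimal_cutoff(roc_curve(c(1, 2, 3, 4), c(0, 0, 1, 1)))  # 3
#' @export
optimal_cutoff <- function(curve) {
  if (!inherits(curve, "roc_curve")) validation_error("need a roc_curve")
  finite <- is.finite(curve$thresholds)
  thr <- curve$thresholds[finite]
  j <- curve$tpr[finite] - curve$fpr[finite]
  spec <- 1 - curve$fpr[finite]
  best <- which(j >= max(j) - 1e-12)
  best <- best[order(-spec[best], -thr[best])]
  thr[best[[1]]]
}

#' Classifier metrics from confusion counts
#'
#' @param tp,fp,tn,fn non-negative integer confusion counts.
#' @param cutoff score cutoff the counts were taken at (optional, `NA` when
#'   constructed directly from counts).
#' @return object of class `classifier_metrics` with the counts plus
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `accuracy` (proportions in
#'   \[0, 1\]; `NaN` where a denominator is empty).
#' @examples
#' m <- classifier_metrics(tp = 13, fp = 12, tn = 88, fn = 1)
#' round(100 * c(m$accuracy, m$ppv, m$npv), 2)  # 88.60 52.00 98.88
#' @export
classifier_metrics <- function(tp, fp, tn, fn, cutoff = NA_real_) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    validation_error("confusion counts must be non-negative integers")
  }
  structure(list(cutoff = cutoff,
                 tp = as.integer(tp), fp = as.integer(fp),
                 tn = as.integer(tn), fn = as.integer(fn),
                 sensitivity = tp / (tp + fn),
                 specificity = tn / (tn + fp),
                 ppv = tp / (tp + fp),
                 npv = tn / (tn + fn),
                 accuracy = (tp + tn) / (tp + tn + fp + fn)),
            class = "classifier_metrics")
}

#' @export
print.classifier_metrics <- function(x, ...) {
  cat(sprintf(
    "cutoff %s: tp %d fp %d tn %d fn %d | Sen %.2f%% Sp %.2f%% PPV %.2f%% NPV %.2f%% Acc %.2f%%\n",
    format(x$cutoff), x$tp, x$fp, x$tn, x$fn, 100 * x$sensitivity,
    100 * x$specificity, 100 * x$ppv, 100 * x$npv, 100 * x$accuracy))
  invisible(x)
}

#' Test characteristics of a score at a cutoff
#'
#' Dichotomises the score at `cutoff` (positive iff `score >= cutoff`) and
#' tabulates the confusion matrix against the outcome.
#'
#' @inheritParams roc_curve
#' @param cutoff score cutoff.
#' @return a [classifier_metrics()].
#' @export
confusion_metrics <- function(scores, outcomes, cutoff) {
  y <- coerce_binary_outcome(outcomes)
  x <- as.numeric(scores)
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  if (!any(y == 1) || !any(y == 0)) {
    validation_error("both outcome classes must be present")
  }
  pred <- x >= cutoff
  classifier_metrics(tp = sum(pred & y == 1), fp = sum(pred & y == 0),
                     tn = sum(!pred & y == 0), fn = sum(!pred & y == 1),
                     cutoff = cutoff)
}
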