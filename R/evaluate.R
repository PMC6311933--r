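# Performance evaluation: confusion counts at a threshold, the five
# standard scalar metrics, ROC / PR curves with their areas, and
# specificity-calibrated confidence thresholds.
#
# Decision rule everywhere: predicted positive <=> score >= threshold.

#' Confusion counts at a threshold
#'
#' @param scores Numeric scores in [0, 1].
#' @param labels Binary labels (0/1 or `"positive"`/`"negative"`).
#' @param threshold Decision threshold; predicted positive when
#'   `score >= threshold`.
#' @return Named list: `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(scores, labels, threshold = 0.5) {
  y <- labels_to_numeric(labels)
  if (length(scores) != length(y)) {
    stopf("scores (%d) and labels (%d) differ in length",
          length(scores), length(y))
  }
  pred <- scores >= threshold
  list(TP = sum(pred & y == 1), TN = sum(!pred & y == 0),
       FP = sum(pred & y == 0), FN = sum(!pred & y == 1))
}

#' Scalar classification metrics
#'
#' Accuracy, sensitivity, specificity, F1 and the Matthews correlation
#' coefficient, evaluated exactly as printed:
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}
#'   {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}}
#' A zero MCC denominator yields MCC = 0 with `mcc_undefined = TRUE`.
#'
#' @param counts Confusion counts from [confusion_counts()].
#' @return Named list: `accuracy`, `sensitivity`, `specificity`, `f1`,
#'   `mcc`, `mcc_undefined`.
#' @export
classification_metrics <- function(counts) {
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  total <- TP + TN + FP + FN
  if (total == 0) stopf("all confusion counts are zero")
  denom <- sqrt((TP + FP) * (TP + FN) * (TN + FP) * (TN + FN))
  list(accuracy = (TP + TN) / total,
       sensitivity = TP / (TP + FN),
       specificity = TN / (TN + FP),
       f1 = 2 * TP / (2 * TP + FP + FN),
       mcc = if (denom == 0) 0 else (TP * TN - FP * FN) / denom,
       mcc_undefined = denom == 0)
}

#' ROC and PR curves with their areas
#'
#' The ROC curve steps through the distinct score thresholds (rule
#' `score >= t`); AUROC is the trapezoidal area, which equals the
#' Mann-Whitney probability P(score_pos > score_neg) + 0.5 P(tie). AUPR
#' uses the interpolation-free step rule (average precision): the sum of
#' precision at each threshold weighted by the recall increment.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels; both classes must be present.
#' @return List with `auroc`, `aupr`, `roc` (data.frame threshold / fpr /
#'   tpr) and `pr` (data.frame threshold / recall / precision).
#' @export
roc_pr <- function(scores, labels) {
  y <- labels_to_numeric(labels)
  if (length(unique(y)) < 2L) stopf("both classes must be present")
  P <- sum(y == 1); N <- sum(y == 0)
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]
  ss <- scores[ord]
  tp <- cumsum(ys == 1)
  fp <- cumsum(ys == 0)
  last <- c(diff(ss) != 0, TRUE)      # keep one point per distinct threshold
  tp <- tp[last]; fp <- fp[last]; th <- ss[last]
  tpr <- c(0, tp / P)
  fpr <- c(0, fp / N)
  auroc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  recall <- tp / P
  precision <- tp / (tp + fp)
  aupr <- sum(diff(c(0, recall)) * precision)
  list(auroc = auroc, aupr = aupr,
       roc = data.frame(threshold = c(Inf, th), fpr = fpr, tpr = tpr),
       pr = data.frame(threshold = th, recall = recall,
                       precision = precision))
}

#' Calibrate specificity-based confidence thresholds
#'
#' For each target specificity s (defaults 90/95/99\%), the smallest
#' threshold t such that the empirical specificity on the validation
#' negatives is at least s, i.e. at least a fraction s of negative scores
#' lie strictly below t under the `score >= t` decision rule. Thresholds
#' are non-decreasing in s by construction.
#'
#' @param scores Validation scores.
#' @param labels Validation labels (negatives must be present).
#' @param targets Target specificities, default `c(moderate = 0.90,
#'   high = 0.95, very_high = 0.99)`.
#' @return An `m6a_thresholds` named numeric vector (one cutoff per tier)
#'   with attribute `targets`.
#' @export
calibrate_confidence <- function(scores, labels,
                                 targets = c(moderate = 0.90, high = 0.95,
                                             very_high = 0.99)) {
  y <- labels_to_numeric(labels)
  neg <- sort(scores[y == 0])
  n <- length(neg)
  if (n == 0L) stopf("no negatives in the validation set")
  if (n < 100L) {
    warnf("only %d validation negatives; the 99%% specificity tier is unstable", n)
  }
  eps <- 1e-9
  candidates <- c(unique(neg), max(neg) + eps)
  th <- vapply(targets, function(s) {
    for (t in candidates) {
      if (sum(neg < t) / n >= s) return(t)
    }
    max(neg) + eps
  }, numeric(1))
  structure(th, targets = targets, class = "m6a_thresholds")
}

#' Assign confidence tiers to scores
#'
#' @param scores Numeric scores.
#' @param thresholds An `m6a_thresholds` object from
#'   [calibrate_confidence()].
#' @return Character vector over `"none"` and the tier names, the highest
#'   tier whose cutoff each score reaches.
#' @export
assign_confidence_tier <- function(scores, thresholds) {
  tiers <- names(thresholds)
  out <- rep("none", length(scores))
  for (i in seq_along(tiers)) {        # ascending cutoffs
    out[scores >= thresholds[i]] <- tiers[i]
  }
  out
}
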