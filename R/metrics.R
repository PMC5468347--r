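# Classification performance: ROC, AUC, and the equal-sensitivity/specificity
# operating threshold.

# coerce labels to logical "is positive (secretory)"
.as_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.numeric(labels)) return(labels == 1)
  labels %in% c("secretory", "positive", "1", "TRUE")
}

.check_two_classes <- function(pos) {
  if (!any(pos) || all(pos)) stop("both classes must be present")
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the fraction of (positive, negative) pairs in
#' which the positive scores higher, with ties credited 0.5. Equals the
#' trapezoidal area under the ROC curve, and is invariant under strictly
#' monotone transforms of the scores.
#'
#' @param scores real-valued classifier outputs, higher = more secretory.
#' @param labels class labels; `"secretory"`, `1`, `TRUE` or `"positive"`
#'   mark the positive class.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  pos <- .as_positive(labels)
  .check_two_classes(pos)
  r <- rank(scores, ties.method = "average")
  n1 <- sum(pos)
  n0 <- sum(!pos)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' Sweeps the decision threshold over the unique scores and returns the
#' operating points, including the (0,0) and (1,1) endpoints. Both
#' coordinates are non-decreasing along the curve.
#'
#' @inheritParams auc
#' @return `data.frame` with columns `fpr` (1 - specificity) and
#'   `sensitivity`.
#' @export
roc_curve <- function(scores, labels) {
  pos <- .as_positive(labels)
  .check_two_classes(pos)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  p <- pos[o]
  last <- cumsum(rle(s)$lengths)  # indices where the threshold drops
  tp <- cumsum(p)[last]
  fp <- cumsum(!p)[last]
  data.frame(fpr = c(0, fp / sum(!pos)), sensitivity = c(0, tp / sum(pos)))
}

#' Sensitivity and specificity at a threshold
#'
#' Scores greater than or equal to the threshold are called positive.
#'
#' @inheritParams auc
#' @param threshold decision threshold.
#' @return named vector `c(sensitivity, specificity)`.
#' @export
sens_spec <- function(scores, labels, threshold) {
  pos <- .as_positive(labels)
  c(sensitivity = mean(scores[pos] >= threshold),
    specificity = mean(scores[!pos] < threshold))
}

#' Equal-sensitivity/specificity threshold
#'
#' Returns the operating threshold at which the classifier succeeds equally
#' on both classes: among candidate thresholds (midpoints between adjacent
#' unique scores, plus one candidate below and above the score range), the
#' one minimizing `|sensitivity - specificity|`; among minimizers, the one
#' maximizing `sensitivity + specificity`; remaining ties resolve to the
#' middle candidate.
#'
#' @inheritParams auc
#' @return the threshold.
#' @export
equal_error_threshold <- function(scores, labels) {
  pos <- .as_positive(labels)
  .check_two_classes(pos)
  uq <- sort(unique(scores))
  gap <- if (length(uq) > 1L) diff(range(uq)) / length(uq) else 1
  cand <- c(uq[1] - gap,
            if (length(uq) > 1L) (uq[-length(uq)] + uq[-1]) / 2,
            uq[length(uq)] + gap)
  ss <- vapply(cand, function(t) sens_spec(scores, labels, t), numeric(2L))
  d <- abs(ss[1, ] - ss[2, ])
  best <- which(d == min(d))
  tot <- ss[1, best] + ss[2, best]
  best <- best[tot == max(tot)]
  cand[best[ceiling(length(best) / 2)]]
}
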