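#' ROC curve and AUC
#'
#' Sweeps the decision threshold over all distinct score values (ties
#' grouped into a single threshold step), accumulating true- and
#' false-positive rates, and integrates the curve by the trapezoid rule.
#' The curve is anchored at (0,0) and (1,1) and is monotone
#' non-decreasing in both coordinates. The trapezoid AUC equals the
#' Mann--Whitney statistic: the fraction of positive--negative pairs
#' ranked correctly, ties counted one half.
#'
#' @param scores Numeric vector of class-1 (cancer) scores.
#' @param labels Logical vector (or coercible) marking positives; both
#'   classes must be present.
#' @return List with `roc_points` (data frame `fpr`, `tpr`) and `auc`.
#' @export
roc_and_auc <- function(scores, labels) {
  pos <- as.logical(labels)
  if (length(scores) != length(pos) || anyNA(pos) || anyNA(scores))
    stop("roc_and_auc: scores/labels malformed")
  P <- sum(pos)
  Ng <- sum(!pos)
  if (P == 0 || Ng == 0)
    stop("roc_and_auc: need at least one item of each class")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- pos[ord]
  last_of_tie <- !duplicated(s, fromLast = TRUE)
  tpr <- c(0, cumsum(y)[last_of_tie] / P)
  fpr <- c(0, cumsum(!y)[last_of_tie] / Ng)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(roc_points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}
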