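# Classification metrics: accuracy, positive-class precision and F1 from
# argmax predictions, AUC from the rank-based (Mann-Whitney) statistic.

#' Rank-based AUC
#'
#' Mann-Whitney formulation: the probability that a random positive scores
#' above a random negative, with average ranks for ties.
#'
#' @param score Numeric scores (higher = more positive).
#' @param truth Integer 0/1 labels.
#' @return AUC in `[0, 1]`, or NA with a warning if only one class is
#'   present.
#' @export
auc_rank <- function(score, truth) {
  n1 <- sum(truth == 1)
  n0 <- sum(truth == 0)
  if (n1 == 0 || n0 == 0) {
    warning("AUC undefined: test set contains a single class")
    return(NA_real_)
  }
  r <- rank(score)
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Binary classification metrics
#'
#' @param truth Integer 0/1 labels.
#' @param pred Integer 0/1 argmax predictions.
#' @param score Positive-class probabilities (for AUC).
#' @return List: `accuracy`, `precision`, `f1`, `auc`, each in `[0, 1]`
#'   (precision/F1 are 0 when undefined, AUC NA on a one-class set).
#' @export
binary_metrics <- function(truth, pred, score) {
  tp <- sum(pred == 1 & truth == 1)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(accuracy = mean(pred == truth),
       precision = precision,
       f1 = f1,
       auc = auc_rank(score, truth))
}

#' Evaluate a trained model
#'
#' Argmax predictions (positive class = label 1) scored with accuracy,
#' positive-class precision and F1, and rank-based AUC from the
#' positive-class probability.
#'
#' @param fit A `csbn_fit` or `csbn_model`.
#' @param X Feature matrix.
#' @param y Integer 0/1 labels.
#' @return Metric list as in [binary_metrics()].
#' @export
evaluate_model <- function(fit, X, y) {
  p <- predict_proba(fit, X)
  binary_metrics(as.integer(y), as.integer(p >= 0.5), p)
}
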