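#' Evaluate ranking and classification metrics for scored pairs
#'
#' Computes the five headline metrics of the method on a scored test set:
#' AUC (by the rank statistic with mid-rank tie correction), AUPR (step
#' integration of the precision-recall curve over distinct score thresholds),
#' and accuracy, precision, recall and F1 at the 0.5 decision threshold
#' (scores `>= 0.5` count as predicted positives).
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 labels of the same length; both classes must be present.
#' @return A one-row tibble with columns `auc`, `aupr`, `f1`, `accuracy`,
#'   `recall`, `precision`.
#' @export
#' @examples
#' evaluate(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
evaluate <- function(scores, labels) {
  if (length(scores) != length(labels)) abort("scores/labels length mismatch.")
  if (!all(labels %in% c(0, 1))) abort("Labels must be 0/1.")
  np <- sum(labels == 1)
  nn <- sum(labels == 0)
  if (np == 0 || nn == 0) abort("Both classes must be present.")

  r <- rank(scores)  # mid-ranks for ties
  auc <- (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)

  # precision-recall step integration over distinct thresholds, descending;
  # tied scores enter as one block.
  ord <- order(scores, decreasing = TRUE)
  s_sorted <- scores[ord]
  y_sorted <- labels[ord]
  cut <- c(which(diff(s_sorted) != 0), length(s_sorted))
  tp <- cumsum(y_sorted)[cut]
  fp <- cut - tp
  prec <- tp / (tp + fp)
  rec <- tp / np
  aupr <- sum(diff(c(0, rec)) * prec)

  pred <- as.integer(scores >= 0.5)
  tp05 <- sum(pred == 1 & labels == 1)
  fp05 <- sum(pred == 1 & labels == 0)
  fn05 <- sum(pred == 0 & labels == 1)
  precision <- if (tp05 + fp05 == 0) 0 else tp05 / (tp05 + fp05)
  recall <- tp05 / (tp05 + fn05)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  accuracy <- mean(pred == labels)

  tibble::tibble(auc = auc, aupr = aupr, f1 = f1, accuracy = accuracy,
                 recall = recall, precision = precision)
}
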