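# Binary-classification evaluation: confusion counts, the four scalar
# metrics computed exactly from them, and a threshold-sweep ROC with
# trapezoidal AUC. "Severe" (label 1) is the positive class throughout.

#' Confusion counts
#'
#' @param predicted integer vector of 0/1 predictions.
#' @param truth integer vector of 0/1 labels (1 = severe = positive).
#' @return object of class `confusion_counts`: list with `TP`, `TN`, `FP`,
#'   `FN`.
#' @export
confusion_counts <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  stop_field(all(predicted %in% c(0, 1)), "predicted", "must be 0/1")
  stop_field(all(truth %in% c(0, 1)), "truth", "must be 0/1")
  structure(list(TP = sum(predicted == 1 & truth == 1),
                 TN = sum(predicted == 0 & truth == 0),
                 FP = sum(predicted == 1 & truth == 0),
                 FN = sum(predicted == 0 & truth == 1)),
            class = "confusion_counts")
}

#' Scalar classification metrics from confusion counts
#'
#' Accuracy = (TP+TN)/(TP+TN+FP+FN), Precision = TP/(TP+FP),
#' Recall = TP/(TP+FN), F1 = 2*Precision*Recall/(Precision+Recall).
#' A zero denominator yields the value 0 with the corresponding entry of
#' `degenerate` set to `TRUE`.
#'
#' @param counts a `confusion_counts` (or list with TP/TN/FP/FN).
#' @return list with `accuracy`, `precision`, `recall`, `f1`, `confusion`,
#'   and `degenerate` (named logical vector).
#' @export
compute_metrics <- function(counts) {
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  total <- TP + TN + FP + FN
  if (total == 0) stop("confusion counts are all zero", call. = FALSE)
  deg <- c(precision = FALSE, recall = FALSE, f1 = FALSE)
  accuracy <- (TP + TN) / total
  if (TP + FP == 0) { precision <- 0; deg["precision"] <- TRUE } else precision <- TP / (TP + FP)
  if (TP + FN == 0) { recall <- 0; deg["recall"] <- TRUE } else recall <- TP / (TP + FN)
  if (deg["precision"] || deg["recall"] || precision + recall == 0) {
    f1 <- 0; deg["f1"] <- TRUE
  } else {
    f1 <- 2 * precision * recall / (precision + recall)
  }
  list(accuracy = accuracy, precision = precision, recall = recall, f1 = f1,
       confusion = counts, degenerate = deg)
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the unique score values as decision thresholds (equal scores are
#' one threshold), accumulating (FPR, TPR) from (0,0) to (1,1), and
#' integrates the curve with the trapezoidal rule.
#'
#' @param scores numeric severe-class probabilities (or any monotone scores).
#' @param labels 0/1 labels; both classes must be present.
#' @return list with `roc_points` (data.frame `fpr`, `tpr`, ordered) and
#'   `auc`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  stop_field(all(labels %in% c(0, 1)), "labels", "must be 0/1")
  if (length(unique(labels)) < 2) stop("both classes required for ROC", call. = FALSE)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- labels[o]
  # cumulative counts at each distinct threshold (predict positive if >= thr)
  keep <- c(diff(s) != 0, TRUE)
  tp <- cumsum(y == 1)[keep]
  fp <- cumsum(y == 0)[keep]
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc_points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}
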