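#' Label peptides by IC50 threshold
#'
#' Applies the activity cutoff used to build the training set: a peptide is
#' active (label 1) iff its IC50 is strictly below the threshold; an IC50
#' equal to or above it is inactive (label 0).
#'
#' @param values Positive IC50 values (micromolar).
#' @param threshold Activity threshold in micromolar (default 2000).
#' @return Integer vector of 0/1 labels.
#' @export
#' @examples
#' label_by_ic50(c(10, 500, 2000, 5000))  # 1 1 0 0
label_by_ic50 <- function(values, threshold = 2000) {
  if (!is.numeric(values) || any(!is.finite(values)) || any(values <= 0))
    stop("IC50 values must be positive and finite", call. = FALSE)
  as.integer(values < threshold)
}

## rank-based AUC: probability a random positive outranks a random
## negative, ties counting one half (equivalent to the Wilcoxon statistic)
.auc_rank <- function(truth, scores) {
  pos <- scores[truth == 1L]
  neg <- scores[truth == 0L]
  if (length(pos) == 0L || length(neg) == 0L) return(NA_real_)
  r <- rank(c(pos, neg), ties.method = "average")
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Binary classification metrics
#'
#' Computes the five evaluation metrics from true labels, predicted labels
#' and predicted scores: accuracy, recall, precision, F1 and ROC-AUC (the
#' rank-based probability that a positive outranks a negative, ties counted
#' one half). If only one class is present in the truth, AUC is undefined
#' and reported as `NA` with a warning; precision/recall follow the usual
#' 0/0 -> NA convention.
#'
#' @param truth 0/1 true labels.
#' @param predicted 0/1 predicted labels.
#' @param scores Numeric scores (e.g. class-1 probabilities); defaults to
#'   `predicted`.
#' @return Named numeric vector `accuracy`, `recall`, `precision`, `f1`,
#'   `auc`.
#' @export
#' @examples
#' compute_metrics(c(1, 1, 0, 0), c(1, 0, 0, 0), c(.9, .4, .3, .2))
compute_metrics <- function(truth, predicted, scores = predicted) {
  truth <- as.integer(truth)
  predicted <- as.integer(predicted)
  if (length(truth) != length(predicted) || length(truth) != length(scores))
    stop("truth, predicted and scores must have equal length", call. = FALSE)
  if (!all(truth %in% 0:1) || !all(predicted %in% 0:1))
    stop("labels must be 0/1", call. = FALSE)

  tp <- sum(truth == 1L & predicted == 1L)
  tn <- sum(truth == 0L & predicted == 0L)
  fp <- sum(truth == 0L & predicted == 1L)
  fn <- sum(truth == 1L & predicted == 0L)

  accuracy <- (tp + tn) / length(truth)
  recall <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
  precision <- if (tp + fp > 0L) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(recall) && !is.na(precision) && (precision + recall) > 0)
    2 * precision * recall / (precision + recall) else NA_real_

  if (length(unique(truth)) < 2L) {
    warning("single-class truth: AUC undefined")
    auc <- NA_real_
  } else {
    auc <- .auc_rank(truth, scores)
  }

  c(accuracy = accuracy, recall = recall, precision = precision,
    f1 = f1, auc = auc)
}
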