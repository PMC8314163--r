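# Classification metrics. Precision/recall/F1 are computed with emphasis
# on the depressed class (label 1); AUC uses midrank tie handling.

#' Cohen's kappa
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` with the
#' expected agreement `p_e` from the marginal products; `kappa = 0` by
#' convention when `p_e = 1`.
#'
#' @param truth,pred Equal-length 0/1 vectors.
#' @return Scalar in `[-1, 1]`.
#' @export
#' @examples
#' cohen_kappa(rep(c(1, 0), c(50, 50)), rep(c(1, 0, 1, 0), c(40, 10, 10, 40)))
cohen_kappa <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  n <- length(truth)
  po <- mean(truth == pred)
  pe <- mean(truth == 1) * mean(pred == 1) + mean(truth == 0) * mean(pred == 0)
  if (abs(1 - pe) < 1e-15) return(0)
  (po - pe) / (1 - pe)
}

#' Area under the ROC curve with midrank ties
#'
#' Rank-based (Mann-Whitney) AUC of scores for the positive class:
#' `AUC = (sum of positive-score midranks - n1(n1+1)/2) / (n1 * n0)`.
#'
#' @param truth 0/1 labels.
#' @param score Numeric scores (probabilities or decision values) for the
#'   positive class; ties get midranks.
#' @return Scalar in `[0, 1]`, or `NA` if one class is absent.
#' @export
auc_score <- function(truth, score) {
  n1 <- sum(truth == 1)
  n0 <- sum(truth == 0)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score, ties.method = "average")
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Positive-class precision/recall/F1 from a confusion summary.
.prf <- function(tp, fp, fn) {
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1)
}

#' Full metric set for one set of predictions
#'
#' Accuracy, positive-class precision/recall/F1, midrank AUC (from
#' `score` when given, else from the hard predictions) and Cohen's
#' kappa — all on the 0-1 scale.
#'
#' @param truth,pred 0/1 vectors.
#' @param score Optional positive-class scores for the AUC.
#' @return One-row tibble with columns `accuracy`, `precision`,
#'   `recall`, `f1`, `auc`, `kappa`.
#' @export
metric_set <- function(truth, pred, score = NULL) {
  tp <- sum(truth == 1 & pred == 1)
  fp <- sum(truth == 0 & pred == 1)
  fn <- sum(truth == 1 & pred == 0)
  prf <- .prf(tp, fp, fn)
  tibble(
    accuracy = mean(truth == pred),
    precision = prf[["precision"]],
    recall = prf[["recall"]],
    f1 = prf[["f1"]],
    auc = auc_score(truth, if (is.null(score)) pred else score),
    kappa = cohen_kappa(truth, pred)
  )
}

# Macro-averaged F1 over the two classes (inner-CV model selection score).
macro_f1 <- function(truth, pred) {
  f1_pos <- .prf(
    sum(truth == 1 & pred == 1), sum(truth == 0 & pred == 1),
    sum(truth == 1 & pred == 0)
  )[["f1"]]
  f1_neg <- .prf(
    sum(truth == 0 & pred == 0), sum(truth == 1 & pred == 0),
    sum(truth == 0 & pred == 1)
  )[["f1"]]
  (f1_pos + f1_neg) / 2
}
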