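#' Area under the ROC curve (Mann-Whitney form)
#'
#' \deqn{AUC = (\#concordant + 0.5\,\#ties) / (n_+ n_-)} where pairs are
#' one positive (Treat = 1) and one negative (Control = 0) sample.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 (or `Control`/`Treat`) class labels.
#' @return the AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

as_binary_labels <- function(labels) {
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1")
    return(as.integer(labels))
  }
  lab <- as.character(labels)
  if (!all(lab %in% c("Control", "Treat"))) {
    stop("labels must be 0/1 or Control/Treat")
  }
  as.integer(lab == "Treat")
}

#' AUC with a DeLong confidence interval
#'
#' The variance of the empirical AUC is estimated from the positive and
#' negative placement values (DeLong's method); the normal-theory
#' interval is clipped to `[0, 1]`.
#'
#' @inheritParams roc_auc
#' @param level confidence level (default 0.95).
#' @return list with `auc`, `ci_low`, `ci_high`, `se`, `method`.
#' @export
auc_ci <- function(scores, labels, level = 0.95) {
  y <- as_binary_labels(labels)
  pos <- scores[y == 1]; neg <- scores[y == 0]
  if (length(pos) < 2 || length(neg) < 2) {
    stop("DeLong interval needs >= 2 samples per class")
  }
  # placement of each positive among negatives and vice versa
  v10 <- vapply(pos, function(s) mean((s > neg) + 0.5 * (s == neg)), 1)
  v01 <- vapply(neg, function(s) mean((pos > s) + 0.5 * (pos == s)), 1)
  auc <- mean(v10)
  se <- sqrt(var(v10) / length(pos) + var(v01) / length(neg))
  z <- qnorm(1 - (1 - level) / 2)
  list(auc = auc,
       ci_low = max(0, auc - z * se),
       ci_high = min(1, auc + z * se),
       se = se, method = "delong")
}

#' Confusion matrix at a probability threshold
#'
#' Predictions at or above the threshold are called `Treat` (positive).
#'
#' @param scores probabilities in `[0, 1]`.
#' @param labels 0/1 or `Control`/`Treat` truth.
#' @param threshold decision threshold (default 0.5; ties positive).
#' @return list of counts `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_at_threshold <- function(scores, labels, threshold = 0.5) {
  if (any(scores < 0 | scores > 1)) stop("scores must lie in [0, 1]")
  y <- as_binary_labels(labels)
  pred <- as.integer(scores >= threshold)
  list(TP = sum(pred == 1 & y == 1), FP = sum(pred == 1 & y == 0),
       TN = sum(pred == 0 & y == 0), FN = sum(pred == 0 & y == 1))
}

#' Sensitivity, specificity and accuracy from a confusion matrix
#'
#' Rates are returned as percentages rounded half-up to one decimal, the
#' convention used in diagnostic reports; raw fractions are attached as
#' an attribute.
#'
#' @param cm list with counts `TP`, `FP`, `TN`, `FN`.
#' @return named numeric vector `sensitivity`, `specificity`, `accuracy`
#'   (percent, 1 decimal) with attribute `raw` (fractions).
#' @export
confusion_rates <- function(cm) {
  with(cm, {
    if (TP + FN == 0) stop("sensitivity undefined: no positive samples")
    if (TN + FP == 0) stop("specificity undefined: no negative samples")
    raw <- c(sensitivity = TP / (TP + FN),
             specificity = TN / (TN + FP),
             accuracy = (TP + TN) / (TP + FP + TN + FN))
    out <- round_half_up(100 * raw, 1)
    attr(out, "raw") <- raw
    out
  })
}

#' Classify probabilities at a fixed threshold
#'
#' @param probabilities numeric in `[0, 1]`.
#' @param threshold decision threshold; `>= threshold` is `Treat`.
#' @return character vector of `Control`/`Treat` calls.
#' @export
predict_class <- function(probabilities, threshold = 0.5) {
  if (any(probabilities < 0 | probabilities > 1)) {
    stop("probabilities must lie in [0, 1]")
  }
  ifelse(probabilities >= threshold, "Treat", "Control")
}
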