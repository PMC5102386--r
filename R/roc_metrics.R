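#' Confusion counts at a single decision threshold
#'
#' Dichotomizes the sample at `threshold` with the package's fixed call
#' convention: subjects with `score >= threshold` are called positive (ties go
#' positive, consistent with higher scores indicating more disease).
#'
#' @param data A [labeled_scores] object.
#' @param threshold Finite decision threshold.
#' @return A list of class `confusion_counts` with integer fields
#'   `tp`, `fp`, `tn`, `fn`.
#' @examples
#' d <- labeled_scores(c(1, 2, 3, 4), c(0, 0, 1, 1))
#' confusion_at(d, 3)
#' @export
confusion_at <- function(data, threshold) {
  data <- as_labeled_scores(data)
  if (!is.finite(threshold)) stop("`threshold` must be finite", call. = FALSE)
  pos_call <- data$score >= threshold
  present  <- data$label == 1L
  structure(
    list(tp = sum(pos_call & present),
         fp = sum(pos_call & !present),
         tn = sum(!pos_call & !present),
         fn = sum(!pos_call & present)),
    class = "confusion_counts"
  )
}

#' Sensitivity, specificity and correct classification rate of counts
#'
#' @param counts A `confusion_counts` list (from [confusion_at()] or
#'   [ui_counts()]).
#' @return Named numeric vector with `se`, `sp`, `ccr`; `NaN` where the
#'   denominator is zero.
#' @export
classification_metrics <- function(counts) {
  with(counts, c(
    se  = tp / (tp + fn),
    sp  = tn / (tn + fp),
    ccr = (tp + tn) / (tp + tn + fp + fn)
  ))
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  TN %d  FN %d\n", x$tp, x$fp, x$tn, x$fn))
  m <- classification_metrics(x)
  cat(sprintf("Se %.4g  Sp %.4g  CCR %.4g\n", m["se"], m["sp"], m["ccr"]))
  invisible(x)
}

#' ROC coordinates over all observed thresholds
#'
#' Computes sensitivity and specificity at every distinct observed score plus
#' the two sentinel endpoints (-Inf: everyone called positive, Se = 1, Sp = 0;
#' +Inf: everyone called negative, Se = 0, Sp = 1). Sensitivity is
#' non-increasing and specificity non-decreasing in the threshold.
#'
#' @param data A [labeled_scores] object with both classes present.
#' @return A data frame with columns `threshold`, `se`, `sp`.
#' @export
roc_points <- function(data) {
  data <- as_labeled_scores(data)
  check_two_class(data)
  thr <- c(-Inf, sort(unique(data$score)), Inf)
  ss <- se_sp_at(data, thr)
  data.frame(threshold = thr, se = ss$se, sp = ss$sp)
}

# Vectorized Se/Sp at a sorted vector of thresholds (positive call: >= t).
# Se(t) = P(score >= t | label 1), Sp(t) = P(score < t | label 0).
se_sp_at <- function(data, thresholds) {
  s1 <- data$score[data$label == 1L]
  s0 <- data$score[data$label == 0L]
  n1 <- length(s1)
  n0 <- length(s0)
  # count of class scores strictly below each threshold
  below1 <- findInterval(thresholds, sort(s1), left.open = TRUE)
  below0 <- findInterval(thresholds, sort(s0), left.open = TRUE)
  list(se = (n1 - below1) / n1, sp = below0 / n0)
}

#' Empirical (Mann-Whitney) area under the ROC curve
#'
#' The probability that a randomly chosen subject with the condition outscores
#' a randomly chosen subject without it, with ties counted 1/2. Computed from
#' midranks, and identical to the trapezoidal area under [roc_points()].
#'
#' @param data A [labeled_scores] object with both classes present.
#' @return AUC in `[0, 1]`.
#' @export
empirical_auc <- function(data) {
  data <- as_labeled_scores(data)
  check_two_class(data)
  r <- rank(data$score)                # midranks handle ties as 1/2
  n1 <- sum(data$label == 1L)
  n0 <- nrow(data) - n1
  (sum(r[data$label == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Analytic AUC of a binormal test model
#'
#' For healthy scores ~ N(mu0, sd0^2) and diseased scores ~ N(mu1, sd1^2),
#' the AUC is `pnorm((mu1 - mu0) / sqrt(sd0^2 + sd1^2))`. It does not depend
#' on prevalence.
#'
#' @param model A [binormal_model] (or any list with `mu0`, `sd0`, `mu1`,
#'   `sd1`).
#' @return AUC in `[0, 1]`.
#' @examples
#' binormal_auc(binormal_model(1))   # strong test, 0.995
#' binormal_auc(binormal_model(27))  # weak test, 0.711
#' @export
binormal_auc <- function(model) {
  if (model$sd0 <= 0 || model$sd1 <= 0) {
    stop("standard deviations must be positive", call. = FALSE)
  }
  stats::pnorm((model$mu1 - model$mu0) / sqrt(model$sd0^2 + model$sd1^2))
}
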