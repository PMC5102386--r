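#' Classical single decision thresholds
#'
#' Seven dichotomization criteria commonly used for cutpoint selection on a
#' diagnostic score. All criteria scan the candidate grid of distinct observed
#' scores (positive call at `score >= threshold`):
#'
#' * `youden` — maximizes the Youden index Se + Sp - 1;
#' * `maxSe` — maximizes sensitivity, ties broken by higher specificity;
#' * `maxSp` — maximizes specificity, ties broken by higher sensitivity;
#' * `minPvalue` — minimizes the p-value of the (uncorrected) Pearson
#'   chi-squared test of association between the dichotomized score and the
#'   reference standard;
#' * `roc01` — minimizes the Euclidean distance of (1 - Sp, Se) to the ideal
#'   ROC corner (0, 1);
#' * `spEqualSe` — minimizes |Sp - Se|;
#' * `fixed` — uses `fixed_value` as the threshold (e.g. 0.5 for predicted
#'   probabilities).
#'
#' Remaining ties are broken deterministically by the smallest threshold.
#'
#' @param data A [labeled_scores] object with both classes present.
#' @param method One of `"youden"`, `"maxSe"`, `"maxSp"`, `"minPvalue"`,
#'   `"roc01"`, `"spEqualSe"`, `"fixed"`.
#' @param fixed_value Required for `method = "fixed"`; ignored otherwise.
#' @return A list of class `threshold_result` with fields `method`,
#'   `threshold`, `se`, `sp`, `ccr`.
#' @examples
#' d <- labeled_scores(1:6, c(0, 0, 0, 1, 1, 1))
#' optimal_threshold(d, "youden")
#' @export
optimal_threshold <- function(data,
                              method = c("youden", "maxSe", "maxSp", "minPvalue",
                                         "roc01", "spEqualSe", "fixed"),
                              fixed_value = NULL) {
  data <- as_labeled_scores(data)
  check_two_class(data)
  method <- match.arg(method)

  if (method == "fixed") {
    if (is.null(fixed_value) || !is.finite(fixed_value)) {
      stop("method \"fixed\" requires a finite `fixed_value`", call. = FALSE)
    }
    thr <- fixed_value
  } else {
    cand <- sort(unique(data$score))
    ss <- se_sp_at(data, cand)
    se <- ss$se
    sp <- ss$sp
    obj <- switch(method,
      youden    = se + sp - 1,
      maxSe     = se,
      maxSp     = sp,
      minPvalue = -pearson_p(data, se, sp),
      roc01     = -sqrt((1 - se)^2 + (1 - sp)^2),
      spEqualSe = -abs(sp - se)
    )
    tie <- switch(method, maxSe = sp, maxSp = se, rep(0, length(cand)))
    best <- obj >= max(obj) - 1e-12
    best_tie <- best & tie >= max(tie[best]) - 1e-12
    thr <- cand[which(best_tie)[1L]]    # candidates sorted: smallest optimum
  }

  m <- classification_metrics(confusion_at(data, thr))
  structure(
    list(method = method, threshold = thr,
         se = unname(m["se"]), sp = unname(m["sp"]), ccr = unname(m["ccr"])),
    class = "threshold_result"
  )
}

# Uncorrected Pearson chi-squared p-value of the 2x2 table at each candidate
# threshold, vectorized from Se/Sp. Degenerate margins (everyone called the
# same way) carry no association: p = 1.
pearson_p <- function(data, se, sp) {
  n1 <- sum(data$label == 1L)
  n0 <- nrow(data) - n1
  tp <- se * n1; fn <- n1 - tp
  tn <- sp * n0; fp <- n0 - tn
  n <- n0 + n1
  num <- n * (tp * tn - fp * fn)^2
  den <- (tp + fp) * (tn + fn) * n1 * n0
  stat <- ifelse(den > 0, num / den, 0)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("Decision threshold (%s): %.4g\n", x$method, x$threshold))
  cat(sprintf("Se %.3f  Sp %.3f  CCR %.3f\n", x$se, x$sp, x$ccr))
  invisible(x)
}
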