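#' Two-Graph ROC (TG-ROC) thresholds, nonparametric
#'
#' Plots (conceptually) sensitivity and specificity against the decision
#' threshold and reads off the two thresholds attaining a pre-selected level:
#' the lower bound of the Intermediate Range is the largest observed score
#' with Se >= `level` and the upper bound the smallest observed score with
#' Sp >= `level` (Se at threshold t is the proportion of positives with score
#' >= t; Sp the proportion of negatives with score < t, mirroring the
#' ties-positive call convention). Scores below the lower bound or above the
#' upper bound form the Valid Range; the scores between them the Intermediate
#' Range.
#'
#' For strong tests whose Se/Sp crossing lies above `level` the two bounds
#' come out reversed (lower > upper). They are then swapped back
#' ("re-reversed") and flagged, so the reported range is a proper interval
#' whose bounds attain even better than the requested level.
#'
#' Note that the achieved Se/Sp over the Valid Range is reported from the
#' data (via [quality_threshold()]) rather than assumed equal to `level`:
#' for tests of moderate strength it routinely falls short of it.
#'
#' @param data A [labeled_scores] object with both classes present.
#' @param level Pre-selected sensitivity/specificity level, in (0.5, 1);
#'   0.9 and 0.95 are the conventional choices.
#' @return An object of class `tgroc_result`: list with `level`, `lower`,
#'   `upper`, `reversed`, and `quality` (a [quality_threshold()] report over
#'   the Intermediate Range).
#' @examples
#' set.seed(2)
#' d <- labeled_scores(c(rnorm(250), rnorm(250, 2)), rep(0:1, each = 250))
#' tgroc_thresholds(d, 0.9)
#' @export
tgroc_thresholds <- function(data, level = 0.9) {
  data <- as_labeled_scores(data)
  check_two_class(data)
  if (!is.numeric(level) || level <= 0.5 || level >= 1) {
    stop("`level` must lie strictly between 0.5 and 1", call. = FALSE)
  }
  cand <- sort(unique(data$score))
  ss <- se_sp_at(data, cand)
  ok_se <- which(ss$se >= level)
  ok_sp <- which(ss$sp >= level)
  if (length(ok_se) == 0L) {
    stop(sprintf("sensitivity never reaches level %.2f on the candidate grid", level),
         call. = FALSE)
  }
  if (length(ok_sp) == 0L) {
    stop(sprintf("specificity never reaches level %.2f on the candidate grid", level),
         call. = FALSE)
  }
  lower <- cand[max(ok_se)]   # Se is non-increasing in the threshold
  upper <- cand[min(ok_sp)]   # Sp is non-decreasing
  reversed <- lower > upper
  if (reversed) {
    tmp <- lower; lower <- upper; upper <- tmp
  }
  structure(
    list(level = level, lower = lower, upper = upper, reversed = reversed,
         quality = quality_threshold(data, lower, upper)),
    class = "tgroc_result"
  )
}

#' @export
print.tgroc_result <- function(x, ...) {
  cat(sprintf("TG-ROC at level %.2f: Intermediate Range [%.4g, %.4g]%s\n",
              x$level, x$lower, x$upper,
              if (x$reversed) " (boundaries re-reversed: strong test)" else ""))
  q <- x$quality
  cat(sprintf("Valid Range (n = %d): CCR %.3f  Se %.3f  Sp %.3f\n",
              q$n_outside, q$mci_ccr, q$mci_se, q$mci_sp))
  invisible(x)
}
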