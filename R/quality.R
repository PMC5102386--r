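#' Trichotomous decision-table quality of a score interval
#'
#' Splits the sample into three zones — below `lower` (called negative),
#' inside `[lower, upper]` (inconclusive), above `upper` (called positive) —
#' and reports the 3x2 decision table together with the quality of the
#' decisions actually made, i.e. the More Certain Interval (MCI) metrics over
#' the two outer zones only: `mci_se` = positives above / positives outside,
#' `mci_sp` = negatives below / negatives outside, `mci_ccr` = correct calls /
#' subjects outside. With `lower == upper` the table degenerates to the usual
#' dichotomous confusion table at a single threshold.
#'
#' @param data A [labeled_scores] object.
#' @param lower,upper Interval bounds, `lower <= upper` (inclusive).
#' @return An object of class `tri_quality`: list with `table` (3x2 counts,
#'   zones x condition no/yes), `mci_ccr`, `mci_se`, `mci_sp`, `n_inside`,
#'   `n_outside`, and `mci_defined` (FALSE when no subject falls outside).
#' @examples
#' d <- make_clinical_fixture()
#' quality_threshold(d, attr(d, "lower"), attr(d, "upper"))
#' @export
quality_threshold <- function(data, lower, upper) {
  data <- as_labeled_scores(data)
  if (lower > upper) stop("`lower` must not exceed `upper`", call. = FALSE)
  if (lower == upper) {
    # degenerate zone: plain dichotomization at the threshold (ties positive)
    zone <- ifelse(data$score >= lower, "above", "below")
  } else {
    zone <- ifelse(data$score < lower, "below",
                   ifelse(data$score > upper, "above", "inside"))
  }
  zone <- factor(zone, levels = c("below", "inside", "above"))
  tab <- table(zone, factor(data$label, levels = 0:1, labels = c("no", "yes")))
  tab <- unclass(tab)[c("below", "inside", "above"), , drop = FALSE]

  neg_below <- tab["below", "no"];  pos_below <- tab["below", "yes"]
  neg_above <- tab["above", "no"];  pos_above <- tab["above", "yes"]
  n_out <- neg_below + pos_below + neg_above + pos_above
  structure(
    list(table = tab,
         mci_ccr = if (n_out > 0) (neg_below + pos_above) / n_out else NA_real_,
         mci_se  = if (pos_below + pos_above > 0) pos_above / (pos_below + pos_above) else NA_real_,
         mci_sp  = if (neg_below + neg_above > 0) neg_below / (neg_below + neg_above) else NA_real_,
         n_inside = sum(tab["inside", ]), n_outside = n_out,
         mci_defined = n_out > 0,
         lower = lower, upper = upper),
    class = "tri_quality"
  )
}

#' @export
print.tri_quality <- function(x, ...) {
  cat(sprintf("Decision table (interval [%.4g, %.4g]):\n", x$lower, x$upper))
  tab <- x$table
  dimnames(tab) <- list(
    Diagnosis = c("negative", "inconclusive", "positive"),
    Condition = c("no", "yes"))
  print(stats::addmargins(as.table(tab)))
  if (x$mci_defined) {
    cat(sprintf("Outside the interval (n = %d): CCR %.3f  Se %.3f  Sp %.3f\n",
                x$n_outside, x$mci_ccr, x$mci_se, x$mci_sp))
  } else {
    cat("No subjects outside the interval: MCI metrics undefined\n")
  }
  invisible(x)
}

#' Within-interval quality report for an Uncertain Interval
#'
#' Reports how inter-mixed the scores inside a found Uncertain Interval are:
#' the within-interval confusion counts relative to the intersection, their
#' Se/Sp/CCR, a continuity-corrected chi-squared test of the 2x2
#' below/above-intersection by class table (balance of TN vs FP and FN vs
#' TP), and a Welch two-sample t-test comparing the within-interval scores of
#' the two classes. Insignificant results support the interval being truly
#' inconclusive.
#'
#' @param data A [labeled_scores] object.
#' @param ui An `uncertain_interval` with `found = TRUE` (from
#'   [find_uncertain_interval()]).
#' @return A list of class `ui_quality`: `counts`, `ui_se`, `ui_sp`,
#'   `ui_ccr`, `chisq` (list `statistic`, `df`, `p`), `t_test` (list `t`,
#'   `df`, `p`, `mean_diff` = diseased minus healthy within-interval mean),
#'   and `tests_defined`.
#' @export
quality_threshold_uncertain <- function(data, ui) {
  data <- as_labeled_scores(data)
  if (!inherits(ui, "uncertain_interval") || !isTRUE(ui$found)) {
    stop("`ui` must be a found uncertain_interval", call. = FALSE)
  }
  counts <- ui_counts(data, ui$lower, ui$upper, ui$intersection)
  m <- classification_metrics(counts)
  inside <- data$score >= ui$lower & data$score <= ui$upper
  x0 <- data$score[inside & data$label == 0L]
  x1 <- data$score[inside & data$label == 1L]

  defined <- length(x0) >= 2L && length(x1) >= 2L &&
    (stats::var(x0) > 0 || stats::var(x1) > 0)
  chi <- tt <- NULL
  if (defined) {
    # Table 3 layout: rows below/above the intersection, columns class no/yes
    tab <- with(counts, matrix(c(tn, fp, fn, tp), nrow = 2))
    chi <- tryCatch(chisq_yates(tab), error = function(e) NULL)
    tt <- welch_t(x0, x1)
    tt$mean_diff <- mean(x1) - mean(x0)
  }
  structure(
    list(counts = counts,
         ui_se = unname(m["se"]), ui_sp = unname(m["sp"]), ui_ccr = unname(m["ccr"]),
         chisq = chi, t_test = tt,
         tests_defined = defined && !is.null(chi)),
    class = "ui_quality"
  )
}

#' @export
print.ui_quality <- function(x, ...) {
  cat("Within the Uncertain Interval:\n")
  print(x$counts)
  if (x$tests_defined) {
    cat(sprintf("Balance chi-squared: %.3f (df %d, p = %.3f)\n",
                x$chisq$statistic, x$chisq$df, x$chisq$p))
    cat(sprintf("Welch t: %.2f (df %.2f, p = %.3f), mean difference %.3f\n",
                x$t_test$t, x$t_test$df, x$t_test$p, x$t_test$mean_diff))
  } else {
    cat("Within-interval tests undefined (a class is empty or degenerate)\n")
  }
  invisible(x)
}

#' Continuity-corrected chi-squared test for a 2x2 table
#'
#' Pearson's chi-squared with the Yates continuity correction:
#' `sum((max(|O - E| - 0.5, 0))^2 / E)` on 1 degree of freedom.
#'
#' @param table A 2x2 matrix of non-negative counts with positive margins.
#' @return List with `statistic`, `df` (= 1), `p`.
#' @examples
#' chisq_yates(matrix(c(47, 39, 26, 31), nrow = 2))  # 0.788, p = 0.375
#' @export
chisq_yates <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("`table` must be 2x2", call. = FALSE)
  if (any(table < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("all table margins must be positive", call. = FALSE)
  }
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  stat <- sum(pmax(abs(table - expected) - 0.5, 0)^2 / expected)
  list(statistic = stat, df = 1L,
       p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Welch two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value, comparing `mean(x) - mean(y)`.
#'
#' @param x,y Numeric vectors, each of length >= 2, not both with zero
#'   variance.
#' @return List with `t`, `df`, `p`.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) {
    stop("each sample needs at least 2 observations", call. = FALSE)
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, df = length(x) + length(y) - 2, p = 1))
    stop("both samples have zero variance", call. = FALSE)
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}
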