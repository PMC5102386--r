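#' Within-interval confusion counts relative to the intersection
#'
#' Restricts the sample to scores in `[lower, upper]` (both bounds inclusive)
#' and counts the four cells relative to the intersection, which acts as the
#' internal cut of the interval: negatives at or below the intersection are
#' true negatives, positives at or below it false negatives, positives above
#' it true positives, negatives above it false positives. Ties at the
#' intersection go to the lower half.
#'
#' @param data A [labeled_scores] object.
#' @param lower,upper Interval bounds, `lower <= upper`.
#' @param intersection Internal cut, `lower <= intersection <= upper`.
#' @return A `confusion_counts` list; all zeros for an empty interval.
#' @export
ui_counts <- function(data, lower, upper, intersection) {
  data <- as_labeled_scores(data)
  if (lower > upper) stop("`lower` must not exceed `upper`", call. = FALSE)
  if (intersection < lower || intersection > upper) {
    stop("`intersection` must lie inside [lower, upper]", call. = FALSE)
  }
  inside <- data$score >= lower & data$score <= upper
  low_half <- data$score <= intersection
  present <- data$label == 1L
  structure(
    list(tp = sum(inside & present & !low_half),
         fp = sum(inside & !present & !low_half),
         tn = sum(inside & !present & low_half),
         fn = sum(inside & present & low_half)),
    class = "confusion_counts"
  )
}

#' Search for the Uncertain Interval
#'
#' The core trichotomization step. An interval `[lower, upper]` of test scores
#' around the intersection of the two class densities is *uncertain* when the
#' scores inside it are so inter-mixed that calling subjects by the
#' intersection yields within-interval sensitivity and specificity no better
#' than `select` (default 0.55, i.e. TP/FN <= 1.22 and TN/FP <= 1.22 — a
#' small tolerated positive bias over the perfectly uncertain 0.5). Decisions
#' for subjects inside such an interval are essentially coin flips and are
#' better withheld.
#'
#' Candidate bounds range over the distinct observed scores with
#' `lower <= intersection <= upper`. A candidate is feasible when all four
#' within-interval cells (see [ui_counts()]) are at least 1 and both
#' within-interval Se and Sp are at most `select`. Among feasible candidates
#' the one containing the most subjects is returned (ties: widest score
#' range, then smallest lower bound). For strong tests with little overlap no
#' feasible candidate may exist; `found` is then `FALSE`.
#'
#' @param data A [labeled_scores] object with both classes present.
#' @param select Upper bound for within-interval Se and Sp, in (0.5, 1).
#' @param intersection `"kde"` or `"normal"` (passed to
#'   [estimate_intersection()]), or a numeric intersection supplied directly.
#' @return An object of class `uncertain_interval`: a list with `found`,
#'   `lower`, `upper`, `intersection`, `counts` (within-interval
#'   `confusion_counts`), `ui_se`, `ui_sp`, `ui_ccr`, `n_inside`, `select`,
#'   and `reason` when not found.
#' @examples
#' set.seed(7)
#' d <- labeled_scores(c(rnorm(300), rnorm(300, 1.5)), rep(0:1, each = 300))
#' find_uncertain_interval(d)
#' @export
find_uncertain_interval <- function(data, select = 0.55,
                                    intersection = c("kde", "normal")) {
  data <- as_labeled_scores(data)
  check_two_class(data)
  if (!is.numeric(select) || select <= 0.5 || select >= 1) {
    stop("`select` must lie strictly between 0.5 and 1", call. = FALSE)
  }
  if (is.character(intersection)) {
    ix <- tryCatch(estimate_intersection(data, match.arg(intersection)),
                   error = function(e) e)
    if (inherits(ix, "error")) {
      return(ui_not_found(select, paste("intersection undeterminable:",
                                        conditionMessage(ix))))
    }
  } else {
    ix <- as.numeric(intersection)
  }

  s <- sort(unique(data$score))
  lower_cand <- s[s <= ix]
  upper_cand <- s[s >= ix]
  if (length(lower_cand) == 0L || length(upper_cand) == 0L) {
    return(ui_not_found(select, "no candidate bounds on one side of the intersection",
                        intersection = ix))
  }

  s0 <- sort(data$score[data$label == 0L])
  s1 <- sort(data$score[data$label == 1L])
  # cumulative class counts: #scores <= x, and strictly < x for the lower bound
  n0_le_ix <- findInterval(ix, s0)
  n1_le_ix <- findInterval(ix, s1)
  tn_l <- n0_le_ix - findInterval(lower_cand, s0, left.open = TRUE)  # neg in [L, ix]
  fn_l <- n1_le_ix - findInterval(lower_cand, s1, left.open = TRUE)  # pos in [L, ix]
  fp_u <- findInterval(upper_cand, s0) - n0_le_ix                    # neg in (ix, U]
  tp_u <- findInterval(upper_cand, s1) - n1_le_ix                    # pos in (ix, U]

  # Feasibility: cells >= 1, Se = tp/(tp+fn) <= select, Sp = tn/(tn+fp) <= select,
  # i.e. tp <= r*fn and tn <= r*fp with r = select/(1-select). For a given lower
  # bound, tp and fp are nondecreasing in the upper bound, so the largest upper
  # bound with tp <= r*fn maximizes the subject count; tn <= r*fp is a lower
  # bound on fp, also best served by the largest upper bound.
  r <- select / (1 - select)
  eps <- 1e-9
  best_u <- findInterval(r * fn_l + eps, tp_u)     # index of largest feasible U
  ok <- best_u >= 1L & tn_l >= 1L & fn_l >= 1L
  ok[ok] <- tp_u[best_u[ok]] >= 1L & fp_u[best_u[ok]] >= 1L &
            tn_l[ok] <= r * fp_u[best_u[ok]] + eps
  if (!any(ok)) {
    return(ui_not_found(select, "no feasible interval under the select constraint",
                        intersection = ix))
  }

  count <- ifelse(ok, tn_l + fn_l + tp_u[pmax(best_u, 1L)] + fp_u[pmax(best_u, 1L)], -Inf)
  width <- ifelse(ok, upper_cand[pmax(best_u, 1L)] - lower_cand, -Inf)
  # most subjects, then widest range, then smallest lower bound
  pick <- order(-count, -width, lower_cand)[1L]
  lower <- lower_cand[pick]
  upper <- upper_cand[best_u[pick]]

  counts <- ui_counts(data, lower, upper, ix)
  m <- classification_metrics(counts)
  structure(
    list(found = TRUE, lower = lower, upper = upper, intersection = ix,
         counts = counts,
         ui_se = unname(m["se"]), ui_sp = unname(m["sp"]), ui_ccr = unname(m["ccr"]),
         n_inside = with(counts, tp + fp + tn + fn),
         select = select, reason = NULL),
    class = "uncertain_interval"
  )
}

ui_not_found <- function(select, reason, intersection = NA_real_) {
  structure(
    list(found = FALSE, lower = NA_real_, upper = NA_real_,
         intersection = intersection, counts = NULL,
         ui_se = NA_real_, ui_sp = NA_real_, ui_ccr = NA_real_,
         n_inside = 0L, select = select, reason = reason),
    class = "uncertain_interval"
  )
}

#' @export
print.uncertain_interval <- function(x, ...) {
  if (!x$found) {
    cat("Uncertain Interval: not found —", x$reason, "\n")
    return(invisible(x))
  }
  cat(sprintf("Uncertain Interval: [%.4g, %.4g] (intersection %.4g)\n",
              x$lower, x$upper, x$intersection))
  cat(sprintf("%d subjects inside; within-interval Se %.3f, Sp %.3f, CCR %.3f (select %.2f)\n",
              x$n_inside, x$ui_se, x$ui_sp, x$ui_ccr, x$select))
  invisible(x)
}
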