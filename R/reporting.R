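#' Mixed probability histogram data
#'
#' Overlaid per-class histograms on identical bin edges, the standard way to
#' visualize how inter-mixed the two classes are over the score range. When
#' all scores are probabilities in `[0, 1]` the default range is `[0, 1]`
#' with 20 bins; otherwise the observed score range is used.
#'
#' @param data A [labeled_scores] object.
#' @param bins Number of bins (>= 2).
#' @param range Length-2 numeric range; default `[0, 1]` for probabilities,
#'   the data range otherwise.
#' @return A list of class `mixed_histogram`: `bin_edges` (length
#'   `bins + 1`), `counts0`, `counts1` (per-class counts per bin).
#' @export
mixed_probability_histogram <- function(data, bins = 20, range = NULL) {
  data <- as_labeled_scores(data)
  if (bins < 2) stop("`bins` must be at least 2", call. = FALSE)
  if (is.null(range)) {
    range <- if (all(data$score >= 0 & data$score <= 1)) c(0, 1)
             else base::range(data$score)
  }
  edges <- seq(range[1], range[2], length.out = bins + 1)
  count_class <- function(lab) {
    s <- data$score[data$label == lab & data$score >= range[1] & data$score <= range[2]]
    if (length(s) == 0L) {
      warning(sprintf("no class-%d subjects in range: zero counts", lab))
      return(integer(bins))
    }
    graphics::hist(s, breaks = edges, plot = FALSE, include.lowest = TRUE)$counts
  }
  structure(
    list(bin_edges = edges, counts0 = count_class(0L), counts1 = count_class(1L)),
    class = "mixed_histogram"
  )
}

#' TG-ROC curve data
#'
#' Sensitivity and specificity against the decision threshold, the two curves
#' a TG-ROC plot overlays. Thin wrapper over [roc_points()].
#'
#' @param data A [labeled_scores] object with both classes present.
#' @return Data frame with columns `threshold`, `se`, `sp` (finite
#'   thresholds only).
#' @export
tgroc_curve_data <- function(data) {
  pts <- roc_points(data)
  pts[is.finite(pts$threshold), , drop = FALSE]
}

#' Per-class density curves with the intersection marker
#'
#' Gaussian-kernel density estimates for each class on a shared grid (the
#' same estimator the Uncertain Interval uses) plus the estimated
#' intersection.
#'
#' @param data A [labeled_scores] object.
#' @param method Intersection estimator passed to [estimate_intersection()].
#' @return A list of class `density_curves`: `x` (grid), `d0`, `d1`
#'   (densities), `intersection`.
#' @export
density_curves <- function(data, method = "kde") {
  data <- as_labeled_scores(data)
  ix <- estimate_intersection(data, method)
  s0 <- data$score[data$label == 0L]
  s1 <- data$score[data$label == 1L]
  pad <- 3 * max(stats::bw.nrd0(s0), stats::bw.nrd0(s1))
  lo <- min(data$score) - pad
  hi <- max(data$score) + pad
  d0 <- stats::density(s0, n = 512, from = lo, to = hi)
  d1 <- stats::density(s1, n = 512, from = lo, to = hi)
  structure(list(x = d0$x, d0 = d0$y, d1 = d1$y, intersection = ix),
            class = "density_curves")
}

#' Render a mixed probability histogram
#'
#' @param data A [labeled_scores] object.
#' @param bins,range Passed to [mixed_probability_histogram()].
#' @param highlight Optional length-2 interval shaded on the plot (e.g. a
#'   found Uncertain Interval).
#' @return A ggplot object.
#' @export
plot_mph <- function(data, bins = 20, range = NULL, highlight = NULL) {
  h <- mixed_probability_histogram(data, bins, range)
  mids <- (h$bin_edges[-1] + h$bin_edges[-length(h$bin_edges)]) / 2
  df <- data.frame(
    mid = rep(mids, 2),
    count = c(h$counts0, h$counts1),
    condition = rep(c("absent", "present"), each = length(mids))
  )
  w <- diff(h$bin_edges[1:2])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$count,
                                        fill = .data$condition)) +
    ggplot2::geom_col(position = "identity", alpha = 0.55, width = w) +
    ggplot2::labs(x = "test score", y = "count", fill = "condition") +
    ggplot2::theme_minimal()
  if (!is.null(highlight)) {
    p <- p + ggplot2::annotate("rect", xmin = highlight[1], xmax = highlight[2],
                               ymin = -Inf, ymax = Inf, alpha = 0.15)
  }
  p
}

#' Render the TG-ROC curves
#'
#' @param data A [labeled_scores] object.
#' @param level Optional horizontal reference line at the pre-selected level.
#' @return A ggplot object.
#' @export
plot_tgroc <- function(data, level = NULL) {
  cd <- tgroc_curve_data(data)
  df <- data.frame(
    threshold = rep(cd$threshold, 2),
    value = c(cd$se, cd$sp),
    curve = rep(c("sensitivity", "specificity"), each = nrow(cd))
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold, y = .data$value,
                                        colour = .data$curve)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "decision threshold", y = "proportion") +
    ggplot2::theme_minimal()
  if (!is.null(level)) p <- p + ggplot2::geom_hline(yintercept = level, linetype = 2)
  p
}

#' Render the class densities and their intersection
#'
#' @param data A [labeled_scores] object.
#' @param method Intersection estimator.
#' @return A ggplot object.
#' @export
plot_densities <- function(data, method = "kde") {
  dc <- density_curves(data, method)
  df <- data.frame(
    x = rep(dc$x, 2),
    density = c(dc$d0, dc$d1),
    condition = rep(c("absent", "present"), each = length(dc$x))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$density,
                                   colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = dc$intersection, linetype = 2) +
    ggplot2::labs(x = "test score", y = "density") +
    ggplot2::theme_minimal()
}
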