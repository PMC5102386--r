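#' Intersection of the two class score distributions
#'
#' Estimates the score at which the densities of the two classes cross
#' between the two class means. At this point a test score carries no
#' diagnostic information: a subject there is (density-wise) equally likely to
#' come from either class.
#'
#' Two estimators are available:
#'
#' * `"kde"` (default) — Gaussian-kernel density estimates for each class
#'   (Silverman's rule-of-thumb bandwidth per class) evaluated on a shared
#'   512-point grid; crossings are located by linear interpolation of the
#'   density difference and the crossing nearest the midpoint of the class
#'   means is returned.
#' * `"normal"` — fits a normal distribution per class (sample mean and sd)
#'   and solves the quadratic obtained by equating the log-densities in
#'   closed form, keeping the root between the class means.
#'
#' @param data A [labeled_scores] object with at least 2 subjects per class.
#' @param method `"kde"` or `"normal"`.
#' @return The intersection score (scalar).
#' @examples
#' set.seed(1)
#' d <- labeled_scores(c(rnorm(200), rnorm(200, 3)), rep(0:1, each = 200))
#' estimate_intersection(d, "normal")  # close to 1.5
#' @export
estimate_intersection <- function(data, method = c("kde", "normal")) {
  data <- as_labeled_scores(data)
  method <- match.arg(method)
  s0 <- data$score[data$label == 0L]
  s1 <- data$score[data$label == 1L]
  if (length(s0) < 2L || length(s1) < 2L) {
    stop("need at least 2 subjects per class to estimate the intersection",
         call. = FALSE)
  }
  m0 <- mean(s0); m1 <- mean(s1)
  if (isTRUE(all.equal(m0, m1))) {
    stop("class means coincide: intersection between the means is undeterminable",
         call. = FALSE)
  }
  lo_mean <- min(m0, m1); hi_mean <- max(m0, m1)

  if (method == "normal") {
    v0 <- stats::sd(s0); v1 <- stats::sd(s1)
    if (v0 <= 0 || v1 <= 0) {
      stop("zero within-class variance: intersection undeterminable", call. = FALSE)
    }
    roots <- normal_crossings(m0, v0, m1, v1)
    roots <- roots[roots > lo_mean & roots < hi_mean]
    if (length(roots) == 0L) {
      stop("no density crossing between the class means", call. = FALSE)
    }
    return(roots[which.min(abs(roots - (m0 + m1) / 2))])
  }

  bw0 <- stats::bw.nrd0(s0)
  bw1 <- stats::bw.nrd0(s1)
  pad <- 3 * max(bw0, bw1)
  lo <- min(data$score) - pad
  hi <- max(data$score) + pad
  d0 <- stats::density(s0, bw = bw0, n = 512, from = lo, to = hi)
  d1 <- stats::density(s1, bw = bw1, n = 512, from = lo, to = hi)
  x <- d0$x
  dif <- d0$y - d1$y
  sgn <- sign(dif)
  flip <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  # linear interpolation of the zero crossing inside each flipped grid cell
  cross <- x[flip] + (x[flip + 1] - x[flip]) * dif[flip] / (dif[flip] - dif[flip + 1])
  cross <- c(cross, x[sgn == 0])
  between <- cross[cross > lo_mean & cross < hi_mean]
  if (length(between) > 0L) {
    return(between[which.min(abs(between - (m0 + m1) / 2))])
  }
  # Sampling noise can push the crossing just past a class mean; accept the
  # crossing nearest the midpoint within one mean-gap of the means, and
  # reject remote tail crossings.
  gap <- hi_mean - lo_mean
  near <- cross[cross > lo_mean - gap & cross < hi_mean + gap]
  if (length(near) == 0L) {
    stop("no density crossing between the class means", call. = FALSE)
  }
  near[which.min(abs(near - (m0 + m1) / 2))]
}

# Real solutions of phi((x-m0)/v0)/v0 = phi((x-m1)/v1)/v1 (log scale).
normal_crossings <- function(m0, v0, m1, v1) {
  a <- 1 / (2 * v1^2) - 1 / (2 * v0^2)
  b <- m0 / v0^2 - m1 / v1^2
  cc <- m1^2 / (2 * v1^2) - m0^2 / (2 * v0^2) + log(v1 / v0)
  if (abs(a) < 1e-12) {
    if (abs(b) < 1e-12) return(numeric(0))
    return(-cc / b)
  }
  disc <- b^2 - 4 * a * cc
  if (disc < 0) return(numeric(0))
  (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
}
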