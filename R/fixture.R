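#' Synthetic clinical-shaped fixture
#'
#' A deterministic 380-subject sample (227 without, 153 with the condition)
#' of predicted probabilities shaped like a typical pre-surgical prediction
#' problem: an uncertain zone `[0.226, 0.632]` around an intersection at
#' 0.42, with zone-by-class counts 124/86/17 (condition absent) and 13/57/83
#' (condition present) across the below/inside/above zones, and the inside
#' zone split 47/39 vs 26/31 at the intersection. Scores are evenly spaced
#' within each zone; only the counts carry meaning, so any deterministic
#' placement is equivalent. This is synthetic data, not a real patient
#' dataset.
#'
#' @return A [labeled_scores] object with attributes `lower`, `upper`,
#'   `intersection` giving the zone boundaries the counts were built around.
#' @examples
#' d <- make_clinical_fixture()
#' quality_threshold(d, attr(d, "lower"), attr(d, "upper"))
#' @export
make_clinical_fixture <- function() {
  fill <- function(a, b, k) if (k > 0) seq(a, b, length.out = k) else numeric(0)
  scores <- c(
    # below zone: called negative
    fill(0.010, 0.220, 124),  # condition absent
    fill(0.030, 0.210, 13),   # condition present
    # inside zone, at or below the intersection
    fill(0.230, 0.415, 47),
    fill(0.235, 0.410, 26),
    # inside zone, above the intersection
    fill(0.425, 0.630, 39),
    fill(0.430, 0.625, 31),
    # above zone: called positive
    fill(0.640, 0.958, 17),
    fill(0.645, 0.976, 83)
  )
  labels <- rep(c(0, 1, 0, 1, 0, 1, 0, 1),
                c(124, 13, 47, 26, 39, 31, 17, 83))
  out <- labeled_scores(scores, labels)
  attr(out, "lower") <- 0.226
  attr(out, "upper") <- 0.632
  attr(out, "intersection") <- 0.42
  out
}
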