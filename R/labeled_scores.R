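#' Paired test scores and reference-standard labels
#'
#' Construct the basic input object used throughout the package: one test
#' score per subject paired with a binary reference-standard label. The
#' orientation convention is fixed: higher scores indicate more of the target
#' condition, so label 1 ("diseased") subjects are expected to score higher
#' than label 0 ("healthy") subjects. Scores with the opposite orientation
#' should be negated before use (see `higher_is_positive` in
#' [read_labeled_scores()]).
#'
#' @param scores Numeric vector of test scores (finite).
#' @param labels Vector coercible to 0/1; 0 = condition absent,
#'   1 = condition present. Logical vectors and the character values
#'   "0"/"1" are accepted.
#' @return A data frame of class `labeled_scores` with columns `score`
#'   and `label`.
#' @examples
#' d <- labeled_scores(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
#' empirical_auc(d)
#' @export
labeled_scores <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop("`scores` and `labels` must have the same length", call. = FALSE)
  }
  if (length(scores) == 0L) {
    stop("no data: at least one subject is required", call. = FALSE)
  }
  scores <- as.numeric(scores)
  if (anyNA(scores) || any(!is.finite(scores))) {
    stop("`scores` must be finite and non-missing", call. = FALSE)
  }
  if (is.logical(labels)) labels <- as.integer(labels)
  labels <- suppressWarnings(as.numeric(as.character(labels)))
  if (anyNA(labels) || !all(labels %in% c(0, 1))) {
    stop("`labels` must be binary (0 = condition absent, 1 = condition present)",
         call. = FALSE)
  }
  structure(
    data.frame(score = scores, label = as.integer(labels)),
    class = c("labeled_scores", "data.frame")
  )
}

#' @export
print.labeled_scores <- function(x, ...) {
  n1 <- sum(x$label == 1L)
  cat(sprintf("Labeled test scores: %d subjects (%d without, %d with the condition)\n",
              nrow(x), nrow(x) - n1, n1))
  cat(sprintf("Score range: [%.4g, %.4g]\n", min(x$score), max(x$score)))
  invisible(x)
}

as_labeled_scores <- function(data) {
  if (inherits(data, "labeled_scores")) return(data)
  if (is.data.frame(data) && all(c("score", "label") %in% names(data))) {
    return(labeled_scores(data$score, data$label))
  }
  stop("expected a `labeled_scores` object or a data frame with columns `score` and `label`",
       call. = FALSE)
}

# Stop unless both classes are present (ROC-type operations need both).
check_two_class <- function(data) {
  if (length(unique(data$label)) < 2L) {
    stop("both classes must be present: need at least one subject with and one without the condition",
         call. = FALSE)
  }
  invisible(data)
}

#' Read labeled scores from a delimited text file
#'
#' Reads a CSV (or other delimited) file with a header and returns a validated
#' [labeled_scores] object. Column names are configurable; labels must be
#' coercible to 0/1. Each validation failure produces a distinct error
#' message, so malformed inputs are easy to diagnose.
#'
#' @param path Path to the file.
#' @param score_col,label_col Column names (defaults `"score"`, `"label"`).
#' @param higher_is_positive If `FALSE`, scores are negated on input so the
#'   package's fixed orientation (higher = more disease) holds.
#' @param sep Field separator; `","` by default, use `"\t"` for TSV.
#' @return A [labeled_scores] object.
#' @export
read_labeled_scores <- function(path, score_col = "score", label_col = "label",
                                higher_is_positive = TRUE, sep = ",") {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c(score_col, label_col)) {
    if (!col %in% names(df)) {
      stop(sprintf("column `%s` not found in %s", col, path), call. = FALSE)
    }
  }
  scores <- suppressWarnings(as.numeric(df[[score_col]]))
  if (anyNA(scores)) {
    stop(sprintf("column `%s` contains non-numeric or missing scores", score_col),
         call. = FALSE)
  }
  if (!higher_is_positive) scores <- -scores
  labs <- df[[label_col]]
  if (!all(as.character(labs) %in% c("0", "1", "TRUE", "FALSE"))) {
    stop(sprintf("column `%s` must contain only binary labels (0/1)", label_col),
         call. = FALSE)
  }
  labeled_scores(scores, labs)
}

#' Write labeled scores to a delimited text file
#'
#' @param data A [labeled_scores] object (or coercible data frame).
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_labeled_scores <- function(data, path, sep = ",") {
  data <- as_labeled_scores(data)
  utils::write.table(data, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
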