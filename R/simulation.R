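#' Binormal test models
#'
#' The simulation grid describes a diagnostic test by a binormal pair:
#' healthy scores ~ N(0, 1) (fixed) and diseased scores ~ N(mu1, sd1^2),
#' sampled with a given prevalence. The standard 27-model grid crosses
#' mu1 in \{3, 2, 1\} (descending), sd1 in \{0.6, 1, 1.5\} (ascending) and
#' prevalence in \{0.5, 0.2, 0.1\} (descending), spanning strong
#' (AUC 0.995) to weak (AUC 0.711) tests.
#'
#' @param model_id Integer 1-27 selecting a row of the standard grid; or
#'   supply `mu1`, `sd1`, `prevalence` directly (and leave `model_id` NULL).
#' @param mu1,sd1,prevalence Parameters of the diseased distribution and the
#'   sampling prevalence.
#' @return A list of class `binormal_model` with fields `model_id`, `mu0`,
#'   `sd0`, `mu1`, `sd1`, `prevalence`.
#' @examples
#' binormal_model(1)                      # strong test
#' binormal_model(mu1 = 2, sd1 = 1, prevalence = 0.5)
#' @export
binormal_model <- function(model_id = NULL, mu1 = NULL, sd1 = NULL,
                           prevalence = NULL) {
  if (!is.null(model_id)) {
    if (!model_id %in% 1:27) stop("`model_id` must be in 1..27", call. = FALSE)
    g <- binormal_model_grid()
    row <- g[g$model_id == model_id, ]
    mu1 <- row$mu1; sd1 <- row$sd1; prevalence <- row$prevalence
  } else {
    if (is.null(mu1) || is.null(sd1) || is.null(prevalence)) {
      stop("supply either `model_id` or all of `mu1`, `sd1`, `prevalence`",
           call. = FALSE)
    }
    model_id <- NA_integer_
  }
  if (sd1 <= 0) stop("`sd1` must be positive", call. = FALSE)
  if (prevalence <= 0 || prevalence >= 1) {
    stop("`prevalence` must lie in (0, 1)", call. = FALSE)
  }
  structure(
    list(model_id = as.integer(model_id), mu0 = 0, sd0 = 1,
         mu1 = mu1, sd1 = sd1, prevalence = prevalence),
    class = "binormal_model"
  )
}

#' @rdname binormal_model
#' @return `binormal_model_grid()`: a 27-row data frame with columns
#'   `model_id`, `mu1`, `sd1`, `prevalence`.
#' @export
binormal_model_grid <- function() {
  g <- expand.grid(prevalence = c(0.5, 0.2, 0.1), sd1 = c(0.6, 1, 1.5),
                   mu1 = c(3, 2, 1))
  data.frame(model_id = 1:27, mu1 = g$mu1, sd1 = g$sd1,
             prevalence = g$prevalence)
}

#' Draw one binormal sample
#'
#' Class sizes are fixed at `round(n * prevalence)` diseased subjects (the
#' rest healthy) rather than drawn binomially, so every replicate represents
#' the stated prevalence exactly.
#'
#' @param model A [binormal_model].
#' @param n Total sample size.
#' @param seed Integer seed; the draw is fully reproducible given it.
#' @return A [labeled_scores] object of `n` subjects.
#' @export
binormal_sample <- function(model, n, seed) {
  n1 <- round(n * model$prevalence)
  n0 <- n - n1
  if (n1 < 1L || n0 < 1L) {
    stop("degenerate class size: need at least one subject per class", call. = FALSE)
  }
  set.seed(seed)
  labeled_scores(
    c(stats::rnorm(n0, model$mu0, model$sd0), stats::rnorm(n1, model$mu1, model$sd1)),
    rep(0:1, c(n0, n1))
  )
}

#' Monte-Carlo comparison of Youden, Uncertain Interval and TG-ROC
#'
#' Runs `reps` replicates of a binormal model. Each replicate draws a sample,
#' fits the maximized-Youden single threshold, searches for the Uncertain
#' Interval (recording when none exists) and determines the TG-ROC
#' Intermediate Range, then computes the decision quality of each: CCR/Se/Sp
#' at the Youden cut, over the More Certain Interval and the Valid Range
#' (outer zones), and within the Uncertain Interval and Intermediate Range
#' (internal cut at the estimated density intersection), plus the
#' within-range Welch t-test of the class score means.
#'
#' Replicate failures (no feasible Uncertain Interval; TG-ROC level
#' unattainable) are recorded in `p_na` / `p_tg_na` and excluded from the
#' corresponding means, never fatal.
#'
#' @param model A [binormal_model].
#' @param reps Number of replicates.
#' @param n Subjects per replicate.
#' @param seed Master seed; replicate r of model m uses
#'   `seed + m * 100000 + r` (m = 0 for ad-hoc models), recorded per
#'   replicate for replay.
#' @param select Uncertain Interval bound on within-interval Se/Sp.
#' @param level TG-ROC pre-selected Se/Sp level.
#' @param intersection Intersection estimator, `"kde"` or `"normal"`.
#' @param keep_reps If TRUE, attach the per-replicate results as attribute
#'   `"replicates"`.
#' @return A one-row data frame (class `simulation_summary`) of means over
#'   replicates: AUC; Youden threshold/CCR/Sp/Se; Uncertain Interval bounds,
#'   MCI size/CCR/Sp/Se, `p_na`; within-interval size/CCR/Sp/Se, mean class
#'   difference `ui_dm`, significant-t proportion `p_t`; TG-ROC bounds,
#'   Valid Range size/CCR/Sp/Se, Intermediate Range size/CCR/Sp/Se, `tg_dm`,
#'   `tg_p_t`, `p_tg_na`, `p_reversed`.
#' @examples
#' run_model(binormal_model(1), reps = 5, n = 500, seed = 1)
#' @export
run_model <- function(model, reps = 1000, n = 1000, seed = 1,
                      select = 0.55, level = 0.9,
                      intersection = "kde", keep_reps = FALSE) {
  stopifnot(reps >= 1)
  mid <- if (is.na(model$model_id)) 0L else model$model_id
  rows <- vector("list", reps)
  for (r in seq_len(reps)) {
    rep_seed <- seed + mid * 100000 + r
    data <- binormal_sample(model, n, rep_seed)
    rows[[r]] <- simulate_one(data, rep_seed, select, level, intersection, r)
  }
  reps_df <- do.call(rbind, rows)

  found <- reps_df$ui_found
  tg_ok <- !reps_df$tg_na
  mean_if <- function(x, w) if (any(w)) mean(x[w], na.rm = TRUE) else NA_real_
  out <- data.frame(
    model_id = model$model_id, mu1 = model$mu1, sd1 = model$sd1,
    prevalence = model$prevalence, reps = reps, n = n,
    auc = mean(reps_df$auc),
    youden_dt = mean(reps_df$youden_dt), youden_ccr = mean(reps_df$youden_ccr),
    youden_sp = mean(reps_df$youden_sp), youden_se = mean(reps_df$youden_se),
    ui_lower = mean_if(reps_df$ui_lower, found),
    ui_upper = mean_if(reps_df$ui_upper, found),
    mci_size = mean_if(reps_df$mci_size, found),
    mci_ccr = mean_if(reps_df$mci_ccr, found),
    mci_sp = mean_if(reps_df$mci_sp, found),
    mci_se = mean_if(reps_df$mci_se, found),
    p_na = mean(!found),
    ui_size = mean_if(reps_df$ui_size, found),
    ui_ccr = mean_if(reps_df$ui_ccr, found),
    ui_sp = mean_if(reps_df$ui_sp, found),
    ui_se = mean_if(reps_df$ui_se, found),
    ui_dm = mean_if(reps_df$ui_dm, found),
    p_t = mean_if(reps_df$ui_t_sig, found & !is.na(reps_df$ui_t_sig)),
    tg_lower = mean_if(reps_df$tg_lower, tg_ok),
    tg_upper = mean_if(reps_df$tg_upper, tg_ok),
    tg_valid_size = mean_if(reps_df$tg_valid_size, tg_ok),
    tg_valid_ccr = mean_if(reps_df$tg_valid_ccr, tg_ok),
    tg_valid_sp = mean_if(reps_df$tg_valid_sp, tg_ok),
    tg_valid_se = mean_if(reps_df$tg_valid_se, tg_ok),
    tg_int_size = mean_if(reps_df$tg_int_size, tg_ok),
    tg_int_ccr = mean_if(reps_df$tg_int_ccr, tg_ok),
    tg_int_sp = mean_if(reps_df$tg_int_sp, tg_ok),
    tg_int_se = mean_if(reps_df$tg_int_se, tg_ok),
    tg_dm = mean_if(reps_df$tg_dm, tg_ok),
    tg_p_t = mean_if(reps_df$tg_t_sig, tg_ok & !is.na(reps_df$tg_t_sig)),
    p_tg_na = mean(reps_df$tg_na),
    p_reversed = mean_if(reps_df$tg_reversed, tg_ok)
  )
  class(out) <- c("simulation_summary", "data.frame")
  if (keep_reps) attr(out, "replicates") <- reps_df
  out
}

# One replicate: all per-sample quantities as a one-row data.frame.
simulate_one <- function(data, rep_seed, select, level, intersection, r) {
  yj <- optimal_threshold(data, "youden")
  ui <- find_uncertain_interval(data, select = select, intersection = intersection)

  res <- data.frame(
    rep = r, seed = rep_seed,
    auc = empirical_auc(data),
    youden_dt = yj$threshold, youden_ccr = yj$ccr,
    youden_sp = yj$sp, youden_se = yj$se,
    ui_found = ui$found,
    ui_lower = NA_real_, ui_upper = NA_real_,
    mci_size = NA_real_, mci_ccr = NA_real_, mci_sp = NA_real_, mci_se = NA_real_,
    ui_size = NA_real_, ui_ccr = NA_real_, ui_sp = NA_real_, ui_se = NA_real_,
    ui_dm = NA_real_, ui_t_sig = NA,
    youden_in_ui = NA,
    tg_na = TRUE, tg_reversed = NA,
    tg_lower = NA_real_, tg_upper = NA_real_,
    tg_valid_size = NA_real_, tg_valid_ccr = NA_real_,
    tg_valid_sp = NA_real_, tg_valid_se = NA_real_,
    tg_int_size = NA_real_, tg_int_ccr = NA_real_,
    tg_int_sp = NA_real_, tg_int_se = NA_real_,
    tg_dm = NA_real_, tg_t_sig = NA
  )

  if (ui$found) {
    q <- quality_threshold(data, ui$lower, ui$upper)
    res$ui_lower <- ui$lower; res$ui_upper <- ui$upper
    res$mci_size <- q$n_outside
    res$mci_ccr <- q$mci_ccr; res$mci_sp <- q$mci_sp; res$mci_se <- q$mci_se
    res$ui_size <- ui$n_inside
    res$ui_ccr <- ui$ui_ccr; res$ui_sp <- ui$ui_sp; res$ui_se <- ui$ui_se
    wt <- within_range_t(data, ui$lower, ui$upper)
    res$ui_dm <- wt$dm; res$ui_t_sig <- wt$sig
    res$youden_in_ui <- yj$threshold >= ui$lower && yj$threshold <= ui$upper
  }

  tg <- tryCatch(tgroc_thresholds(data, level), error = function(e) NULL)
  if (!is.null(tg)) {
    q <- tg$quality
    res$tg_na <- FALSE
    res$tg_reversed <- tg$reversed
    res$tg_lower <- tg$lower; res$tg_upper <- tg$upper
    res$tg_valid_size <- q$n_outside
    res$tg_valid_ccr <- q$mci_ccr; res$tg_valid_sp <- q$mci_sp
    res$tg_valid_se <- q$mci_se
    res$tg_int_size <- q$n_inside
    ix <- ui$intersection
    if (is.finite(ix) && ix >= tg$lower && ix <= tg$upper) {
      cnt <- ui_counts(data, tg$lower, tg$upper, ix)
      m <- classification_metrics(cnt)
      res$tg_int_ccr <- unname(m["ccr"]); res$tg_int_sp <- unname(m["sp"])
      res$tg_int_se <- unname(m["se"])
    }
    wt <- within_range_t(data, tg$lower, tg$upper)
    res$tg_dm <- wt$dm; res$tg_t_sig <- wt$sig
  }
  res
}

# Welch t-test of the class means inside [lower, upper]; dm = diseased minus
# healthy mean. sig is NA when the test is undefined.
within_range_t <- function(data, lower, upper) {
  inside <- data$score >= lower & data$score <= upper
  x0 <- data$score[inside & data$label == 0L]
  x1 <- data$score[inside & data$label == 1L]
  dm <- if (length(x0) && length(x1)) mean(x1) - mean(x0) else NA_real_
  if (length(x0) >= 2L && length(x1) >= 2L &&
      (stats::var(x0) > 0 || stats::var(x1) > 0)) {
    tt <- welch_t(x0, x1)
    list(dm = dm, sig = tt$p < 0.05)
  } else {
    list(dm = dm, sig = NA)
  }
}

#' Run the full 27-model simulation grid
#'
#' Applies [run_model()] to every row of [binormal_model_grid()] and
#' optionally writes two TSV summaries: one comparing Youden, the More
#' Certain Interval and TG-ROC's Valid Range, and one comparing the Uncertain
#' Interval with TG-ROC's Intermediate Range.
#'
#' @inheritParams run_model
#' @param models Integer vector of model ids (default all 27).
#' @param out_dir If non-NULL, directory where `comparison_outer.tsv` and
#'   `comparison_inner.tsv` are written.
#' @return A data frame with one [run_model()] summary row per model.
#' @export
run_grid <- function(models = 1:27, reps = 1000, n = 1000, seed = 1,
                     select = 0.55, level = 0.9, intersection = "kde",
                     out_dir = NULL) {
  res <- do.call(rbind, lapply(models, function(m) {
    run_model(binormal_model(m), reps = reps, n = n, seed = seed,
              select = select, level = level, intersection = intersection)
  }))
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    outer_cols <- c("model_id", "mu1", "sd1", "prevalence", "auc",
                    "youden_dt", "youden_ccr", "youden_sp", "youden_se",
                    "ui_lower", "ui_upper", "mci_size", "mci_ccr", "mci_sp",
                    "mci_se", "p_na",
                    "tg_lower", "tg_upper", "tg_valid_size", "tg_valid_ccr",
                    "tg_valid_sp", "tg_valid_se")
    inner_cols <- c("model_id", "mu1", "sd1", "prevalence", "auc",
                    "ui_lower", "ui_upper", "ui_size", "ui_ccr", "ui_sp",
                    "ui_se", "ui_dm", "p_t", "p_na",
                    "tg_lower", "tg_upper", "tg_int_size", "tg_int_ccr",
                    "tg_int_sp", "tg_int_se", "tg_dm", "tg_p_t")
    utils::write.table(res[, outer_cols], file.path(out_dir, "comparison_outer.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(res[, inner_cols], file.path(out_dir, "comparison_inner.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  res
}
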