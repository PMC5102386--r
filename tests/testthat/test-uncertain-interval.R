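test_that("ui_counts splits the interval at the intersection (ties to the lower half)", {
  d <- labeled_scores(c(0.1, 0.3, 0.4, 0.5, 0.7, 0.9),
                      c(0, 0, 1, 0, 1, 1))
  cc <- ui_counts(d, 0.3, 0.7, 0.4)
  expect_equal(with(cc, c(tn, fn, fp, tp)), c(1, 1, 1, 1))
  # empty interval
  cc0 <- ui_counts(d, -2, -2, -2)
  expect_equal(with(cc0, tp + fp + tn + fn), 0)
  expect_error(ui_counts(d, 0.5, 0.3, 0.4), "lower")
  expect_error(ui_counts(d, 0.3, 0.7, 0.9), "intersection")
})

test_that("interval search equals the exhaustive brute-force oracle", {
  set.seed(51)
  checked <- 0
  for (i in 1:25) {
    d <- random_dataset(n = 60, k = 18)
    ix <- median(d$score)
    got <- find_uncertain_interval(d, select = 0.55, intersection = ix)
    want <- oracle_ui_search(d$score, d$label, ix, select = 0.55)
    if (is.null(want)) {
      expect_false(got$found)
    } else {
      checked <- checked + 1
      expect_true(got$found)
      expect_equal(got$lower, want$lower)
      expect_equal(got$upper, want$upper)
      expect_equal(got$n_inside, want$count)
    }
  }
  expect_gt(checked, 5)  # the comparison must actually have exercised intervals
})

test_that("every returned interval honors the select constraint and cell floor", {
  set.seed(52)
  for (i in 1:15) {
    sel <- sample(c(0.55, 0.6, 0.7), 1)
    d <- random_dataset(n = 80, k = 20)
    ui <- find_uncertain_interval(d, select = sel, intersection = median(d$score))
    if (!ui$found) next
    expect_lte(ui$ui_se, sel + 1e-12)
    expect_lte(ui$ui_sp, sel + 1e-12)
    expect_true(all(unlist(ui$counts) >= 1))
    expect_true(ui$lower <= ui$intersection && ui$intersection <= ui$upper)
  }
})

test_that("completely inter-mixed classes yield a wide interval with ~0.5 quality", {
  set.seed(53)
  scores <- rep(seq(0, 1, length.out = 50), 2)
  d <- labeled_scores(scores, rep(0:1, each = 50))
  ui <- find_uncertain_interval(d, intersection = 0.5)
  expect_true(ui$found)
  expect_gt(ui$n_inside, 80)          # nearly the whole sample
  expect_lt(abs(ui$ui_se - 0.5), 0.06)
  expect_lt(abs(ui$ui_sp - 0.5), 0.06)
})

test_that("select outside (0.5, 1) is rejected", {
  d <- random_dataset()
  expect_error(find_uncertain_interval(d, select = 0.5), "strictly between")
  expect_error(find_uncertain_interval(d, select = 1), "strictly between")
})

test_that("monotone score transforms leave count-based outputs invariant", {
  set.seed(54)
  for (i in 1:8) {
    d <- random_dataset(n = 70, k = 15)
    ix <- median(d$score)
    trans <- function(x) exp(2 * x) + x   # strictly increasing
    dt <- labeled_scores(trans(d$score), d$label)
    ui <- find_uncertain_interval(d, intersection = ix)
    uit <- find_uncertain_interval(dt, intersection = trans(ix))
    expect_equal(uit$found, ui$found)
    if (ui$found) {
      expect_equal(unclass(uit$counts), unclass(ui$counts))
      expect_equal(uit$lower, trans(ui$lower))
      expect_equal(uit$upper, trans(ui$upper))
      q <- quality_threshold(d, ui$lower, ui$upper)
      qt <- quality_threshold(dt, uit$lower, uit$upper)
      expect_equal(qt$table, q$table)
    }
    # rank-based single thresholds transform along
    y <- optimal_threshold(d, "youden")
    yt <- optimal_threshold(dt, "youden")
    expect_equal(yt$threshold, trans(y$threshold))
    expect_equal(c(yt$se, yt$sp), c(y$se, y$sp))
  }
})

test_that("the maximized Youden threshold falls inside the found interval on binormal samples", {
  s <- run_model(binormal_model(13), reps = 60, n = 1000, seed = 77,
                 keep_reps = TRUE)
  reps <- attr(s, "replicates")
  found <- reps[reps$ui_found, ]
  expect_gt(nrow(found), 40)
  expect_gte(mean(found$youden_in_ui), 0.97)
})
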