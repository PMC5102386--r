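test_that("trichotomous quality on the fixture reproduces its outer-zone metrics", {
  d <- make_clinical_fixture()
  q <- quality_threshold(d, 0.226, 0.632)
  expect_equal(q$mci_ccr, 207 / 237)
  expect_equal(q$mci_se, 83 / 96)
  expect_equal(q$mci_sp, 124 / 141)
  expect_equal(q$n_inside, 143)
  expect_equal(q$n_outside, 237)
})

test_that("degenerate interval reduces to the dichotomous confusion table", {
  set.seed(61)
  for (i in 1:6) {
    d <- random_dataset()
    t <- sample(d$score, 1)
    q <- quality_threshold(d, t, t)
    cc <- confusion_at(d, t)
    expect_equal(sum(q$table["inside", ]), 0)
    expect_equal(unname(q$table["above", ]), c(cc$fp, cc$tp))
    expect_equal(unname(q$table["below", ]), c(cc$tn, cc$fn))
    expect_equal(q$mci_ccr, unname(classification_metrics(cc)["ccr"]))
  }
})

test_that("decision-table margins always conserve the class sizes", {
  set.seed(62)
  for (i in 1:10) {
    d <- random_dataset(n = 55, k = 13)
    b <- sort(sample(d$score, 2))
    q <- quality_threshold(d, b[1], b[2])
    expect_equal(unname(colSums(q$table)),
                 c(sum(d$label == 0), sum(d$label == 1)))
    expect_equal(q$n_inside + q$n_outside, nrow(d))
  }
})

test_that("within-interval report reproduces the fixture's balance tests", {
  d <- make_clinical_fixture()
  ui <- find_uncertain_interval(d, intersection = attr(d, "intersection"))
  # force the documented bounds for the report regardless of search outcome
  ui$lower <- attr(d, "lower"); ui$upper <- attr(d, "upper"); ui$found <- TRUE
  ui$intersection <- attr(d, "intersection")
  rep <- quality_threshold_uncertain(d, ui)
  expect_equal(with(rep$counts, c(tn, fn, fp, tp)), c(47, 26, 39, 31))
  expect_equal(rep$ui_ccr, 78 / 143)
  expect_equal(round(rep$chisq$statistic, 3), 0.788)
  expect_equal(rep$chisq$df, 1L)
  expect_equal(round(rep$chisq$p, 3), 0.375)
  expect_true(rep$tests_defined)
})

test_that("continuity-corrected chi-squared matches hand values and stats::chisq.test", {
  expect_equal(round(chisq_yates(matrix(c(47, 39, 26, 31), 2))$statistic, 3), 0.788)
  expect_equal(chisq_yates(matrix(c(10, 10, 10, 10), 2))$statistic, 0)
  # all expected counts 15; statistic = 4 * 4.5^2 / 15
  expect_equal(chisq_yates(matrix(c(20, 10, 10, 20), 2))$statistic, 5.4)

  set.seed(63)
  for (i in 1:10) {
    tab <- matrix(rpois(4, 20) + 1, 2)
    ref <- suppressWarnings(chisq.test(tab, correct = TRUE))
    got <- chisq_yates(tab)
    expect_equal(got$statistic, unname(ref$statistic))
    expect_equal(got$p, ref$p.value)
  }
  expect_error(chisq_yates(matrix(c(0, 0, 3, 4), 2)), "margins")
  expect_error(chisq_yates(matrix(1:6, 2)), "2x2")
})

test_that("welch_t matches the hand formula and handles degenerate input", {
  res <- welch_t(c(0, 1), c(10, 11))
  expect_equal(res$t, -10 / sqrt(0.5))
  expect_equal(res$df, 2)
  x <- c(1.2, 3.4, 2.2, 0.5)
  same <- welch_t(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  set.seed(64)
  a <- rnorm(15); b <- rnorm(12, 0.8, 2)
  ref <- t.test(a, b)
  got <- welch_t(a, b)
  expect_equal(got$t, unname(ref$statistic))
  expect_equal(got$df, unname(ref$parameter))
  expect_equal(got$p, ref$p.value)
  expect_error(welch_t(1, c(2, 3)), "at least 2")
  expect_error(welch_t(c(1, 1), c(2, 2)), "zero variance")
})

test_that("empty-outer and empty-class cases are flagged, not fatal", {
  d <- labeled_scores(seq(0.1, 0.9, length.out = 10), rep(0:1, 5))
  q <- quality_threshold(d, 0, 1)
  expect_false(q$mci_defined)
  expect_true(is.na(q$mci_ccr))
})
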