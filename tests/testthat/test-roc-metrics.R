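test_that("confusion_at partitions the sample with ties called positive", {
  d <- labeled_scores(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(unclass(confusion_at(d, 3))[c("tp", "fn", "tn", "fp")],
               list(tp = 2L, fn = 0L, tn = 2L, fp = 0L))
  expect_equal(unclass(confusion_at(d, 5))[c("tp", "fn", "tn", "fp")],
               list(tp = 0L, fn = 2L, tn = 2L, fp = 0L))
  d2 <- labeled_scores(c(1, 1, 2, 2), c(0, 1, 0, 1))
  expect_equal(unclass(confusion_at(d2, 2))[c("tp", "fn", "tn", "fp")],
               list(tp = 1L, fn = 1L, tn = 1L, fp = 1L))

  set.seed(21)
  for (i in 1:20) {
    d <- random_dataset()
    t <- sample(d$score, 1)
    got <- confusion_at(d, t)
    want <- oracle_confusion(d$score, d$label, t)
    expect_equal(unclass(got)[names(want)], want)
    expect_equal(with(got, tp + fp + tn + fn), nrow(d))
  }
})

test_that("roc_points has sentinel endpoints and monotone Se/Sp", {
  set.seed(22)
  for (i in 1:10) {
    d <- random_dataset()
    pts <- roc_points(d)
    first <- pts[1, ]; last <- pts[nrow(pts), ]
    expect_equal(c(first$se, first$sp), c(1, 0))
    expect_equal(c(last$se, last$sp), c(0, 1))
    expect_true(all(diff(pts$se) <= 1e-12))
    expect_true(all(diff(pts$sp) >= -1e-12))
  }
  d2 <- labeled_scores(c(1, 1, 2, 2), c(0, 1, 0, 1))
  row <- roc_points(d2)
  expect_equal(unlist(row[row$threshold == 2, c("se", "sp")]),
               c(se = 0.5, sp = 0.5))
  expect_error(roc_points(labeled_scores(1:3, c(1, 1, 1))), "both classes")
})

test_that("empirical_auc matches the pairwise Mann-Whitney oracle and trapezoid area", {
  expect_equal(empirical_auc(labeled_scores(1:4, c(0, 0, 1, 1))), 1)
  expect_equal(empirical_auc(labeled_scores(rep(2, 6), c(0, 0, 0, 1, 1, 1))), 0.5)
  expect_equal(empirical_auc(labeled_scores(c(1, 1, 2, 2), c(0, 1, 0, 1))), 0.5)

  set.seed(23)
  for (i in 1:15) {
    d <- random_dataset()
    auc <- empirical_auc(d)
    expect_equal(auc, oracle_auc(d$score, d$label))
    # trapezoidal area under the ROC curve (handles ties via the midpoints)
    pts <- roc_points(d)
    fpr <- 1 - pts$sp
    trap <- -sum(diff(fpr) * (pts$se[-1] + pts$se[-nrow(pts)]) / 2)
    expect_equal(auc, trap)
    # label swap symmetry
    swapped <- labeled_scores(d$score, 1L - d$label)
    expect_equal(empirical_auc(swapped), 1 - auc)
  }
})

test_that("empirical_auc agrees with pROC on tied data", {
  skip_if_not_installed("pROC")
  set.seed(24)
  d <- random_dataset(n = 200, k = 15)
  ref <- as.numeric(pROC::auc(d$label, d$score, direction = "<", quiet = TRUE))
  expect_equal(empirical_auc(d), ref)
})

test_that("binormal_auc matches the analytic normal-pair formula", {
  expect_equal(binormal_auc(binormal_model(1)), pnorm(3 / sqrt(1 + 0.36)))
  expect_equal(round(binormal_auc(binormal_model(1)), 3), 0.995)
  expect_equal(binormal_auc(binormal_model(27)), 0.711, tolerance = 0.001)
  expect_equal(binormal_auc(binormal_model(mu1 = 0, sd1 = 1, prevalence = 0.5)), 0.5)
  expect_error(binormal_auc(list(mu0 = 0, sd0 = 1, mu1 = 1, sd1 = -1)), "positive")
})

test_that("sampled empirical AUC is within Monte-Carlo error of the analytic AUC", {
  m <- binormal_model(mu1 = 1.5, sd1 = 1, prevalence = 0.5)
  target <- binormal_auc(m)
  aucs <- vapply(1:40, function(r) {
    empirical_auc(binormal_sample(m, 1000, 900 + r))
  }, numeric(1))
  se <- sd(aucs) / sqrt(length(aucs))
  expect_lt(abs(mean(aucs) - target), 3 * se + 1e-4)
})
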