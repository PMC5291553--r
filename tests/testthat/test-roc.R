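test_that("pair-counting AUC matches worked examples and symmetry", {
  lab <- c(FALSE, FALSE, TRUE, TRUE)
  expect_equal(roc_auc(c(1, 2, 3, 4), lab)$auc, 1)
  # controls {1,2,3} vs cases {2,3,4}: 7 of 9 pairs (ties at 1/2)
  r <- roc_auc(c(1, 2, 3, 2, 3, 4), rep(c(FALSE, TRUE), each = 3))
  expect_equal(r$auc, 7 / 9, tolerance = 1e-12)
  expect_identical(r$orientation, "higher")
  # label swap flips the raw AUC; orientation reporting keeps it >= 0.5
  rs <- roc_auc(c(1, 2, 3, 2, 3, 4), rep(c(TRUE, FALSE), each = 3))
  expect_equal(rs$auc, 7 / 9, tolerance = 1e-12)
  expect_identical(rs$orientation, "lower")
  expect_error(roc_auc(1:4, rep(TRUE, 4)), "Both classes")
})

test_that("AUC estimator equals brute-force pair counting on 1000 random draws", {
  set.seed(77)
  for (i in 1:1000) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    scores <- sample(1:6, n1 + n2, replace = TRUE) +
      sample(c(0, 0.5), n1 + n2, replace = TRUE)
    labels <- c(rep(TRUE, n1), rep(FALSE, n2))
    expect_equal(auc_pair_count <- roc_auc(scores, labels)$auc,
                 max(brute_auc(scores, labels),
                     1 - brute_auc(scores, labels)),
                 tolerance = 1e-12)
  }
})

test_that("AUC and CI agree with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  scores <- c(rnorm(15, 1), rnorm(20))
  labels <- rep(c(TRUE, FALSE), c(15, 20))
  ours <- roc_auc(scores, labels)
  ref <- pROC::roc(response = labels, predictor = scores, quiet = TRUE,
                   direction = "auto")
  expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
})

test_that("Youden cutoff is never beaten by a brute-force threshold scan", {
  # clean separation: cutoff between the groups, J = 1
  res <- youden_cutoff(c(1, 2, 3, 4, 5, 6),
                       rep(c(FALSE, TRUE), each = 3), "higher")
  expect_equal(res$cutoff, 3.5)
  expect_equal(res$youden_j, 1)
  # identical overlapping sets: J = 0 with sens + spec = 1
  res0 <- youden_cutoff(c(1, 2, 3, 1, 2, 3),
                        rep(c(FALSE, TRUE), each = 3), "higher")
  expect_equal(res0$youden_j, 0, tolerance = 1e-12)
  expect_equal(res0$sensitivity + res0$specificity, 1, tolerance = 1e-12)
  # oracle property over random instances
  set.seed(99)
  for (i in 1:200) {
    n1 <- sample(3:9, 1); n2 <- sample(3:9, 1)
    scores <- round(rnorm(n1 + n2), 1)
    labels <- c(rep(TRUE, n1), rep(FALSE, n2))
    for (orient in c("higher", "lower")) {
      got <- youden_cutoff(scores, labels, orient)
      expect_equal(got$youden_j, brute_best_youden(scores, labels, orient),
                   tolerance = 1e-12)
    }
  }
})

test_that("diagnostic metrics reproduce exact binomial intervals", {
  # 9 of 9 positives detected: sens 100%, exact lower bound 0.025^(1/9)
  m <- diagnostic_metrics(tp = 9, fp = 5, tn = 14, fn = 0)
  sens <- m[m$metric == "sensitivity", ]
  expect_equal(sens$estimate_pct, 100)
  expect_equal(sens$ci_lo_pct, 100 * 0.025^(1 / 9), tolerance = 1e-9)
  expect_equal(round(sens$ci_lo_pct, 1), 66.4)
  # 14 of 19 negatives correct: spec 73.7%, CI (48.8, 90.9)
  spec <- m[m$metric == "specificity", ]
  expect_equal(round(spec$estimate_pct, 1), 73.7)
  expect_equal(round(spec$ci_lo_pct, 1), 48.8)
  expect_equal(round(spec$ci_hi_pct, 1), 90.9)
  # 0 of 1: CI (0, 97.5)
  m01 <- diagnostic_metrics(tp = 0, fp = 0, tn = 1, fn = 1)
  s01 <- m01[m01$metric == "sensitivity", ]
  expect_equal(s01$estimate_pct, 0)
  expect_equal(s01$ci_lo_pct, 0)
  expect_equal(s01$ci_hi_pct, 97.5, tolerance = 1e-6)
  # intervals always contain the estimate within [0, 100]
  set.seed(3)
  for (i in 1:50) {
    cts <- sample(0:12, 4, replace = TRUE)
    mm <- diagnostic_metrics(cts[1], cts[2], cts[3], cts[4])
    ok <- mm[mm$defined, ]
    expect_true(all(ok$ci_lo_pct <= ok$estimate_pct + 1e-9))
    expect_true(all(ok$ci_hi_pct >= ok$estimate_pct - 1e-9))
    expect_true(all(ok$ci_lo_pct >= 0 & ok$ci_hi_pct <= 100))
  }
  # undefined metric is flagged, not fabricated
  und <- diagnostic_metrics(tp = 0, fp = 0, tn = 3, fn = 0)
  expect_false(und$defined[und$metric == "ppv"])
  expect_error(diagnostic_metrics(-1, 0, 0, 0), "non-negative")
})

test_that("Hanley-McNeil SE and z-test match hand evaluation", {
  # A = 0.5, n = 5/5: SE = sqrt(0.9167 / 25)
  h <- hanley_mcneil_test(0.5, 0.5, 5, 5, r = 0)
  expect_equal(h$z, 0)
  expect_equal(h$p_value, 1)
  se <- sqrt((0.5 * 0.5 + 4 * (0.5 / 1.5 - 0.25) * 2) / 25)
  expect_equal(se, 0.1915, tolerance = 1e-3)
  # r = 0 reduces to the independent-sample denominator
  h2 <- hanley_mcneil_test(0.9, 0.7, 9, 19, r = 0)
  se1 <- sqrt((0.9 * 0.1 + 8 * (0.9 / 1.1 - 0.81) +
                 18 * (2 * 0.81 / 1.9 - 0.81)) / (9 * 19))
  se2 <- sqrt((0.7 * 0.3 + 8 * (0.7 / 1.3 - 0.49) +
                 18 * (2 * 0.49 / 1.7 - 0.49)) / (9 * 19))
  expect_equal(h2$z, 0.2 / sqrt(se1^2 + se2^2), tolerance = 1e-12)
  expect_error(hanley_mcneil_test(0.9, 0.7, 9, 19, r = 1), "r")
  # paired correlation helper stays in [0, 0.99]
  set.seed(8)
  s1 <- rnorm(30); s2 <- s1 + rnorm(30, sd = 0.3)
  lab <- rep(c(TRUE, FALSE), 15)
  r <- auc_correlation(s1, s2, lab)
  expect_true(r >= 0 && r <= 0.99)
  expect_gt(r, 0.5)
})

test_that("roc_analysis bundles AUC, cutoff and metrics coherently", {
  set.seed(21)
  scores <- c(rnorm(9, 2), rnorm(19, 0))
  labels <- rep(c(TRUE, FALSE), c(9, 19))
  ra <- roc_analysis(scores, labels, marker = "demo")
  gl <- glance(ra)
  expect_equal(gl$auc, roc_auc(scores, labels)$auc)
  expect_equal(gl$sensitivity + gl$specificity - 1, gl$youden_j,
               tolerance = 1e-12)
  expect_identical(nrow(tidy(ra)), 4L)
  expect_s3_class(autoplot(ra), "ggplot")
})
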