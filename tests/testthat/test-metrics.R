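test_that("confusion counts match a per-element tally oracle", {
  cm <- confusion(rep(TRUE, 10), c(rep(TRUE, 6), rep(FALSE, 4)))
  expect_identical(c(cm$tp, cm$fp, cm$fn, cm$tn), c(6L, 4L, 0L, 0L))
  cm2 <- confusion(c(rep(TRUE, 7), rep(FALSE, 3)),
                   c(rep(TRUE, 7), rep(FALSE, 3)))
  expect_identical(c(cm2$tp, cm2$fp, cm2$fn, cm2$tn), c(7L, 0L, 0L, 3L))
  set.seed(1)
  for (rep in 1:10) {
    p <- runif(20) < 0.5
    o <- runif(20) < 0.5
    cm3 <- confusion(p, o)
    tally <- table(factor(p, c(FALSE, TRUE)), factor(o, c(FALSE, TRUE)))
    expect_identical(cm3$tp, unname(tally["TRUE", "TRUE"]))
    expect_identical(cm3$fp, unname(tally["TRUE", "FALSE"]))
    expect_identical(cm3$fn, unname(tally["FALSE", "TRUE"]))
    expect_identical(cm3$tn, unname(tally["FALSE", "FALSE"]))
  }
  expect_error(confusion(logical(0), logical(0)), "empty")
  expect_error(confusion(c(TRUE, FALSE), TRUE), "length")
})

test_that("panel point estimates follow the 2x2 arithmetic", {
  cm <- confusion_counts(tp = 263, fp = 27, fn = 73, tn = 93)
  pan <- diagnostic_panel(cm)
  expect_equal(pan$sens, 263 / 336, tolerance = 1e-12)
  expect_equal(round(pan$sens, 3), 0.783)
  expect_equal(round(pan$spec, 3), 0.775)
  expect_equal(pan$ppv, 263 / 290, tolerance = 1e-12)
  expect_equal(pan$npv, 93 / 166, tolerance = 1e-12)
  expect_identical(pan$n_evaluated, 456L)
})

test_that("panel entries satisfy the LR and Bayes identities to 1e-12", {
  set.seed(3)
  for (rep in 1:20) {
    cm <- confusion_counts(tp = sample(5:200, 1), fp = sample(5:200, 1),
                           fn = sample(5:200, 1), tn = sample(5:200, 1))
    pan <- diagnostic_panel(cm)
    lrs <- lr_from_sens_spec(pan$sens, pan$spec)
    expect_equal(pan$lr_pos, unname(lrs["lr_pos"]), tolerance = 1e-12)
    expect_equal(pan$lr_neg, unname(lrs["lr_neg"]), tolerance = 1e-12)
    prev <- (cm$tp + cm$fn) / pan$n_evaluated
    pv <- ppv_npv_from_sens_spec_prev(pan$sens, pan$spec, prev)
    expect_equal(pan$ppv, unname(pv["ppv"]), tolerance = 1e-12)
    expect_equal(pan$npv, unname(pv["npv"]), tolerance = 1e-12)
  }
})

test_that("published-panel identities: LR+, LR-, PPV and NPV recompute from sens/spec", {
  expect_equal(round(unname(lr_from_sens_spec(0.679, 0.787)["lr_pos"]), 2),
               3.19)
  expect_equal(round(unname(lr_from_sens_spec(0.843, 0.393)["lr_neg"]), 2),
               0.40)
  prev <- 336 / 463
  expect_equal(
    round(100 * unname(
      ppv_npv_from_sens_spec_prev(0.679, 0.787, prev)["ppv"]), 1), 89.4)
  # the published 62.7 was computed before its inputs were rounded; the
  # identity on the printed sens/spec lands within one print-ulp of it
  expect_equal(
    100 * unname(ppv_npv_from_sens_spec_prev(0.804, 0.874, prev)["npv"]),
    62.7, tolerance = 0.0015)
  # degenerate and uninformative cases
  expect_equal(unname(lr_from_sens_spec(0.5, 0.5)), c(1, 1))
  expect_true(all(ppv_npv_from_sens_spec_prev(1, 1, 0.3) == 1))
  expect_true(all(is.na(ppv_npv_from_sens_spec_prev(0.8, 0.9, 0))))
  expect_true(is.na(lr_from_sens_spec(0.8, 1)["lr_pos"]))
})

test_that("Wilson intervals agree with prop.test, contain the estimate, and tighten with n", {
  ks <- c(5, 50, 263); ns <- c(10, 80, 336)
  for (i in seq_along(ks)) {
    ci <- appendiscore:::wilson_ci(ks[i], ns[i])
    ref <- prop.test(ks[i], ns[i], correct = FALSE)$conf.int
    expect_equal(ci, as.numeric(ref), tolerance = 1e-10)
    expect_true(ci[1] <= ks[i] / ns[i] && ks[i] / ns[i] <= ci[2])
    expect_true(ci[1] >= 0 && ci[2] <= 1)
  }
  widths <- vapply(c(20, 80, 320, 1280), function(n) {
    diff(appendiscore:::wilson_ci(round(0.7 * n), n))
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("zero denominators surface as NA statistics, never as zero", {
  cm <- confusion_counts(tp = 10, fp = 0, fn = 5, tn = 8)
  pan <- diagnostic_panel(cm)
  expect_equal(pan$spec, 1)
  expect_true(is.na(pan$lr_pos))
  expect_error(diagnostic_panel(confusion_counts(0, 5, 0, 5)),
               "condition classes")
})

test_that("ROC-AUC handles separation, ties, monotone transforms and matches pROC", {
  y <- c(rep(TRUE, 5), rep(FALSE, 5))
  expect_equal(roc_auc(c(6:10, 1:5), y), 1.0)     # perfect separation
  expect_equal(roc_auc(rep(3, 10), y), 0.5)       # all ties, half credit
  set.seed(11)
  totals <- sample(0:10, 60, replace = TRUE)
  labs <- runif(60) < 0.5
  a <- roc_auc(totals, labs)
  expect_equal(roc_auc(totals^3 + 2, labs), a, tolerance = 1e-12)
  expect_equal(roc_auc(exp(totals / 4), labs), a, tolerance = 1e-12)
  ref <- as.numeric(pROC::auc(pROC::roc(labs, totals, quiet = TRUE,
                                        direction = "<")))
  expect_equal(a, ref, tolerance = 1e-12)
  # label-independent scores hover near 0.5
  aucs <- vapply(1:20, function(s) {
    set.seed(s)
    roc_auc(sample(0:10, 400, replace = TRUE), runif(400) < 0.5)
  }, numeric(1))
  expect_lt(max(abs(aucs - 0.5)), 0.12)
  expect_equal(two_point_auc(0.8, 0.6), 0.7)
})

test_that("DeLong AUC interval matches pROC's", {
  set.seed(21)
  totals <- sample(0:15, 120, replace = TRUE) +
    3 * (runif(120) < 0.5)
  labs <- totals + rnorm(120) > 9
  ci <- appendiscore:::delong_auc_ci(totals, labs)
  ref <- suppressWarnings(as.numeric(pROC::ci.auc(
    pROC::roc(labs, totals, quiet = TRUE, direction = "<"),
    method = "delong")))
  expect_equal(ci, ref[c(1, 3)], tolerance = 1e-6)
})

test_that("bootstrap CIs are seeded-deterministic and bracket the estimate", {
  set.seed(5)
  o <- runif(300) < 0.6
  totals <- rbinom(300, 8, ifelse(o, 0.7, 0.4))
  pred <- totals >= 5
  cm <- confusion(pred, o)
  b1 <- diagnostic_panel(cm, totals, o, ci = "bootstrap", predictions = pred,
                         boot = 400, seed = 99)
  b2 <- diagnostic_panel(cm, totals, o, ci = "bootstrap", predictions = pred,
                         boot = 400, seed = 99)
  expect_identical(b1, b2)
  for (s in c("sens", "spec", "ppv", "npv", "auc")) {
    expect_lte(b1[[paste0(s, "_lo")]], b1[[s]])
    expect_gte(b1[[paste0(s, "_hi")]], b1[[s]])
  }
})

test_that("missed-case counterfactual reproduces the published counts", {
  expect_equal(unname(missed_cases(0.402, 102)),
               c(61, 61 / 102))               # 59.8%
  expect_equal(round(100 * missed_cases(0.402, 102)[["missed_fraction"]], 1),
               59.8)
  expect_equal(unname(missed_cases(0.980, 102)), c(2, 2 / 102))  # 2.0%
  expect_equal(unname(missed_cases(1, 50)), c(0, 0))
  expect_true(is.na(missed_cases(0.5, 0)[["missed_fraction"]]))
})

test_that("feature-row inversion reproduces implied cells and flags inconsistent rows", {
  nausea <- invert_feature_row(319, 463, 0.815, 0.453, 336)
  expect_identical(c(nausea$tp, nausea$fn), c(260L, 79L))
  expect_identical(nausea$consistency_gap, 3L)

  rebound <- invert_feature_row(293, 463, 0.897, 0.365, 336)
  expect_identical(rebound$consistency_gap, 35L)

  # a row constructed from an exact 2x2 is perfectly consistent
  tp <- 80L; fp <- 20L; fn <- 30L; tn <- 70L
  fr <- invert_feature_row(tp + fp, tp + fp + fn + tn,
                           ppv = tp / (tp + fp), npv = tn / (tn + fn),
                           reported_cases = tp + fn)
  expect_identical(fr$consistency_gap, 0L)
  expect_identical(c(fr$tp, fr$fp, fr$fn, fr$tn), c(tp, fp, fn, tn))
})

test_that("inversion followed by the panel returns the input PPV/NPV within rounding", {
  set.seed(8)
  for (rep in 1:20) {
    present <- sample(30:300, 1); total <- present + sample(30:300, 1)
    ppv <- runif(1, 0.2, 0.95); npv <- runif(1, 0.2, 0.95)
    fr <- invert_feature_row(present, total, ppv, npv, reported_cases = 1)
    pan <- diagnostic_panel(confusion_counts(fr$tp, fr$fp, fr$fn, fr$tn))
    expect_lte(abs(pan$ppv - ppv), 1 / (2 * present) + 1e-12)
    expect_lte(abs(pan$npv - npv), 1 / (2 * (total - present)) + 1e-12)
  }
})
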