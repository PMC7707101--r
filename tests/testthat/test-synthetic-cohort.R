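test_that("calibration inverts published rows into class-conditional probabilities", {
  cal <- calibrate_feature_probs()
  probs <- cal$probs
  rownames(probs) <- probs$feature
  # consistent row used as-is: nausea implies 260 of 336 cases
  expect_equal(probs["nausea_vomiting", "p_case"], 260 / 336,
               tolerance = 1e-12)
  expect_false(cal$report$adjusted[cal$report$feature == "nausea_vomiting"])
  # rebound row is internally inconsistent (implies ~371 cases): flagged and
  # renormalized onto the case margin
  reb <- cal$report[cal$report$feature == "rebound_tenderness", ]
  expect_true(reb$adjusted)
  expect_identical(reb$gap, 35L)
  expect_equal(probs["rebound_tenderness", "p_case"],
               263 * (336 / 371) / 336, tolerance = 1e-12)
  # a feature absent in the whole cohort gets probability zero
  expect_equal(unlist(probs["migration_of_pain", c("p_case", "p_noncase")]),
               c(p_case = 0, p_noncase = 0))
  expect_true(all(probs$p_case >= 0 & probs$p_case <= 1))
  expect_true(all(probs$p_noncase >= 0 & probs$p_noncase <= 1))
})

test_that("a row built from an exact 2x2 is recovered exactly with no flags", {
  tp <- 120L; fp <- 15L; fn <- 40L; tn <- 80L
  row <- data.frame(feature = "synthetic", present = tp + fp,
                    total = tp + fp + fn + tn, ppv = tp / (tp + fp),
                    npv = tn / (tn + fn))
  cal <- calibrate_feature_probs(row, case_total = tp + fn,
                                 noncase_total = fp + tn)
  expect_false(cal$report$adjusted)
  expect_equal(cal$probs$p_case, tp / (tp + fn), tolerance = 1e-12)
  expect_equal(cal$probs$p_noncase, fp / (fp + tn), tolerance = 1e-12)
})

test_that("generation is bit-identical under a fixed seed", {
  params <- cohort_parameters(n_total = 200, seed = 123)
  expect_identical(generate_cohort(params), generate_cohort(params))
  # and differs for another seed
  other <- generate_cohort(cohort_parameters(n_total = 200, seed = 124))
  expect_false(identical(generate_cohort(params), other))
})

test_that("class mix matches the published 336/463 appendicitis share within binomial noise", {
  counts <- vapply(1:20, function(s) {
    cohort <- generate_cohort(cohort_parameters(seed = s))
    sum(cohort$outcome != "no_appendicitis")
  }, numeric(1))
  sd3 <- 3 * sqrt(463 * (336 / 463) * (127 / 463))
  expect_true(all(abs(counts - 336) <= sd3))
})

test_that("large-sample feature frequencies converge to the calibrated probabilities", {
  params <- cohort_parameters(n_total = 1e5, seed = 77)
  cohort <- generate_cohort(params)
  fv <- derive_features(cohort)
  case <- cohort$outcome != "no_appendicitis"
  p_us <- mean(fv$us_appendicitis[case], na.rm = TRUE)
  expect_lt(abs(p_us - params$feature_probs["us_appendicitis", "simple"]),
            0.01)
  p_crp <- mean(fv$crp_high[!case], na.rm = TRUE)
  expect_lt(abs(p_crp -
                  params$feature_probs["crp_high", "no_appendicitis"]), 0.01)
})

test_that("structural invariants: age range, durations, joint lab/US missingness", {
  cohort <- generate_cohort(cohort_parameters(n_total = 5000, seed = 31))
  expect_true(all(cohort$age > 1 & cohort$age < 17))
  expect_true(all(cohort$duration_h >= 0))
  lab_cols <- c("wbc", "neutrophils_abs", "neutrophils_pct", "crp",
                "us_appendicitis")
  miss <- is.na(cohort[lab_cols])
  # block missingness: each row all-missing or all-present
  expect_true(all(rowSums(miss) %in% c(0L, length(lab_cols))))
  # clinical findings are always recorded
  expect_false(anyNA(cohort$tenderness_rlq))
  expect_false(anyNA(cohort$nausea_vomiting))
  expect_false(anyNA(cohort$temperature_c))
  # continuous labs sit on the side of the cutoff their indicator says
  fv <- derive_features(cohort)
  ok <- !is.na(cohort$wbc)
  expect_identical(fv$wbc_high[ok], as.integer(cohort$wbc[ok] > 11))
})

test_that("per-class parameters are recovered from n = 10^4 cohorts (>=90% CI coverage over 20 seeds)", {
  params <- cohort_parameters(n_total = 1e4)
  hits <- 0L; tries <- 0L
  for (s in 1:20) {
    params$seed <- s
    cohort <- generate_cohort(params)
    fv <- derive_features(cohort)
    for (cl in colnames(params$feature_probs)) {
      sel <- cohort$outcome == cl
      for (f in rownames(params$feature_probs)) {
        x <- fv[[f]][sel]
        x <- x[!is.na(x)]
        ci <- appendiscore:::wilson_ci(sum(x), length(x))
        tries <- tries + 1L
        p_true <- params$feature_probs[f, cl]
        if (p_true >= ci[1] && p_true <= ci[2]) hits <- hits + 1L
      }
    }
  }
  expect_gte(hits / tries, 0.9)
})

test_that("cohort summaries mirror hand counts and the published moments", {
  h1 <- patient_with_features(c(tenderness_rlq = 1L), id = "a",
                              outcome = "simple")
  h2 <- patient_with_features(c(tenderness_rlq = 1L, us_appendicitis = 1L),
                              id = "b", outcome = "perforated")
  h3 <- patient_with_features(c(nausea_vomiting = 1L), id = "c",
                              outcome = "no_appendicitis")
  s <- summarize_cohort(rbind(h1, h2, h3))
  expect_equal(s$classes$n, c(1, 1, 1))
  expect_equal(s$features["tenderness_rlq", "simple"], 1)
  expect_equal(s$features["tenderness_rlq", "no_appendicitis"], 0)
  expect_equal(s$features["us_appendicitis", "perforated"], 1)

  # single-class cohort: other class rows have zero counts
  s1 <- summarize_cohort(rbind(h1, h1))
  expect_equal(s1$classes$n[s1$classes$class == "perforated"], 0)

  # a default-size generated cohort sits near the published mean age
  big <- generate_cohort(cohort_parameters(seed = 2))
  sb <- summarize_cohort(big)
  mean_age <- sum(sb$classes$n * sb$classes$age_mean) / sum(sb$classes$n)
  expect_lt(abs(mean_age - 10.9), 0.6)
  # simple appendicitis durations shorter than perforated on average
  d <- setNames(sb$classes$duration_mean_h, sb$classes$class)
  expect_lt(d["simple"], d["perforated"])
})

test_that("invalid parameters are rejected", {
  expect_error(cohort_parameters(class_probs = c(no_appendicitis = 0.5,
                                                 simple = 0.4,
                                                 perforated = 0.2)),
               "sum to 1")
  expect_error(cohort_parameters(missing_prob = 1.5), "missing_prob")
  bad <- default_feature_probs(); bad[1, 1] <- 2
  expect_error(cohort_parameters(feature_probs = bad), "feature_probs")
})
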