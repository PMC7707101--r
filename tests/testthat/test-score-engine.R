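test_that("threshold comparisons are strict and honour both neutrophilia branches", {
  p <- blank_patient(wbc = 11.5, crp = 20.0, neutrophils_pct = 80,
                     neutrophils_abs = 5.0)
  fv <- derive_features(p)
  expect_identical(fv$wbc_high, 1L)       # 11.5 > 11
  expect_identical(fv$crp_high, 0L)       # 20 is not > 20
  expect_identical(fv$neutrophilia, 1L)   # percentage branch of the OR

  # boundary: exactly at every cutoff is negative
  q <- blank_patient(wbc = 11, crp = 20, temperature_c = 38.5,
                     neutrophils_abs = 7.9, neutrophils_pct = 75)
  fq <- derive_features(q)
  expect_identical(unname(unlist(fq[c("wbc_high", "crp_high", "fever",
                                      "neutrophilia")])),
                   rep(0L, 4))
})

test_that("missing raw values yield NA indicators, never silent zeros", {
  p <- blank_patient(wbc = NA, us_appendicitis = NA,
                     neutrophils_abs = NA, neutrophils_pct = NA)
  fv <- derive_features(p)
  expect_true(is.na(fv$wbc_high))
  expect_true(is.na(fv$us_appendicitis))
  expect_true(is.na(fv$neutrophilia))
  expect_false(fv$complete)
  # one recorded neutrophil branch below cutoff is enough to call it 0
  q <- blank_patient(neutrophils_abs = NA, neutrophils_pct = 60)
  expect_identical(derive_features(q)$neutrophilia, 0L)
  # ...and one recorded branch above cutoff dominates a missing one
  r <- blank_patient(neutrophils_abs = 9.5, neutrophils_pct = NA)
  expect_identical(derive_features(r)$neutrophilia, 1L)
})

test_that("built-in definitions carry the published weights and cutoffs", {
  defs <- builtin_scores()
  expect_named(defs, c("alvarado", "pas", "tzanakis", "has", "mhas", "ai"))
  expect_equal(defs$alvarado$items,
               c(tenderness_rlq = 2L, rebound_tenderness = 1L,
                 wbc_high = 2L, nausea_vomiting = 1L, anorexia = 1L,
                 migration_of_pain = 1L, fever = 1L, neutrophilia = 1L))
  cut_max <- t(vapply(defs, function(d) c(d$positivity_cutoff, d$max_score),
                      integer(2)))
  expect_equal(unname(cut_max),
               matrix(c(5L, 10L, 6L, 10L, 8L, 15L, 3L, 4L, 3L, 5L, 2L, 4L),
                      ncol = 2, byrow = TRUE))
  for (d in defs) expect_identical(d$max_score, sum(d$items))
})

test_that("worked examples: Tzanakis 13 with tenderness+rebound+US; empty patient scores 0 everywhere", {
  p <- patient_with_features(c(tenderness_rlq = 1L, rebound_tenderness = 1L,
                               us_appendicitis = 1L))
  r <- compute_score(p, builtin_scores("tzanakis")[[1]])
  expect_identical(r$total, 13L)  # 4 + 3 + 6
  expect_true(r$positive)
  empty <- blank_patient()
  for (d in builtin_scores()) {
    r0 <- compute_score(empty, d)
    expect_identical(r0$total, 0L)
    expect_false(r0$positive)
  }
})

test_that("every built-in score matches a brute-force dot-product oracle over all item combinations", {
  for (d in builtin_scores()) {
    k <- length(d$items)
    combos <- as.matrix(expand.grid(rep(list(0:1), k)))
    colnames(combos) <- names(d$items)
    positives <- 0L
    for (i in seq_len(nrow(combos))) {
      ind <- combos[i, ]
      p <- patient_with_features(ind)
      r <- compute_score(p, d)
      oracle_total <- sum(d$items * ind)
      expect_identical(r$total, as.integer(oracle_total))
      expect_identical(r$positive, oracle_total >= d$positivity_cutoff)
      positives <- positives + as.integer(r$positive)
    }
    if (d$name == "mhas") {
      # 5 unit items, cutoff 3: choose(5,3)+choose(5,4)+choose(5,5) = 16
      expect_identical(positives, 16L)
    }
  }
})

test_that("flipping any single item 0 -> 1 never decreases any score total", {
  set.seed(42)
  defs <- builtin_scores()
  for (rep in 1:25) {
    ind <- setNames(rbinom(length(score_features), 1, 0.5), score_features)
    base <- patient_with_features(ind)
    for (f in score_features[ind == 0]) {
      ind2 <- ind; ind2[f] <- 1L
      flipped <- patient_with_features(ind2)
      for (d in defs) {
        expect_gte(compute_score(flipped, d)$total,
                   compute_score(base, d)$total)
      }
    }
  }
})

test_that("AI positivity implies a modified-HAS total at least as large", {
  defs <- builtin_scores(c("mhas", "ai"))
  set.seed(7)
  for (rep in 1:50) {
    ind <- setNames(rbinom(length(score_features), 1, 0.5), score_features)
    p <- patient_with_features(ind)
    ai <- compute_score(p, defs$ai)
    mhas <- compute_score(p, defs$mhas)
    expect_gte(mhas$total, ai$total)  # AI items are a subset of mHAS items
  }
})

test_that("score definitions round-trip through JSON bit-exactly", {
  defs <- builtin_scores()
  path <- tempfile(fileext = ".json")
  write_score_definitions(defs, path)
  back <- read_score_definitions(path)
  expect_identical(back, defs)
})

test_that("definition validation rejects unknown items and bad cutoffs", {
  expect_error(score_definition("x", c(not_a_feature = 1), 1),
               "unknown feature")
  expect_error(score_definition("x", c(wbc_high = 1), 2), "positivity_cutoff")
  expect_error(score_definition("x", c(wbc_high = 0L), 1), "weights")
})

test_that("apply_scores excludes lab/US-incomplete patients and reconciles counts", {
  complete <- lapply(1:4, function(i) {
    patient_with_features(c(tenderness_rlq = 1L), id = paste0("c", i),
                          outcome = "simple")
  })
  incomplete <- lapply(1:2, function(i) {
    blank_patient(id = paste0("m", i), wbc = NA, crp = NA,
                  neutrophils_abs = NA, neutrophils_pct = NA,
                  us_appendicitis = NA, outcome = "no_appendicitis")
  })
  cohort <- do.call(rbind, c(complete, incomplete))
  sm <- apply_scores(cohort)
  expect_identical(sm$n_evaluated, 4L)
  expect_identical(sm$n_excluded, 2L)
  expect_identical(sm$n_evaluated + sm$n_excluded, nrow(cohort))
  expect_setequal(sm$excluded$id, c("m1", "m2"))
  expect_match(sm$excluded$missing_items[1], "wbc_high")

  # error mode raises on the first incomplete patient
  expect_error(apply_scores(cohort, exclusion = "error"), "m1")

  # degenerate: everyone incomplete
  all_bad <- do.call(rbind, incomplete)
  sm0 <- apply_scores(all_bad)
  expect_identical(sm0$n_evaluated, 0L)
  expect_identical(nrow(sm0$excluded), 2L)

  # single complete patient: evaluated, empty log
  sm1 <- apply_scores(complete[[1]])
  expect_identical(sm1$n_evaluated, 1L)
  expect_identical(nrow(sm1$excluded), 0L)
})

test_that("a generated 463-patient cohort reproduces the 456-complete pattern on average", {
  evaluated <- vapply(1:10, function(s) {
    cohort <- generate_cohort(cohort_parameters(seed = s))
    apply_scores(cohort)$n_evaluated
  }, numeric(1))
  # binomial(463, 7/463): mean 456 complete, SD ~ 2.6
  expect_true(all(abs((463 - evaluated) - 7) <= 3 * sqrt(7 * (1 - 7 / 463))))
})

test_that("cohort CSV round-trips through the documented dialect", {
  cohort <- generate_cohort(cohort_parameters(n_total = 40, seed = 9))
  path <- tempfile(fileext = ".csv")
  write_cohort_csv(cohort, path)
  back <- read_cohort_csv(path)
  expect_equal(back$id, cohort$id)
  expect_equal(back$wbc, cohort$wbc, tolerance = 1e-12)
  expect_identical(back$us_appendicitis, cohort$us_appendicitis)
  expect_identical(back$outcome, cohort$outcome)
})
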