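#' Calibrate per-class feature probabilities from published feature rows
#'
#' Inverts each feature's (present, PPV, NPV) row into an implied 2x2 table
#' (see [invert_feature_row()]) and converts it into class-conditional
#' Bernoulli probabilities `P(feature | case) = tp / case_total` and
#' `P(feature | non-case) = fp / noncase_total`. Rows whose implied case
#' count disagrees with the reported case margin by more than `tolerance`
#' are flagged and renormalized: the gap is distributed proportionally over
#' TP and FN (both scaled by `case_total / implied_cases`), FP recovered by
#' subtraction from the fixed `present` margin. Every adjustment is listed
#' in the consistency report; nothing is silently corrected. A feature with
#' `present = 0` gets probability 0 in every class.
#'
#' @param rows `data.frame` with columns `feature`, `present`, `total`,
#'   `ppv`, `npv` (defaults to the published rows,
#'   [reported_feature_rows()]).
#' @param case_total,noncase_total Reported condition-positive and -negative
#'   margins (defaults 336 and 127).
#' @param tolerance Maximum tolerated `consistency_gap` before a row is
#'   renormalized (default 5 patients).
#' @return A list with
#'   \describe{
#'     \item{probs}{`data.frame`: `feature`, `p_case`, `p_noncase`.}
#'     \item{report}{`data.frame`: per feature the implied cells, the
#'       consistency gap, and whether it was adjusted.}
#'   }
#' @examples
#' cal <- calibrate_feature_probs()
#' subset(cal$report, adjusted)  # the internally inconsistent rows
#' @export
calibrate_feature_probs <- function(rows = reported_feature_rows(),
                                    case_total = 336, noncase_total = 127,
                                    tolerance = 5) {
  if (!is.data.frame(rows) || nrow(rows) == 0) {
    stop2("rows must be a non-empty data.frame")
  }
  one <- function(i) {
    r <- rows[i, ]
    if (r$present == 0) {
      return(data.frame(feature = r$feature, present = r$present,
                        tp = 0L, fp = 0L, fn = NA_integer_, tn = NA_integer_,
                        gap = 0L, adjusted = FALSE,
                        p_case = 0, p_noncase = 0,
                        stringsAsFactors = FALSE))
    }
    fr <- invert_feature_row(r$present, r$total, r$ppv, r$npv, case_total)
    adjusted <- fr$consistency_gap > tolerance
    if (adjusted) {
      scale <- case_total / fr$implied_cases
      tp_adj <- fr$tp * scale
      fp_adj <- r$present - tp_adj
    } else {
      tp_adj <- fr$tp
      fp_adj <- fr$fp
    }
    data.frame(feature = r$feature, present = r$present,
               tp = fr$tp, fp = fr$fp, fn = fr$fn, tn = fr$tn,
               gap = fr$consistency_gap, adjusted = adjusted,
               p_case = min(1, max(0, tp_adj / case_total)),
               p_noncase = min(1, max(0, fp_adj / noncase_total)),
               stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, lapply(seq_len(nrow(rows)), one))
  list(probs = report[c("feature", "p_case", "p_noncase")],
       report = report)
}

#' Generative parameters of a synthetic abdominal-pain cohort
#'
#' Defaults encode the reference cohort: n = 463 with class mix
#' (127, 234, 102)/463 for no appendicitis / simple / perforated; per-class
#' ages 11.6 (3.7), 10.9 (3.3), 10.0 (4.2) years truncated to (1, 17);
#' female fractions 53/127, 143/234, 70/102; symptom durations 57.8 (73.4),
#' 34.3 (39.7), 52.1 (48.7) hours (lognormal, moment-matched); per-class
#' feature probabilities calibrated to the published feature rows via
#' [calibrate_feature_probs()] (cases' probabilities shared between simple
#' and perforated appendicitis, since the published rows only condition on
#' appendicitis vs none); and a joint lab/ultrasound missingness
#' probability of 7/463.
#'
#' @param n_total Number of patients to generate.
#' @param class_probs Named probabilities for
#'   `c(no_appendicitis, simple, perforated)`; must sum to 1.
#' @param feature_probs Matrix (features x 3 classes) of Bernoulli
#'   probabilities; rownames from [score_features], colnames the outcome
#'   classes.
#' @param demographics `data.frame` as in `reported_cohort()$by_class`
#'   (columns `class`, `age_mean`, `age_sd`, `female`, `n`,
#'   `duration_mean_h`, `duration_sd_h`).
#' @param missing_prob Probability that a patient's laboratory and
#'   ultrasound block is jointly missing.
#' @param seed RNG seed; a fixed seed makes [generate_cohort()] bit-identical.
#' @return An object of class `cohort_parameters`.
#' @export
cohort_parameters <- function(n_total = 463,
                              class_probs = c(no_appendicitis = 127 / 463,
                                              simple = 234 / 463,
                                              perforated = 102 / 463),
                              feature_probs = default_feature_probs(),
                              demographics = reported_cohort()$by_class,
                              missing_prob = 7 / 463,
                              seed = NULL) {
  stopifnot(n_total >= 1)
  if (abs(sum(class_probs) - 1) > 1e-8 || any(class_probs < 0)) {
    stop2("class_probs must be non-negative and sum to 1")
  }
  if (!setequal(names(class_probs), outcome_levels)) {
    stop2("class_probs must be named no_appendicitis/simple/perforated")
  }
  stopifnot(is.matrix(feature_probs),
            setequal(rownames(feature_probs), score_features),
            setequal(colnames(feature_probs), outcome_levels),
            all(feature_probs >= 0 & feature_probs <= 1))
  stopifnot(is.data.frame(demographics),
            setequal(demographics$class, outcome_levels),
            all(demographics$age_sd > 0), all(demographics$duration_sd_h > 0))
  stopifnot(missing_prob >= 0, missing_prob <= 1)
  structure(
    list(n_total = as.integer(n_total),
         class_probs = class_probs[outcome_levels],
         feature_probs = feature_probs[score_features, outcome_levels],
         demographics = demographics[match(outcome_levels,
                                           demographics$class), ],
         missing_prob = missing_prob, seed = seed),
    class = "cohort_parameters"
  )
}

#' Default calibrated feature-probability matrix
#'
#' @param tolerance Consistency-gap tolerance passed to
#'   [calibrate_feature_probs()].
#' @return Matrix (features x classes) of Bernoulli probabilities; the
#'   appendicitis-conditional column is used for both simple and perforated
#'   disease.
#' @export
default_feature_probs <- function(tolerance = 5) {
  cal <- calibrate_feature_probs(tolerance = tolerance)
  m <- cbind(no_appendicitis = cal$probs$p_noncase,
             simple = cal$probs$p_case,
             perforated = cal$probs$p_case)
  rownames(m) <- cal$probs$feature
  m[score_features, , drop = FALSE]
}

# truncated-normal draws on (lo, hi) by inverse-CDF
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# lognormal draws matching a target mean and SD
rlnorm_moments <- function(n, mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  stats::rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

# Two-component continuous magnitude around a strict cutoff: a positive
# lognormal relative offset is added above (value = cutoff * (1 + off)) or
# divided below (value = cutoff / (1 + off)), so the thresholded indicator
# equals the Bernoulli draw by construction and values stay positive.
two_component <- function(ind, cutoff, meanlog, sdlog) {
  off <- stats::rlnorm(length(ind), meanlog, sdlog)
  ifelse(ind == 1L, cutoff * (1 + off), cutoff / (1 + off))
}

#' Generate a synthetic abdominal-pain cohort
#'
#' Samples patients from the generative model in [cohort_parameters()]:
#' outcome class multinomial; binary score items conditionally independent
#' Bernoulli given class; age truncated-normal on (1, 17); symptom duration
#' lognormal moment-matched to the class mean/SD; continuous labs and
#' temperature drawn by a two-component construction that places the value
#' on the correct side of its strict cutoff so the thresholded indicators
#' exactly realize the calibrated probabilities; the laboratory/ultrasound
#' block (WBC, neutrophils, CRP, ultrasound) is jointly missing with the
#' configured probability while clinical findings are always recorded. With
#' a fixed seed the output is bit-identical across calls.
#'
#' @param params A [cohort_parameters()] object.
#' @return A validated cohort `data.frame` (see [cohort_columns]).
#' @examples
#' cohort <- generate_cohort(cohort_parameters(n_total = 100, seed = 42))
#' table(cohort$outcome)
#' @export
generate_cohort <- function(params = cohort_parameters()) {
  stopifnot(inherits(params, "cohort_parameters"))
  with_seed(params$seed, {
    n <- params$n_total
    cls <- sample(outcome_levels, n, replace = TRUE,
                  prob = params$class_probs)
    ci <- match(cls, outcome_levels)
    demo <- params$demographics
    age <- rtruncnorm(n, demo$age_mean[ci], demo$age_sd[ci], 1, 17)
    female <- stats::runif(n) < (demo$female / demo$n)[ci]
    duration <- numeric(n)
    for (k in seq_len(3)) {
      sel <- ci == k
      if (any(sel)) {
        duration[sel] <- rlnorm_moments(sum(sel), demo$duration_mean_h[k],
                                        demo$duration_sd_h[k])
      }
    }
    fp <- params$feature_probs
    ind <- sapply(score_features, function(f) {
      as.integer(stats::runif(n) < fp[f, ][ci])
    })
    # continuous raw values on the indicated side of each strict cutoff
    temp <- pmin(two_component(ind[, "fever"], 38.5, log(0.012), 0.5), 41.8)
    wbc <- two_component(ind[, "wbc_high"], 11, log(0.30), 0.6)
    crp <- two_component(ind[, "crp_high"], 20, log(1.0), 0.9)
    # neutrophilia is an OR of the percentage and absolute criteria: when
    # positive the percentage branch is always made to fire and the absolute
    # branch with probability 1/2; when negative both stay below cutoff
    abs_high <- ind[, "neutrophilia"] == 1L & stats::runif(n) < 0.5
    npct <- pmin(two_component(ind[, "neutrophilia"], 75, log(0.08), 0.5),
                 99.5)
    nabs <- two_component(as.integer(abs_high), 7.9, log(0.25), 0.6)
    cohort <- data.frame(
      id = sprintf("p%05d", seq_len(n)),
      age = age,
      sex = ifelse(female, "female", "male"),
      duration_h = duration,
      continuous_pain = ind[, "continuous_pain"] == 1L,
      nausea_vomiting = ind[, "nausea_vomiting"] == 1L,
      anorexia = ind[, "anorexia"] == 1L,
      migration_of_pain = ind[, "migration_of_pain"] == 1L,
      tenderness_rlq = ind[, "tenderness_rlq"] == 1L,
      rebound_tenderness = ind[, "rebound_tenderness"] == 1L,
      cough_hop_tenderness = ind[, "cough_hop_tenderness"] == 1L,
      temperature_c = temp,
      wbc = wbc,
      neutrophils_abs = nabs,
      neutrophils_pct = npct,
      crp = crp,
      us_appendicitis = ind[, "us_appendicitis"] == 1L,
      outcome = cls,
      stringsAsFactors = FALSE
    )
    miss <- stats::runif(n) < params$missing_prob
    cohort[miss, c("wbc", "neutrophils_abs", "neutrophils_pct", "crp")] <-
      NA_real_
    cohort$us_appendicitis[miss] <- NA
    validate_cohort(cohort)
    cohort
  })
}

#' Summarize a cohort for side-by-side comparison with published figures
#'
#' @param cohort A cohort `data.frame`.
#' @param policy [threshold_policy()] used to derive the binary items.
#' @return A list with `classes` (per-class n, female fraction, age and
#'   duration moments) and `features` (per-class empirical frequency of each
#'   binary item among patients where it is derivable).
#' @export
summarize_cohort <- function(cohort, policy = threshold_policy()) {
  validate_cohort(cohort)
  if (nrow(cohort) == 0) stop2("cohort is empty")
  fv <- derive_features(cohort, policy)
  cls_stats <- lapply(outcome_levels, function(cl) {
    sel <- !is.na(cohort$outcome) & cohort$outcome == cl
    data.frame(
      class = cl, n = sum(sel),
      female = sum(cohort$sex[sel] == "female"),
      age_mean = if (any(sel)) mean(cohort$age[sel]) else NA_real_,
      age_sd = if (sum(sel) > 1) stats::sd(cohort$age[sel]) else NA_real_,
      duration_mean_h = if (any(sel)) mean(cohort$duration_h[sel])
                        else NA_real_,
      duration_sd_h = if (sum(sel) > 1) stats::sd(cohort$duration_h[sel])
                      else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  feat <- sapply(outcome_levels, function(cl) {
    sel <- !is.na(cohort$outcome) & cohort$outcome == cl
    vapply(score_features, function(f) {
      x <- fv[[f]][sel]
      if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
    }, numeric(1))
  })
  list(classes = do.call(rbind, cls_stats),
       features = as.data.frame(feat))
}
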