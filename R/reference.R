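# Published summaries of the two-center pediatric abdominal-pain cohort
# (463 children, 336 histologically confirmed appendicitis: 234 simple, 102
# perforated, 127 without appendicitis) that the simulator is calibrated to
# and the identity checks recompute from.

#' Published cohort composition and demographics
#'
#' Headline counts and per-class demographic moments of the reference
#' cohort: 463 included children, 348 appendectomies, 336 histologically
#' confirmed appendicitis (234 simple, 102 perforated), 127 without
#' appendicitis; lab/ultrasound available in 456/463. Ages are mean (SD)
#' years, durations mean (SD) hours of abdominal pain.
#'
#' @return A list with `counts` (named integer vector) and `by_class`
#'   (`data.frame` with one row per outcome class).
#' @export
reported_cohort <- function() {
  list(
    counts = c(
      n_total = 463L, n_operated = 348L, n_appendicitis = 336L,
      n_simple = 234L, n_perforated = 102L, n_no_appendicitis = 127L,
      n_complete = 456L
    ),
    by_class = data.frame(
      class = c("no_appendicitis", "simple", "perforated"),
      n = c(127L, 234L, 102L),
      age_mean = c(11.6, 10.9, 10.0),
      age_sd = c(3.7, 3.3, 4.2),
      female = c(53L, 143L, 70L),
      duration_mean_h = c(57.8, 34.3, 52.1),
      duration_sd_h = c(73.4, 39.7, 48.7),
      stringsAsFactors = FALSE
    )
  )
}

#' Published per-feature predictive-value rows
#'
#' For each score item the reference cohort reports the number of patients
#' in whom it was present and its PPV/NPV for appendicitis. These rows are
#' the calibration input for [calibrate_feature_probs()]. Migration of pain
#' was present in 0/463 patients and carries no predictive values; its
#' per-class probability is fixed at 0.
#'
#' @return A `data.frame` with columns `feature`, `present`, `total`, `ppv`,
#'   `npv` (proportions).
#' @export
reported_feature_rows <- function() {
  data.frame(
    feature = c("continuous_pain", "nausea_vomiting", "anorexia",
                "migration_of_pain", "fever", "tenderness_rlq",
                "rebound_tenderness", "cough_hop_tenderness", "wbc_high",
                "neutrophilia", "crp_high", "us_appendicitis"),
    present = c(7L, 319L, 176L, 0L, 312L, 334L, 293L, 205L, 333L, 72L,
                332L, 287L),
    total = c(463L, 463L, 463L, 463L, 463L, 463L, 463L, 463L, 463L, 463L,
              456L, 456L),
    ppv = c(0.400, 0.815, 0.821, NA, 0.974, 0.733, 0.897, 0.897, 0.857,
            0.964, 0.946, 0.959),
    npv = c(0.500, 0.453, 0.380, NA, 0.300, 0.583, 0.365, 0.372, 0.488,
            0.136, 0.477, 0.681),
    stringsAsFactors = FALSE
  )
}

#' Published diagnostic-accuracy estimates per score
#'
#' Sensitivity and specificity of the six scores in the reference cohort,
#' for the appendicitis-vs-none dichotomy (full abdominal-pain cohort) and
#' the perforated-vs-non-perforated dichotomy (within appendicitis cases).
#' Used by the identity checks: likelihood ratios and predictive values are
#' recomputed from these via [lr_from_sens_spec()] and
#' [ppv_npv_from_sens_spec_prev()].
#'
#' @return A `data.frame` with columns `score`, `dichotomy`, `sens`, `spec`
#'   (proportions).
#' @export
reported_score_panels <- function() {
  rbind(
    data.frame(
      score = c("alvarado", "pas", "tzanakis", "has", "mhas", "ai"),
      dichotomy = "appendicitis",
      sens = c(0.679, 0.342, 0.804, 0.310, 0.866, 0.872),
      spec = c(0.787, 0.953, 0.874, 0.961, 0.709, 0.701),
      stringsAsFactors = FALSE
    ),
    data.frame(
      score = c("alvarado", "pas", "tzanakis", "has", "mhas", "ai"),
      dichotomy = "perforation",
      sens = c(0.843, 0.402, 0.814, 0.412, 0.971, 0.980),
      spec = c(0.393, 0.684, 0.201, 0.735, 0.179, 0.175),
      stringsAsFactors = FALSE
    )
  )
}
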