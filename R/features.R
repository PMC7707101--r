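#' Names of the binary score items derivable from a patient record
#'
#' All six scoring systems are additive over this common item vocabulary:
#' seven tri-state clinical findings passed through as-is, plus five
#' indicators obtained by strict-threshold dichotomization of continuous
#' measurements (`fever`, `wbc_high`, `neutrophilia`, `crp_high`) or of the
#' ultrasound read (`us_appendicitis`).
#'
#' @format Character vector of feature names.
#' @export
score_features <- c(
  "tenderness_rlq", "rebound_tenderness", "cough_hop_tenderness",
  "continuous_pain", "nausea_vomiting", "anorexia", "migration_of_pain",
  "fever", "wbc_high", "neutrophilia", "crp_high", "us_appendicitis"
)

# the jointly-missing laboratory/ultrasound block: in the study cohort these
# were either all recorded or all absent for a patient
lab_us_features <- c("wbc_high", "neutrophilia", "crp_high", "us_appendicitis")

#' Dichotomization thresholds for continuous measurements
#'
#' All comparisons are strict (`value > cutoff`), matching the usual notation
#' of the published item definitions ("WBC > 11 x 10^9/L", "CRP > 20 mg/L",
#' "temperature > 38.5 C", "neutrophilia > 7.9 x 10^9/L or > 75%"). The WBC
#' cutoff is 11 x 10^9/L by default; the 12 x 10^9/L variant used by some
#' formulations of the Alvarado score can be selected per policy.
#'
#' @param wbc_cutoff White-cell count cutoff, 10^9/L.
#' @param neutrophilia_abs_cutoff Absolute neutrophil cutoff, 10^9/L.
#' @param neutrophilia_pct_cutoff Neutrophil percentage cutoff, %.
#' @param crp_cutoff C-reactive protein cutoff, mg/L.
#' @param temp_cutoff Fever cutoff, degrees Celsius.
#' @return An object of class `threshold_policy`.
#' @examples
#' threshold_policy()                  # defaults
#' threshold_policy(wbc_cutoff = 12)   # Alvarado's original WBC criterion
#' @export
threshold_policy <- function(wbc_cutoff = 11, neutrophilia_abs_cutoff = 7.9,
                             neutrophilia_pct_cutoff = 75, crp_cutoff = 20,
                             temp_cutoff = 38.5) {
  pol <- list(
    wbc_cutoff = as.numeric(wbc_cutoff),
    neutrophilia_abs_cutoff = as.numeric(neutrophilia_abs_cutoff),
    neutrophilia_pct_cutoff = as.numeric(neutrophilia_pct_cutoff),
    crp_cutoff = as.numeric(crp_cutoff),
    temp_cutoff = as.numeric(temp_cutoff)
  )
  if (any(vapply(pol, function(x) !is.finite(x) || x <= 0, logical(1)))) {
    stop2("all threshold cutoffs must be finite and strictly positive")
  }
  structure(pol, class = "threshold_policy")
}

#' Derive binary score items from a cohort
#'
#' Maps each patient's raw values onto the common item vocabulary in
#' [score_features]. Tri-state findings map yes to 1, no to 0, and missing to
#' `NA` (a missing raw value is represented, never silently treated as
#' absent). Thresholded indicators use the strict comparisons of `policy`.
#' Neutrophilia is positive if *either* the absolute count or the percentage
#' criterion holds; it is negative only when at least one of the two
#' measurements is recorded and no recorded one exceeds its cutoff, and `NA`
#' when both are missing.
#'
#' @param cohort A cohort `data.frame` (see [cohort_columns]).
#' @param policy A [threshold_policy()].
#' @return A `data.frame` with one integer (0/1/`NA`) column per feature in
#'   [score_features], plus `id` and a logical `complete` column that is
#'   `TRUE` iff every feature is derivable for that patient.
#' @examples
#' p <- patient_record("p1", 9, "male", wbc = 11.5, neutrophils_pct = 80,
#'                     crp = 20)
#' derive_features(p)  # wbc_high = 1, neutrophilia = 1, crp_high = 0 (strict >)
#' @export
derive_features <- function(cohort, policy = threshold_policy()) {
  validate_cohort(cohort)
  stopifnot(inherits(policy, "threshold_policy"))
  ind <- function(x) as.integer(x)  # logical/NA -> 0/1/NA
  neut_abs <- cohort$neutrophils_abs > policy$neutrophilia_abs_cutoff
  neut_pct <- cohort$neutrophils_pct > policy$neutrophilia_pct_cutoff
  # OR with missingness: positive beats missing, missing beats negative
  neutrophilia <- ifelse(
    !is.na(neut_abs) & neut_abs | !is.na(neut_pct) & neut_pct, 1L,
    ifelse(is.na(neut_abs) & is.na(neut_pct), NA_integer_, 0L)
  )
  fv <- data.frame(
    id = cohort$id,
    tenderness_rlq = ind(cohort$tenderness_rlq),
    rebound_tenderness = ind(cohort$rebound_tenderness),
    cough_hop_tenderness = ind(cohort$cough_hop_tenderness),
    continuous_pain = ind(cohort$continuous_pain),
    nausea_vomiting = ind(cohort$nausea_vomiting),
    anorexia = ind(cohort$anorexia),
    migration_of_pain = ind(cohort$migration_of_pain),
    fever = ind(cohort$temperature_c > policy$temp_cutoff),
    wbc_high = ind(cohort$wbc > policy$wbc_cutoff),
    neutrophilia = neutrophilia,
    crp_high = ind(cohort$crp > policy$crp_cutoff),
    us_appendicitis = ind(cohort$us_appendicitis),
    stringsAsFactors = FALSE
  )
  fv$complete <- stats::complete.cases(fv[score_features])
  fv
}
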