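#' Column names of a patient cohort table
#'
#' A cohort is an ordinary `data.frame` with one row per patient and exactly
#' these columns. Tri-state clinical findings (`continuous_pain`,
#' `nausea_vomiting`, `anorexia`, `migration_of_pain`, `tenderness_rlq`,
#' `rebound_tenderness`, `cough_hop_tenderness`, `us_appendicitis`) are stored
#' as logical (`TRUE`/`FALSE`/`NA`); continuous measurements use `NA` for
#' missing; `outcome` is one of `"no_appendicitis"`, `"simple"`,
#' `"perforated"`, or `NA` when the histology label is unknown.
#'
#' @format Character vector of column names.
#' @export
cohort_columns <- c(
  "id", "age", "sex", "duration_h",
  "continuous_pain", "nausea_vomiting", "anorexia", "migration_of_pain",
  "tenderness_rlq", "rebound_tenderness", "cough_hop_tenderness",
  "temperature_c", "wbc", "neutrophils_abs", "neutrophils_pct", "crp",
  "us_appendicitis", "outcome"
)

tristate_columns <- c(
  "continuous_pain", "nausea_vomiting", "anorexia", "migration_of_pain",
  "tenderness_rlq", "rebound_tenderness", "cough_hop_tenderness",
  "us_appendicitis"
)

outcome_levels <- c("no_appendicitis", "simple", "perforated")

#' Construct a single patient record
#'
#' Convenience constructor returning a one-row cohort `data.frame`; mostly
#' useful in examples and tests. All clinical findings default to `FALSE`
#' (absent), all labs to `NA` (not measured).
#'
#' @param id Patient identifier (coerced to character).
#' @param age Age in years, in (0, 18].
#' @param sex `"female"` or `"male"`.
#' @param duration_h Duration of abdominal pain in hours (>= 0).
#' @param continuous_pain,nausea_vomiting,anorexia,migration_of_pain
#'   Tri-state history items: `TRUE`, `FALSE` or `NA`.
#' @param tenderness_rlq,rebound_tenderness,cough_hop_tenderness Tri-state
#'   examination findings.
#' @param temperature_c Body temperature in degrees Celsius, or `NA`.
#' @param wbc White-cell count in 10^9/L, or `NA`.
#' @param neutrophils_abs Absolute neutrophil count in 10^9/L, or `NA`.
#' @param neutrophils_pct Neutrophil percentage in [0, 100], or `NA`.
#' @param crp C-reactive protein in mg/L, or `NA`.
#' @param us_appendicitis Tri-state ultrasound finding of appendicitis.
#' @param outcome Histology-based class: `"no_appendicitis"`, `"simple"`,
#'   `"perforated"`, or `NA`.
#' @return A one-row `data.frame` with the columns in [cohort_columns].
#' @examples
#' patient_record("p1", age = 9, sex = "male", tenderness_rlq = TRUE,
#'                wbc = 14.2, crp = 31, us_appendicitis = TRUE)
#' @export
patient_record <- function(id, age, sex, duration_h = NA_real_,
                           continuous_pain = FALSE, nausea_vomiting = FALSE,
                           anorexia = FALSE, migration_of_pain = FALSE,
                           tenderness_rlq = FALSE, rebound_tenderness = FALSE,
                           cough_hop_tenderness = FALSE,
                           temperature_c = NA_real_, wbc = NA_real_,
                           neutrophils_abs = NA_real_,
                           neutrophils_pct = NA_real_, crp = NA_real_,
                           us_appendicitis = FALSE, outcome = NA_character_) {
  rec <- data.frame(
    id = as.character(id), age = as.numeric(age), sex = as.character(sex),
    duration_h = as.numeric(duration_h),
    continuous_pain = as.logical(continuous_pain),
    nausea_vomiting = as.logical(nausea_vomiting),
    anorexia = as.logical(anorexia),
    migration_of_pain = as.logical(migration_of_pain),
    tenderness_rlq = as.logical(tenderness_rlq),
    rebound_tenderness = as.logical(rebound_tenderness),
    cough_hop_tenderness = as.logical(cough_hop_tenderness),
    temperature_c = as.numeric(temperature_c), wbc = as.numeric(wbc),
    neutrophils_abs = as.numeric(neutrophils_abs),
    neutrophils_pct = as.numeric(neutrophils_pct), crp = as.numeric(crp),
    us_appendicitis = as.logical(us_appendicitis),
    outcome = as.character(outcome),
    stringsAsFactors = FALSE
  )
  validate_cohort(rec)
  rec
}

#' Validate a cohort table
#'
#' Checks column presence and the physiological range invariants: age in
#' (0, 18], duration >= 0, WBC/CRP/absolute neutrophils >= 0 when present,
#' neutrophil percentage in [0, 100] when present, and outcome labels within
#' the known set.
#'
#' @param cohort A cohort `data.frame`.
#' @return The cohort, invisibly, on success; otherwise an error.
#' @export
validate_cohort <- function(cohort) {
  if (!is.data.frame(cohort)) stop2("cohort must be a data.frame")
  missing_cols <- setdiff(cohort_columns, names(cohort))
  if (length(missing_cols) > 0) {
    stop2("cohort is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  chk <- function(ok, msg) {
    bad <- which(!ok & !is.na(ok))
    if (length(bad) > 0) {
      stop2(msg, " (rows ", paste(utils::head(bad, 5), collapse = ", "),
            if (length(bad) > 5) ", ..." else "", ")")
    }
  }
  chk(cohort$age > 0 & cohort$age <= 18, "age must be in (0, 18]")
  chk(cohort$duration_h >= 0, "duration_h must be >= 0")
  chk(cohort$wbc >= 0, "wbc must be >= 0")
  chk(cohort$crp >= 0, "crp must be >= 0")
  chk(cohort$neutrophils_abs >= 0, "neutrophils_abs must be >= 0")
  chk(cohort$neutrophils_pct >= 0 & cohort$neutrophils_pct <= 100,
      "neutrophils_pct must be in [0, 100]")
  chk(cohort$sex %in% c("female", "male"), "sex must be 'female' or 'male'")
  chk(is.na(cohort$outcome) | cohort$outcome %in% outcome_levels,
      "outcome must be no_appendicitis/simple/perforated or NA")
  for (col in tristate_columns) {
    if (!is.logical(cohort[[col]])) {
      stop2("column '", col, "' must be logical (TRUE/FALSE/NA)")
    }
  }
  invisible(cohort)
}

#' Read a patient cohort from CSV
#'
#' The CSV dialect has one header row with exactly the [cohort_columns]
#' names, UTF-8 encoding, and empty cells for missing values. Tri-state
#' columns accept `yes`/`no`, `true`/`false`, or `1`/`0` (case-insensitive).
#'
#' @param path Path to a CSV file.
#' @return A validated cohort `data.frame`.
#' @seealso [write_cohort_csv()]
#' @export
read_cohort_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = "",
                         fileEncoding = "UTF-8")
  missing_cols <- setdiff(cohort_columns, names(raw))
  if (length(missing_cols) > 0) {
    stop2("cohort CSV is missing columns: ",
          paste(missing_cols, collapse = ", "))
  }
  out <- raw[cohort_columns]
  for (col in c("age", "duration_h", "temperature_c", "wbc",
                "neutrophils_abs", "neutrophils_pct", "crp")) {
    out[[col]] <- as.numeric(out[[col]])
  }
  for (col in tristate_columns) {
    out[[col]] <- parse_tristate(out[[col]], col)
  }
  validate_cohort(out)
  out
}

parse_tristate <- function(x, col) {
  lx <- tolower(trimws(x))
  out <- rep(NA, length(x))
  out[lx %in% c("yes", "true", "1")] <- TRUE
  out[lx %in% c("no", "false", "0")] <- FALSE
  bad <- !is.na(lx) & !(lx %in% c("yes", "no", "true", "false", "1", "0"))
  if (any(bad)) {
    stop2("column '", col, "' has unparseable values: ",
          paste(unique(x[bad]), collapse = ", "))
  }
  out
}

#' Write a patient cohort to CSV
#'
#' Inverse of [read_cohort_csv()]: tri-state columns are written as
#' `yes`/`no`, missing values as empty cells.
#'
#' @param cohort A cohort `data.frame`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  validate_cohort(cohort)
  out <- cohort[cohort_columns]
  for (col in tristate_columns) {
    out[[col]] <- ifelse(is.na(out[[col]]), NA_character_,
                         ifelse(out[[col]], "yes", "no"))
  }
  utils::write.csv(out, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}
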