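#' Define an additive clinical score
#'
#' A score is a weighted sum of binary items from the common vocabulary in
#' [score_features], dichotomized at an inclusive positivity cutoff
#' (`total >= cutoff` is positive).
#'
#' @param name Score name.
#' @param items Named integer vector of item weights (names from
#'   [score_features], weights >= 1).
#' @param positivity_cutoff Integer cutoff; a total at or above it is
#'   positive.
#' @param threshold_policy A [threshold_policy()] used when deriving the
#'   score's items from raw values.
#' @return An object of class `score_definition` with fields `name`, `items`,
#'   `max_score` (sum of weights), `positivity_cutoff`, `threshold_policy`.
#' @examples
#' score_definition("toy", c(tenderness_rlq = 2, wbc_high = 1), 2)
#' @export
score_definition <- function(name, items, positivity_cutoff,
                             threshold_policy = appendiscore::threshold_policy()) {
  if (is.null(names(items)) || any(!nzchar(names(items)))) {
    stop2("items must be a named vector of weights")
  }
  unknown <- setdiff(names(items), score_features)
  if (length(unknown) > 0) {
    stop2("unknown feature name(s) in score '", name, "': ",
          paste(unknown, collapse = ", "))
  }
  if (anyDuplicated(names(items))) stop2("duplicate item names")
  w <- as.integer(items)
  if (any(is.na(w) | w < 1)) stop2("item weights must be integers >= 1")
  names(w) <- names(items)
  max_score <- sum(w)
  cutoff <- as.integer(positivity_cutoff)
  if (is.na(cutoff) || cutoff < 1 || cutoff > max_score) {
    stop2("positivity_cutoff must lie in [1, max_score]")
  }
  stopifnot(inherits(threshold_policy, "threshold_policy"))
  structure(
    list(name = as.character(name), items = w, max_score = max_score,
         positivity_cutoff = cutoff, threshold_policy = threshold_policy),
    class = "score_definition"
  )
}

#' @export
print.score_definition <- function(x, ...) {
  cat(sprintf("<score_definition> %s (positive if total >= %d of %d)\n",
              x$name, x$positivity_cutoff, x$max_score))
  for (f in names(x$items)) cat(sprintf("  %-22s %d\n", f, x$items[[f]]))
  invisible(x)
}

#' The six built-in appendicitis score definitions
#'
#' Returns the published definitions of the Alvarado score, the Pediatric
#' Appendicitis Score (PAS), the Tzanakis score, the Heidelberg Appendicitis
#' Score (HAS), the modified HAS, and the random-forest derived "AI" score,
#' read from the JSON shipped with the package. All use the default
#' [threshold_policy()] (WBC > 11 x 10^9/L) unless `policy` overrides it.
#'
#' @param names Optional character vector selecting a subset (default: all
#'   six, in the order alvarado, pas, tzanakis, has, mhas, ai).
#' @param policy Optional [threshold_policy()] applied to every returned
#'   definition (e.g. the WBC > 12 variant).
#' @return A named list of [score_definition()] objects.
#' @examples
#' names(builtin_scores())
#' builtin_scores("tzanakis")[[1]]
#' @export
builtin_scores <- function(names = NULL, policy = NULL) {
  path <- system.file("extdata", "score_definitions.json",
                      package = "appendiscore", mustWork = TRUE)
  defs <- read_score_definitions(path)
  if (!is.null(names)) {
    unknown <- setdiff(names, base::names(defs))
    if (length(unknown) > 0) {
      stop2("unknown score(s): ", paste(unknown, collapse = ", "),
            "; available: ", paste(base::names(defs), collapse = ", "))
    }
    defs <- defs[names]
  }
  if (!is.null(policy)) {
    defs <- lapply(defs, function(d) {
      score_definition(d$name, d$items, d$positivity_cutoff, policy)
    })
  }
  defs
}

#' Read score definitions from JSON
#'
#' The JSON format holds one object per score with fields `name`, `items`
#' (feature name to integer weight), `positivity_cutoff`, and
#' `threshold_policy`.
#'
#' @param path Path to a JSON file.
#' @return Named list of [score_definition()] objects.
#' @seealso [write_score_definitions()]
#' @export
read_score_definitions <- function(path) {
  raw <- jsonlite::read_json(path)
  defs <- lapply(raw, function(obj) {
    pol <- do.call(threshold_policy, obj$threshold_policy)
    items <- unlist(obj$items)
    score_definition(obj$name, items, obj$positivity_cutoff, pol)
  })
  stats::setNames(defs, vapply(defs, `[[`, character(1), "name"))
}

#' Write score definitions to JSON
#'
#' @param definitions A list of [score_definition()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_definitions <- function(definitions, path) {
  payload <- lapply(unname(definitions), function(d) {
    list(name = d$name, items = as.list(d$items),
         positivity_cutoff = d$positivity_cutoff,
         threshold_policy = unclass(d$threshold_policy))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Evaluate one score on one patient
#'
#' @param patient A one-row cohort `data.frame` (see [patient_record()]).
#' @param definition A [score_definition()].
#' @return A list of class `score_result`: `name`, `total` (sum of
#'   weight x indicator over derivable items), `positive` (`TRUE`/`FALSE`, or
#'   `NA` when incomplete), `complete`, and `contributing` (names of items
#'   scoring points).
#' @examples
#' p <- patient_record("p1", 9, "male", tenderness_rlq = TRUE,
#'                     rebound_tenderness = TRUE, us_appendicitis = TRUE,
#'                     wbc = 8, neutrophils_pct = 60, crp = 4,
#'                     temperature_c = 37.2)
#' compute_score(p, builtin_scores("tzanakis")[[1]])  # 4 + 3 + 6 = 13
#' @export
compute_score <- function(patient, definition) {
  stopifnot(inherits(definition, "score_definition"))
  if (nrow(patient) != 1L) stop2("compute_score expects a single patient row")
  fv <- derive_features(patient, definition$threshold_policy)
  ind <- unlist(fv[1, names(definition$items)])
  complete <- !anyNA(ind)
  total <- sum(definition$items * ind, na.rm = TRUE)
  structure(
    list(name = definition$name, total = as.integer(total),
         positive = if (complete) total >= definition$positivity_cutoff else NA,
         complete = complete,
         contributing = names(definition$items)[!is.na(ind) & ind == 1L]),
    class = "score_result"
  )
}

#' @export
print.score_result <- function(x, ...) {
  cat(sprintf("<score_result> %s: total %d, %s%s\n", x$name, x$total,
              if (is.na(x$positive)) "positivity undefined"
              else if (x$positive) "POSITIVE" else "negative",
              if (x$complete) "" else " (incomplete record)"))
  invisible(x)
}

#' Score a whole cohort against several definitions
#'
#' Evaluates every requested score on every patient with complete data for
#' the requested scores' items. Mirroring a complete-case analysis, a patient
#' missing *any* item used by *any* requested score is excluded from every
#' score's evaluation set (so all scores are compared on the same patients)
#' and listed in the exclusion log.
#'
#' @param cohort A cohort `data.frame`.
#' @param definitions List of [score_definition()] objects (default: all six
#'   built-ins).
#' @param exclusion `"drop_incomplete"` (default) to exclude incomplete
#'   patients and log them, or `"error"` to fail on the first incomplete
#'   patient.
#' @return A list of class `score_matrix`:
#'   \describe{
#'     \item{results}{`data.frame` with `id`, `outcome`, and per score
#'       `<name>_total` / `<name>_positive` columns, one row per evaluated
#'       patient.}
#'     \item{excluded}{`data.frame` with `id` and `missing_items` for each
#'       excluded patient.}
#'     \item{n_input, n_evaluated, n_excluded}{Reconciling counts.}
#'   }
#' @examples
#' cohort <- generate_cohort(cohort_parameters(n_total = 50, seed = 1))
#' sm <- apply_scores(cohort)
#' sm$n_evaluated + sm$n_excluded == nrow(cohort)
#' @export
apply_scores <- function(cohort, definitions = builtin_scores(),
                         exclusion = c("drop_incomplete", "error")) {
  exclusion <- match.arg(exclusion)
  validate_cohort(cohort)
  if (nrow(cohort) == 0) stop2("cohort is empty")
  stopifnot(length(definitions) > 0,
            all(vapply(definitions, inherits, logical(1), "score_definition")))
  needed <- unique(unlist(lapply(definitions, function(d) names(d$items))))
  # each definition may carry its own policy; derive per distinct policy
  policies <- unique(lapply(definitions, `[[`, "threshold_policy"))
  fvs <- lapply(policies, function(p) derive_features(cohort, p))
  pol_idx <- vapply(definitions, function(d) {
    which(vapply(policies, identical, logical(1), d$threshold_policy))[1]
  }, integer(1))
  ok <- Reduce(`&`, lapply(fvs, function(fv) {
    stats::complete.cases(fv[intersect(needed, names(fv))])
  }))
  if (exclusion == "error" && any(!ok)) {
    stop2("incomplete patient record: id ", cohort$id[which(!ok)[1]])
  }
  miss_items <- vapply(which(!ok), function(i) {
    miss <- unique(unlist(lapply(fvs, function(fv) {
      needed[is.na(unlist(fv[i, needed]))]
    })))
    paste(miss, collapse = ";")
  }, character(1))
  excluded <- data.frame(id = cohort$id[!ok],
                         missing_items = miss_items,
                         stringsAsFactors = FALSE)
  res <- data.frame(id = cohort$id[ok], outcome = cohort$outcome[ok],
                    stringsAsFactors = FALSE)
  for (k in seq_along(definitions)) {
    d <- definitions[[k]]
    fv <- fvs[[pol_idx[k]]][ok, , drop = FALSE]
    mat <- as.matrix(fv[names(d$items)])
    totals <- as.integer(mat %*% d$items)
    res[[paste0(d$name, "_total")]] <- totals
    res[[paste0(d$name, "_positive")]] <- totals >= d$positivity_cutoff
  }
  structure(
    list(results = res, excluded = excluded, n_input = nrow(cohort),
         n_evaluated = sum(ok), n_excluded = sum(!ok)),
    class = "score_matrix"
  )
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("<score_matrix> %d patients scored, %d excluded (of %d)\n",
              x$n_evaluated, x$n_excluded, x$n_input))
  invisible(x)
}
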