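#' Diagnostic-performance panels for scored patients
#'
#' Computes one [diagnostic_panel()] row per score from an [apply_scores()]
#' result. The `"appendicitis"` dichotomy contrasts histology-confirmed
#' appendicitis (simple or perforated) against no appendicitis over all
#' evaluated patients; the `"perforation"` dichotomy contrasts perforated
#' against non-perforated appendicitis *within* appendicitis cases only.
#'
#' @param scored A `score_matrix` from [apply_scores()].
#' @param dichotomy `"appendicitis"` or `"perforation"`.
#' @param ci,conf,boot,seed Passed to [diagnostic_panel()].
#' @return A list with `panels` (one `data.frame` row per score, stacked)
#'   and `confusions` (the underlying confusion matrices, named by score).
#' @export
evaluate_scores <- function(scored, dichotomy = c("appendicitis",
                                                  "perforation"),
                            ci = "wilson", conf = 0.95, boot = 2000,
                            seed = NULL) {
  dichotomy <- match.arg(dichotomy)
  stopifnot(inherits(scored, "score_matrix"))
  res <- scored$results
  if (anyNA(res$outcome)) {
    stop2("evaluation requires known outcomes for all scored patients")
  }
  if (dichotomy == "appendicitis") {
    keep <- rep(TRUE, nrow(res))
    truth <- res$outcome %in% c("simple", "perforated")
  } else {
    keep <- res$outcome %in% c("simple", "perforated")
    truth <- res$outcome[keep] == "perforated"
  }
  sub <- res[keep, , drop = FALSE]
  score_names <- sub(
    "_total$", "", grep("_total$", names(sub), value = TRUE)
  )
  confusions <- list()
  panels <- NULL
  for (s in score_names) {
    pred <- sub[[paste0(s, "_positive")]]
    totals <- sub[[paste0(s, "_total")]]
    cm <- confusion(pred, truth, dichotomy = dichotomy)
    confusions[[s]] <- cm
    row <- diagnostic_panel(cm, totals = totals, outcomes = truth, ci = ci,
                            predictions = pred, conf = conf, boot = boot,
                            seed = seed)
    row <- cbind(data.frame(score = s, stringsAsFactors = FALSE), row)
    panels <- rbind(panels, row)
  }
  rownames(panels) <- NULL
  list(panels = panels, confusions = confusions)
}

#' Per-feature predictive values of a cohort
#'
#' Empirical analogue of a published feature table: for each binary item,
#' the number of patients in whom it is present (among those where it is
#' derivable) and its PPV/NPV for the appendicitis dichotomy.
#'
#' @param cohort A cohort `data.frame` with known outcomes.
#' @param policy [threshold_policy()].
#' @return `data.frame` with `feature`, `present`, `total`, `ppv`, `npv`.
#' @export
feature_report <- function(cohort, policy = threshold_policy()) {
  validate_cohort(cohort)
  fv <- derive_features(cohort, policy)
  truth <- cohort$outcome %in% c("simple", "perforated")
  rows <- lapply(score_features, function(f) {
    x <- fv[[f]]
    ok <- !is.na(x)
    present <- sum(x[ok] == 1L)
    absent <- sum(x[ok] == 0L)
    data.frame(
      feature = f, present = present, total = sum(ok),
      ppv = if (present > 0) sum(x == 1L & truth, na.rm = TRUE) / present
            else NA_real_,
      npv = if (absent > 0) sum(x == 0L & !truth, na.rm = TRUE) / absent
            else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Missed-perforation counterfactual per score
#'
#' "If only children with a positive score had undergone appendectomy":
#' for each score, the perforated cases with a negative score would have
#' been missed. Computed through [missed_cases()] on each score's
#' perforation-dichotomy sensitivity.
#'
#' @param scored A `score_matrix` from [apply_scores()].
#' @return `data.frame` with `score`, `sens_perforation`, `n_perforated`,
#'   `missed`, `missed_pct`.
#' @export
missed_perforation_table <- function(scored) {
  stopifnot(inherits(scored, "score_matrix"))
  res <- scored$results
  perf <- res$outcome == "perforated"
  n_perf <- sum(perf)
  score_names <- sub("_total$", "", grep("_total$", names(res),
                                         value = TRUE))
  rows <- lapply(score_names, function(s) {
    pred <- res[[paste0(s, "_positive")]]
    sens <- if (n_perf > 0) sum(pred & perf) / n_perf else NA_real_
    mc <- if (n_perf > 0) missed_cases(sens, n_perf)
          else c(missed_count = NA_real_, missed_fraction = NA_real_)
    data.frame(score = s, sens_perforation = sens, n_perforated = n_perf,
               missed = unname(mc["missed_count"]),
               missed_pct = 100 * unname(mc["missed_fraction"]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full simulate / score / evaluate / report pipeline
#'
#' Generates (or loads) a cohort, scores it with the requested definitions,
#' evaluates both outcome dichotomies, and assembles a report bundle: a
#' feature predictive-value table, an appendicitis panel, a perforation
#' panel, the missed-perforation counterfactual, the underlying confusion
#' matrices, and the exclusion log. Deterministic given the seed; when
#' `outdir` is given the bundle is also written as CSV files plus one JSON
#' document (percentages to 1 decimal, ratios and AUC to 2, in the files).
#'
#' @param n Cohort size when simulating (default 463).
#' @param seed RNG seed, recorded in the bundle.
#' @param cohort Optional pre-built cohort `data.frame` (skips simulation).
#' @param cohort_csv Optional path to a cohort CSV (skips simulation).
#' @param scores Character vector of built-in score names (default all six).
#' @param params Optional [cohort_parameters()] overriding `n`/`seed` for
#'   simulation.
#' @param ci CI method for the panels (`"wilson"` or `"bootstrap"`).
#' @param outdir Optional output directory.
#' @return A list of class `report_bundle`.
#' @examples
#' bundle <- run_pipeline(n = 200, seed = 11)
#' bundle$panel_appendicitis[, c("score", "sens", "spec")]
#' @export
run_pipeline <- function(n = 463, seed = 1, cohort = NULL,
                         cohort_csv = NULL, scores = NULL, params = NULL,
                         ci = "wilson", outdir = NULL) {
  if (!is.null(cohort_csv)) {
    if (!file.exists(cohort_csv)) stop2("simulate/load stage: cohort file '",
                                        cohort_csv, "' not found")
    cohort <- read_cohort_csv(cohort_csv)
  } else if (is.null(cohort)) {
    if (is.null(params)) params <- cohort_parameters(n_total = n, seed = seed)
    cohort <- generate_cohort(params)
  }
  defs <- builtin_scores(scores)
  scored <- apply_scores(cohort, defs)
  ev_app <- evaluate_scores(scored, "appendicitis", ci = ci, seed = seed)
  ev_perf <- evaluate_scores(scored, "perforation", ci = ci, seed = seed)
  bundle <- structure(
    list(seed = seed, n_input = scored$n_input,
         n_evaluated = scored$n_evaluated, n_excluded = scored$n_excluded,
         excluded = scored$excluded,
         feature_report = feature_report(cohort),
         panel_appendicitis = ev_app$panels,
         panel_perforation = ev_perf$panels,
         missed_perforation = missed_perforation_table(scored),
         confusions = c(appendicitis = ev_app$confusions,
                        perforation = ev_perf$confusions),
         cohort_summary = summarize_cohort(cohort)),
    class = "report_bundle"
  )
  if (!is.null(outdir)) write_report_bundle(bundle, outdir)
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf(
    "<report_bundle> seed %s: %d patients, %d evaluated, %d excluded\n",
    format(x$seed), x$n_input, x$n_evaluated, x$n_excluded))
  cat("  panels: appendicitis, perforation; tables: features, missed\n")
  invisible(x)
}

round_panel <- function(df) {
  out <- df
  for (col in names(out)) {
    if (!is.numeric(out[[col]])) next
    if (grepl("^(sens|spec|ppv|npv)", col)) {
      out[[col]] <- round(100 * out[[col]], 1)
    } else if (grepl("^(lr_|auc)", col)) {
      out[[col]] <- round(out[[col]], 2)
    }
  }
  out
}

#' Write a report bundle to disk
#'
#' @param bundle A `report_bundle` from [run_pipeline()].
#' @param outdir Directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_report_bundle <- function(bundle, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    utils::write.csv(df, file.path(outdir, paste0(name, ".csv")),
                     row.names = FALSE, na = "")
  }
  fr <- bundle$feature_report
  fr$ppv <- round(100 * fr$ppv, 1); fr$npv <- round(100 * fr$npv, 1)
  w(fr, "feature_report")
  w(round_panel(bundle$panel_appendicitis), "panel_appendicitis")
  w(round_panel(bundle$panel_perforation), "panel_perforation")
  mp <- bundle$missed_perforation
  mp$sens_perforation <- round(100 * mp$sens_perforation, 1)
  mp$missed_pct <- round(mp$missed_pct, 1)
  w(mp, "missed_perforation")
  w(bundle$excluded, "excluded")
  json <- list(
    seed = bundle$seed, n_input = bundle$n_input,
    n_evaluated = bundle$n_evaluated, n_excluded = bundle$n_excluded,
    feature_report = bundle$feature_report,
    panel_appendicitis = bundle$panel_appendicitis,
    panel_perforation = bundle$panel_perforation,
    missed_perforation = bundle$missed_perforation,
    confusions = lapply(bundle$confusions, function(cm) {
      list(dichotomy = cm$dichotomy, tp = cm$tp, fp = cm$fp, fn = cm$fn,
           tn = cm$tn)
    })
  )
  jsonlite::write_json(json, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
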