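#' Build a 2x2 confusion matrix from predictions and outcomes
#'
#' @param predictions Logical (or 0/1) vector of test results.
#' @param outcomes Logical (or 0/1) vector of true condition status, same
#'   length.
#' @param dichotomy Label describing the condition dichotomy (e.g.
#'   `"appendicitis"` or `"perforation"`).
#' @return An object of class `confusion_matrix` with integer fields `tp`,
#'   `fp`, `fn`, `tn` and the `dichotomy` label.
#' @examples
#' confusion(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
#' @export
confusion <- function(predictions, outcomes, dichotomy = "appendicitis") {
  if (length(predictions) != length(outcomes)) {
    stop2("predictions and outcomes must have the same length")
  }
  if (length(predictions) == 0) stop2("empty input")
  p <- as.logical(predictions)
  o <- as.logical(outcomes)
  if (anyNA(p) || anyNA(o)) stop2("predictions/outcomes must not contain NA")
  structure(
    list(tp = sum(p & o), fp = sum(p & !o), fn = sum(!p & o),
         tn = sum(!p & !o), dichotomy = dichotomy),
    class = "confusion_matrix"
  )
}

#' Construct a confusion matrix from known cell counts
#'
#' @param tp,fp,fn,tn Non-negative integer cell counts.
#' @inheritParams confusion
#' @return A `confusion_matrix`.
#' @export
confusion_counts <- function(tp, fp, fn, tn, dichotomy = "appendicitis") {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop2("cell counts must be non-negative integers")
  }
  cells <- as.integer(cells)
  structure(list(tp = cells[1], fp = cells[2], fn = cells[3],
                 tn = cells[4], dichotomy = dichotomy),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> (%s)\n", x$dichotomy))
  print(matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
               dimnames = list(c("test+", "test-"), c("cond+", "cond-"))))
  invisible(x)
}

# Wilson score interval for a binomial proportion; returns c(lower, upper).
wilson_ci <- function(k, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, center - half), min(1, center + half))
}

# Log-method (Simel) confidence interval for a likelihood ratio.
lr_ci <- function(lr, num_k, num_n, den_k, den_n, conf = 0.95) {
  if (!is.finite(lr) || lr <= 0 || num_k == 0 || den_k == 0) {
    return(c(NA_real_, NA_real_))
  }
  z <- stats::qnorm(1 - (1 - conf) / 2)
  se <- sqrt(1 / num_k - 1 / num_n + 1 / den_k - 1 / den_n)
  exp(log(lr) + c(-1, 1) * z * se)
}

#' Likelihood ratios from sensitivity and specificity
#'
#' `lr_pos = sens / (1 - spec)`, `lr_neg = (1 - sens) / spec`. Boundary
#' specificities make the corresponding ratio undefined and it is returned
#' as `NA`, never coerced to 0 or infinity.
#'
#' @param sens,spec Proportions in [0, 1].
#' @return Named numeric vector `c(lr_pos, lr_neg)`.
#' @examples
#' lr_from_sens_spec(0.679, 0.787)  # LR+ about 3.19
#' @export
lr_from_sens_spec <- function(sens, spec) {
  stopifnot(sens >= 0, sens <= 1, spec >= 0, spec <= 1)
  c(lr_pos = if (spec < 1) sens / (1 - spec) else NA_real_,
    lr_neg = if (spec > 0) (1 - sens) / spec else NA_real_)
}

#' Predictive values from sensitivity, specificity and prevalence
#'
#' Bayes' identity:
#' `ppv = sens p / (sens p + (1 - spec)(1 - p))` and
#' `npv = spec (1 - p) / (spec (1 - p) + (1 - sens) p)`.
#'
#' @param sens,spec Proportions in [0, 1].
#' @param prevalence Condition prevalence in (0, 1); the degenerate values 0
#'   and 1 yield `NA` predictive values.
#' @return Named numeric vector `c(ppv, npv)`.
#' @examples
#' ppv_npv_from_sens_spec_prev(0.679, 0.787, 336 / 463)  # ppv about 0.894
#' @export
ppv_npv_from_sens_spec_prev <- function(sens, spec, prevalence) {
  stopifnot(sens >= 0, sens <= 1, spec >= 0, spec <= 1,
            prevalence >= 0, prevalence <= 1)
  if (prevalence <= 0 || prevalence >= 1) {
    return(c(ppv = NA_real_, npv = NA_real_))
  }
  p <- prevalence
  ppv_den <- sens * p + (1 - spec) * (1 - p)
  npv_den <- spec * (1 - p) + (1 - sens) * p
  c(ppv = if (ppv_den > 0) sens * p / ppv_den else NA_real_,
    npv = if (npv_den > 0) spec * (1 - p) / npv_den else NA_real_)
}

#' Missed cases implied by a sensitivity
#'
#' The counterfactual "if only test-positive children had surgery": with a
#' sensitivity `sens` among `n_cases` true cases, `(1 - sens) * n_cases`
#' cases (rounded half away from zero) would have been missed.
#'
#' @param sens Sensitivity in [0, 1].
#' @param n_cases Number of true cases (>= 0).
#' @return Named vector `c(missed_count, missed_fraction)`;
#'   the fraction is `NA` when `n_cases` is 0.
#' @examples
#' missed_cases(0.402, 102)  # 61 missed, 59.8%
#' @export
missed_cases <- function(sens, n_cases) {
  stopifnot(sens >= 0, sens <= 1, n_cases >= 0)
  m <- round_half_away((1 - sens) * n_cases)
  c(missed_count = m,
    missed_fraction = if (n_cases > 0) m / n_cases else NA_real_)
}

#' Area under the ROC curve over integer score totals
#'
#' Trapezoidal ROC over all thresholds, with tied case/control totals given
#' half credit; equivalently the Mann-Whitney statistic
#' `P(case > control) + 0.5 P(case = control)`.
#'
#' @param totals Numeric score totals.
#' @param outcomes Logical condition status, same length.
#' @return AUC in [0, 1]; `NA` if either class is empty.
#' @export
roc_auc <- function(totals, outcomes) {
  o <- as.logical(outcomes)
  stopifnot(length(totals) == length(o))
  n1 <- sum(o); n0 <- sum(!o)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(totals)
  (sum(r[o]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong variance of the AUC via placement values.
delong_auc_ci <- function(totals, outcomes, conf = 0.95) {
  o <- as.logical(outcomes)
  x <- totals[o]; y <- totals[!o]
  m <- length(x); n <- length(y)
  auc <- roc_auc(totals, o)
  if (m < 2 || n < 2) return(c(NA_real_, NA_real_))
  v10 <- vapply(x, function(xi) mean((xi > y) + 0.5 * (xi == y)), numeric(1))
  v01 <- vapply(y, function(yj) mean((x > yj) + 0.5 * (x == yj)), numeric(1))
  se <- sqrt(stats::var(v10) / m + stats::var(v01) / n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  c(max(0, auc - z * se), min(1, auc + z * se))
}

#' AUC of a binary (positive/negative) classifier
#'
#' With only a dichotomous test result the ROC has a single interior point
#' and the trapezoidal area reduces to `(sens + spec) / 2`. Exposed for
#' completeness; it is *not* the AUC of the underlying graded score.
#'
#' @param sens,spec Proportions in [0, 1].
#' @return The two-point AUC.
#' @export
two_point_auc <- function(sens, spec) {
  stopifnot(sens >= 0, sens <= 1, spec >= 0, spec <= 1)
  (sens + spec) / 2
}

#' Full diagnostic-performance panel from a confusion matrix
#'
#' Computes sensitivity, specificity, PPV, NPV, LR+ and LR-, each with a 95%
#' confidence interval, plus the ROC-AUC over graded score totals when
#' supplied. Proportion CIs use the Wilson score method, LR CIs the log
#' method, and the AUC CI the DeLong variance; alternatively all CIs can be
#' obtained by a seeded nonparametric bootstrap. A statistic with a zero
#' denominator is reported as `NA` (undefined), never as 0.
#'
#' @param cm A [confusion()] matrix.
#' @param totals Optional per-patient score totals (for the AUC).
#' @param outcomes Condition status aligned with `totals`; required when
#'   `totals` is given.
#' @param ci `"wilson"` (analytic; default) or `"bootstrap"` (percentile,
#'   `boot` resamples). Bootstrap requires `totals`/`outcomes` plus
#'   `predictions` so patient-level resampling is possible.
#' @param predictions Patient-level test results, required for
#'   `ci = "bootstrap"`.
#' @param conf Confidence level (default 0.95).
#' @param boot Number of bootstrap resamples (default 2000).
#' @param seed RNG seed for the bootstrap.
#' @return A one-row `data.frame` of class `diagnostic_panel` with columns
#'   `<stat>`, `<stat>_lo`, `<stat>_hi` for sens, spec, ppv, npv, lr_pos,
#'   lr_neg, auc, plus `n_evaluated` and `dichotomy`.
#' @examples
#' cm <- confusion_counts(tp = 263, fp = 27, fn = 73, tn = 93)
#' diagnostic_panel(cm)
#' @export
diagnostic_panel <- function(cm, totals = NULL, outcomes = NULL,
                             ci = c("wilson", "bootstrap"),
                             predictions = NULL, conf = 0.95, boot = 2000,
                             seed = NULL) {
  ci <- match.arg(ci)
  stopifnot(inherits(cm, "confusion_matrix"))
  tp <- cm$tp; fp <- cm$fp; fn <- cm$fn; tn <- cm$tn
  if (tp + fn == 0 || fp + tn == 0) {
    stop2("both condition classes must be non-empty")
  }
  prop <- function(k, n) if (n > 0) k / n else NA_real_
  est <- list(
    sens = prop(tp, tp + fn), spec = prop(tn, tn + fp),
    ppv = prop(tp, tp + fp), npv = prop(tn, tn + fn)
  )
  lrs <- lr_from_sens_spec(est$sens, est$spec)
  est$lr_pos <- unname(lrs["lr_pos"]); est$lr_neg <- unname(lrs["lr_neg"])
  est$auc <- if (!is.null(totals)) {
    if (is.null(outcomes)) stop2("outcomes required alongside totals")
    roc_auc(totals, outcomes)
  } else NA_real_

  if (ci == "wilson") {
    cis <- list(
      sens = wilson_ci(tp, tp + fn, conf), spec = wilson_ci(tn, tn + fp, conf),
      ppv = wilson_ci(tp, tp + fp, conf), npv = wilson_ci(tn, tn + fn, conf),
      lr_pos = lr_ci(est$lr_pos, tp, tp + fn, fp, fp + tn, conf),
      lr_neg = lr_ci(est$lr_neg, fn, tp + fn, tn, fp + tn, conf),
      auc = if (!is.null(totals)) delong_auc_ci(totals, outcomes, conf)
            else c(NA_real_, NA_real_)
    )
  } else {
    if (is.null(predictions) || is.null(outcomes)) {
      stop2("bootstrap CIs need patient-level predictions and outcomes")
    }
    cis <- bootstrap_panel_cis(predictions, outcomes, totals, conf, boot, seed)
  }
  row <- data.frame(
    dichotomy = cm$dichotomy, n_evaluated = tp + fp + fn + tn,
    stringsAsFactors = FALSE
  )
  for (s in names(est)) {
    row[[s]] <- est[[s]]
    row[[paste0(s, "_lo")]] <- cis[[s]][1]
    row[[paste0(s, "_hi")]] <- cis[[s]][2]
  }
  class(row) <- c("diagnostic_panel", "data.frame")
  row
}

bootstrap_panel_cis <- function(predictions, outcomes, totals, conf, boot,
                                seed) {
  p <- as.logical(predictions); o <- as.logical(outcomes)
  n <- length(p)
  stats_one <- function(idx) {
    pi <- p[idx]; oi <- o[idx]
    tp <- sum(pi & oi); fp <- sum(pi & !oi)
    fn <- sum(!pi & oi); tn <- sum(!pi & !oi)
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA
    spec <- if (tn + fp > 0) tn / (tn + fp) else NA
    c(sens = sens, spec = spec,
      ppv = if (tp + fp > 0) tp / (tp + fp) else NA,
      npv = if (tn + fn > 0) tn / (tn + fn) else NA,
      lr_pos = if (!is.na(spec) && spec < 1) sens / (1 - spec) else NA,
      lr_neg = if (!is.na(spec) && spec > 0) (1 - sens) / spec else NA,
      auc = if (!is.null(totals)) roc_auc(totals[idx], oi) else NA)
  }
  draws <- with_seed(seed, {
    vapply(seq_len(boot), function(b) stats_one(sample.int(n, n, TRUE)),
           numeric(7))
  })
  alpha <- (1 - conf) / 2
  out <- apply(draws, 1, stats::quantile, probs = c(alpha, 1 - alpha),
               na.rm = TRUE)
  lapply(stats::setNames(colnames(out), colnames(out)),
         function(s) unname(out[, s]))
}

#' @export
print.diagnostic_panel <- function(x, ...) {
  fmt_pct <- function(e, lo, hi) {
    sprintf("%.1f (%.1f-%.1f)", 100 * e, 100 * lo, 100 * hi)
  }
  fmt_num <- function(e, lo, hi) sprintf("%.2f (%.2f-%.2f)", e, lo, hi)
  cat(sprintf("<diagnostic_panel> %s, n = %d\n", x$dichotomy, x$n_evaluated))
  for (s in c("sens", "spec", "ppv", "npv")) {
    cat(sprintf("  %-6s %s\n", s, fmt_pct(x[[s]], x[[paste0(s, "_lo")]],
                                          x[[paste0(s, "_hi")]])))
  }
  for (s in c("lr_pos", "lr_neg", "auc")) {
    if (!is.na(x[[s]])) {
      cat(sprintf("  %-6s %s\n", s, fmt_num(x[[s]], x[[paste0(s, "_lo")]],
                                            x[[paste0(s, "_hi")]])))
    }
  }
  invisible(x)
}

#' Invert a published feature row into an implied 2x2 table
#'
#' Cohort summaries often report, per clinical feature, only the number of
#' patients in whom it was present plus its PPV and NPV. Those three numbers
#' imply a full 2x2 table: `tp = round(ppv * present)`,
#' `fp = present - tp`, `tn = round(npv * (total - present))`,
#' `fn = (total - present) - tn` (rounding half away from zero; FP/FN by
#' subtraction so the margins are preserved). The implied case count
#' `tp + fn` is compared with the independently reported case count and the
#' discrepancy is surfaced as `consistency_gap` — reported, never silently
#' corrected.
#'
#' @param present Number of patients with the feature present (0 < present <
#'   total).
#' @param total Number of patients assessed.
#' @param ppv,npv Reported predictive values, proportions in [0, 1].
#' @param reported_cases Independently reported number of condition-positive
#'   patients.
#' @return A list of class `feature_row`: `present`, `total`, `ppv`, `npv`,
#'   implied `tp`, `fp`, `fn`, `tn`, `implied_cases`, and `consistency_gap`.
#' @examples
#' invert_feature_row(319, 463, 0.815, 0.453, 336)  # gap 3
#' @export
invert_feature_row <- function(present, total, ppv, npv, reported_cases) {
  stopifnot(present > 0, present < total, ppv >= 0, ppv <= 1,
            npv >= 0, npv <= 1, reported_cases >= 0)
  absent <- total - present
  tp <- round_half_away(ppv * present)
  fp <- present - tp
  tn <- round_half_away(npv * absent)
  fn <- absent - tn
  if (min(tp, fp, tn, fn) < 0) stop2("inversion yields a negative cell")
  structure(
    list(present = as.integer(present), total = as.integer(total),
         ppv = ppv, npv = npv, tp = as.integer(tp), fp = as.integer(fp),
         fn = as.integer(fn), tn = as.integer(tn),
         implied_cases = as.integer(tp + fn),
         consistency_gap = as.integer(abs(tp + fn - reported_cases))),
    class = "feature_row"
  )
}

#' @export
print.feature_row <- function(x, ...) {
  cat(sprintf(
    "<feature_row> present %d/%d; implied tp=%d fp=%d fn=%d tn=%d; gap %d\n",
    x$present, x$total, x$tp, x$fp, x$fn, x$tn, x$consistency_gap))
  invisible(x)
}
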