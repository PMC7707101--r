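# Fixtures built in code: patients with fully recorded labs so that score
# positivity is driven solely by the named items.

# A complete patient with every item negative; flip items on via `...`
# (logical clinical findings, or raw lab overrides).
blank_patient <- function(id = "p1", outcome = "no_appendicitis", ...) {
  args <- list(...)
  base <- list(
    id = id, age = 10, sex = "male", duration_h = 24,
    continuous_pain = FALSE, nausea_vomiting = FALSE, anorexia = FALSE,
    migration_of_pain = FALSE, tenderness_rlq = FALSE,
    rebound_tenderness = FALSE, cough_hop_tenderness = FALSE,
    temperature_c = 37.0, wbc = 8, neutrophils_abs = 4,
    neutrophils_pct = 60, crp = 5, us_appendicitis = FALSE,
    outcome = outcome
  )
  base[names(args)] <- args
  do.call(patient_record, base)
}

# Patient whose derived feature vector equals a named 0/1 vector over
# score_features (unnamed features default to 0).
patient_with_features <- function(ind, id = "p1",
                                  outcome = "no_appendicitis") {
  full <- setNames(rep(0L, length(score_features)), score_features)
  full[names(ind)] <- ind
  blank_patient(
    id = id, outcome = outcome,
    continuous_pain = full[["continuous_pain"]] == 1,
    nausea_vomiting = full[["nausea_vomiting"]] == 1,
    anorexia = full[["anorexia"]] == 1,
    migration_of_pain = full[["migration_of_pain"]] == 1,
    tenderness_rlq = full[["tenderness_rlq"]] == 1,
    rebound_tenderness = full[["rebound_tenderness"]] == 1,
    cough_hop_tenderness = full[["cough_hop_tenderness"]] == 1,
    temperature_c = if (full[["fever"]] == 1) 39.2 else 37.0,
    wbc = if (full[["wbc_high"]] == 1) 14 else 8,
    neutrophils_abs = if (full[["neutrophilia"]] == 1) 9.5 else 4,
    neutrophils_pct = if (full[["neutrophilia"]] == 1) 85 else 60,
    crp = if (full[["crp_high"]] == 1) 45 else 5,
    us_appendicitis = full[["us_appendicitis"]] == 1
  )
}

# Bind several one-row patients into a cohort.
bind_patients <- function(...) do.call(rbind, list(...))

# Cohort realizing an exact Alvarado confusion matrix: positives carry
# tenderness (2) + WBC (2) + nausea (1) = 5 points, negatives 0 points.
alvarado_cohort <- function(tp, fp, fn, tn) {
  pos <- c(tenderness_rlq = 1L, wbc_high = 1L, nausea_vomiting = 1L)
  neg <- c(tenderness_rlq = 0L)
  rows <- list()
  add <- function(k, ind, outcome) {
    for (i in seq_len(k)) {
      rows[[length(rows) + 1]] <<- patient_with_features(
        ind, id = sprintf("p%04d", length(rows) + 1), outcome = outcome)
    }
  }
  add(tp, pos, "simple"); add(fp, pos, "no_appendicitis")
  add(fn, neg, "simple"); add(tn, neg, "no_appendicitis")
  do.call(rbind, rows)
}

# Binary feature matrix + labels from a simple planted-rule generative
# model: `signal` features have P(x|case) = p1, P(x|control) = p0; the
# rest are 0.5 in both classes.
planted_features <- function(n, p, signal, p1 = 0.8, p0 = 0.2,
                             prev = 0.5) {
  y <- as.integer(runif(n) < prev)
  x <- matrix(0L, n, p, dimnames = list(NULL, paste0("f", seq_len(p))))
  for (j in seq_len(p)) {
    pr <- if (j %in% signal) ifelse(y == 1, p1, p0) else 0.5
    x[, j] <- as.integer(runif(n) < pr)
  }
  list(x = as.data.frame(x), y = y)
}

# Cohort whose label follows a noisy OR of two features -- a rule a depth-2
# tree can express exactly.
or_rule_features <- function(n, p = 6, signal = c(1, 4), hi = 0.95,
                             lo = 0.05) {
  x <- matrix(rbinom(n * p, 1, 0.4), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  pr <- ifelse(x[, signal[1]] == 1 | x[, signal[2]] == 1, hi, lo)
  list(x = as.data.frame(x), y = as.integer(runif(n) < pr))
}

# Exhaustive search over all depth<=2 trees on binary features: returns the
# best achievable training accuracy. Independent oracle for fit_cart.
best_depth2_accuracy <- function(x, y) {
  x <- as.matrix(x)
  n <- length(y)
  acc_leaf <- function(idx) {
    if (length(idx) == 0) return(0)
    max(sum(y[idx]), sum(1 - y[idx]))
  }
  split_acc <- function(idx, j) {
    right <- idx[x[idx, j] == 1]
    left <- idx[x[idx, j] == 0]
    acc_leaf(left) + acc_leaf(right)
  }
  best <- acc_leaf(seq_len(n))  # stump
  for (r in seq_len(ncol(x))) {
    left <- which(x[, r] == 0)
    right <- which(x[, r] == 1)
    # each child: leaf or best single split
    left_best <- max(acc_leaf(left),
                     if (length(left)) vapply(seq_len(ncol(x)), split_acc,
                                              numeric(1), idx = left) else 0)
    right_best <- max(acc_leaf(right),
                      if (length(right)) vapply(seq_len(ncol(x)), split_acc,
                                                numeric(1), idx = right)
                      else 0)
    best <- max(best, left_best + right_best)
  }
  best / n
}
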