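#' Derive a unit-weight score from a cohort by CART or random forest
#'
#' Re-implements the score-development procedure: the cohort is repeatedly
#' split 70/30 into training and test sets; a CART tree or a random forest
#' is fitted on each training split; per-feature importances are averaged
#' over the repeats; features whose mean importance reaches
#' `importance_floor` are retained and assembled into a unit-weight
#' additive score; the positivity cutoff is the value maximizing the Youden
#' index (sens + spec - 1) of the unit score on the pooled test splits
#' (ties broken toward the lower, more sensitive cutoff). Per-repeat test
#' metrics of the resulting score are reported.
#'
#' @param cohort A cohort `data.frame` with known outcomes; must be
#'   complete-case for every candidate feature.
#' @param candidates Character vector of candidate features (default: all of
#'   [score_features]).
#' @param method `"forest"` (default) or `"cart"`.
#' @param importance_floor Minimum mean normalized importance for a feature
#'   to enter the derived score (default 0.05).
#' @param repeats Number of random train/test splits (default 20).
#' @param train_fraction Fraction of patients used for training
#'   (default 0.7).
#' @param dichotomy Outcome dichotomy the score is derived for:
#'   `"appendicitis"` (simple or perforated vs none).
#' @param name Name given to the derived [score_definition()].
#' @param policy [threshold_policy()] used to derive the items.
#' @param seed Master RNG seed; each repeat uses a sub-seed derived from it.
#' @param n_trees,mtry Forest size parameters (see [fit_forest()]).
#' @param min_leaf,complexity CART parameters (see [fit_cart()]).
#' @return An object of class `derivation_result`:
#'   \describe{
#'     \item{importance}{`data.frame` of mean (and SD) importance per
#'       candidate, sorted decreasing.}
#'     \item{selected}{Retained feature names.}
#'     \item{definition}{The derived unit-weight [score_definition()].}
#'     \item{cutoff_search}{Youden index of each candidate cutoff on the
#'       pooled test splits.}
#'     \item{test_metrics}{Per-repeat sensitivity/specificity/accuracy of
#'       the derived score on its test split.}
#'   }
#' @examples
#' cohort <- generate_cohort(cohort_parameters(n_total = 300, seed = 7))
#' dr <- derive_score(cohort, method = "forest", repeats = 3, n_trees = 25,
#'                    seed = 7)
#' dr$selected
#' @export
derive_score <- function(cohort, candidates = score_features,
                         method = c("forest", "cart"),
                         importance_floor = 0.05, repeats = 20,
                         train_fraction = 0.7,
                         dichotomy = "appendicitis",
                         name = paste0("derived_", method[1]),
                         policy = threshold_policy(), seed = NULL,
                         n_trees = 200, mtry = NULL,
                         min_leaf = 5L, complexity = 0.01) {
  method <- match.arg(method)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop2("train_fraction must lie in (0, 1)")
  }
  if (repeats < 1) stop2("repeats must be >= 1")
  stopifnot(all(candidates %in% score_features))
  validate_cohort(cohort)
  if (anyNA(cohort$outcome)) stop2("cohort outcomes must all be known")
  fv <- derive_features(cohort, policy)
  x <- fv[candidates]
  if (anyNA(x)) {
    stop2("cohort must be complete-case for all candidate features")
  }
  y <- as.integer(cohort$outcome %in% c("simple", "perforated"))
  if (length(unique(y)) < 2) stop2("need both outcome classes to derive")
  n <- nrow(x)
  n_train <- max(1L, round(train_fraction * n))
  seeds <- derive_seeds(seed, repeats)

  imp <- matrix(NA_real_, repeats, length(candidates),
                dimnames = list(NULL, candidates))
  test_idx <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    idx <- with_seed(seeds[[r]], sample.int(n, n_train))
    test_idx[[r]] <- setdiff(seq_len(n), idx)
    fit <- if (method == "forest") {
      fit_forest(x[idx, , drop = FALSE], y[idx], n_trees = n_trees,
                 mtry = mtry, seed = seeds[[r]])
    } else {
      fit_cart(x[idx, , drop = FALSE], y[idx], min_leaf = min_leaf,
               complexity = complexity)
    }
    imp[r, ] <- fit$importance[candidates]
  }
  mean_imp <- colMeans(imp)
  ord <- order(mean_imp, decreasing = TRUE)
  imp_table <- data.frame(feature = candidates[ord],
                          importance = unname(mean_imp[ord]),
                          importance_sd = unname(apply(imp, 2,
                                                       stats::sd))[ord],
                          stringsAsFactors = FALSE)
  selected <- imp_table$feature[imp_table$importance >= importance_floor]
  if (length(selected) == 0) {
    stop2("no candidate feature reached the importance floor (",
          importance_floor, "); the candidates carry no detectable signal")
  }

  # unit-weight totals on the pooled test splits; Youden-optimal cutoff
  totals <- as.matrix(x[selected]) %*% rep(1L, length(selected))
  pooled_idx <- unlist(test_idx)
  pooled_tot <- totals[pooled_idx]
  pooled_y <- y[pooled_idx]
  cutoffs <- seq_len(length(selected))
  youden <- vapply(cutoffs, function(cut) {
    pred <- pooled_tot >= cut
    sens <- sum(pred & pooled_y == 1) / sum(pooled_y == 1)
    spec <- sum(!pred & pooled_y == 0) / sum(pooled_y == 0)
    sens + spec - 1
  }, numeric(1))
  best_cut <- cutoffs[which.max(youden)]  # ties -> lower (more sensitive)
  if (max(youden) <= 0) {
    stop2("the derived unit-weight score performs no better than chance on ",
          "the pooled test splits; the candidate features carry no ",
          "detectable signal")
  }

  definition <- score_definition(
    name, stats::setNames(rep(1L, length(selected)), selected), best_cut,
    policy
  )
  test_metrics <- do.call(rbind, lapply(seq_len(repeats), function(r) {
    ti <- test_idx[[r]]
    pred <- totals[ti] >= best_cut
    yt <- y[ti]
    data.frame(
      repeat_id = r,
      n_test = length(ti),
      sens = if (any(yt == 1)) sum(pred & yt == 1) / sum(yt == 1)
             else NA_real_,
      spec = if (any(yt == 0)) sum(!pred & yt == 0) / sum(yt == 0)
             else NA_real_,
      accuracy = mean((totals[ti] >= best_cut) == (yt == 1))
    )
  }))
  structure(
    list(method = method, importance = imp_table, selected = selected,
         definition = definition,
         cutoff_search = data.frame(cutoff = cutoffs, youden = youden),
         test_metrics = test_metrics, repeats = repeats,
         dichotomy = dichotomy, seed = seed),
    class = "derivation_result"
  )
}

#' @export
print.derivation_result <- function(x, ...) {
  cat(sprintf("<derivation_result> method = %s, %d repeat(s)\n",
              x$method, x$repeats))
  cat("  importance ranking:\n")
  for (i in seq_len(nrow(x$importance))) {
    r <- x$importance[i, ]
    cat(sprintf("    %-22s %.3f%s\n", r$feature, r$importance,
                if (r$feature %in% x$selected) "  *selected*" else ""))
  }
  cat(sprintf("  derived score: %s, cutoff %d of %d\n", x$definition$name,
              x$definition$positivity_cutoff, x$definition$max_score))
  cat(sprintf("  mean test sens %.3f, spec %.3f\n",
              mean(x$test_metrics$sens, na.rm = TRUE),
              mean(x$test_metrics$spec, na.rm = TRUE)))
  invisible(x)
}
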