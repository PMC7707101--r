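#' Fit a bagged random forest of classification trees
#'
#' Each of `n_trees` trees is grown on a bootstrap resample of the patients
#' (sample size n, with replacement), with `mtry` candidate features drawn
#' uniformly at each split; trees are grown to purity (`min_leaf = 1`, no
#' pruning) as is conventional for classification forests. Prediction
#' averages the per-tree leaf probabilities; feature importance is the mean
#' decrease in Gini impurity (each split's impurity reduction weighted by
#' the fraction of its tree's sample reaching the node), averaged over
#' trees and normalized to sum to 1. A fixed seed makes the fit fully
#' reproducible.
#'
#' @param features Complete 0/1 feature `data.frame`/matrix.
#' @param labels Binary outcome vector.
#' @param n_trees Number of trees (default 200).
#' @param mtry Candidate features per split (default `ceiling(sqrt(p))`).
#' @param min_leaf Minimum samples per leaf (default 1).
#' @param bootstrap Draw a bootstrap resample per tree (default `TRUE`);
#'   with `bootstrap = FALSE` and `mtry = p` a one-tree forest degenerates
#'   to a single unpruned CART fit.
#' @param seed RNG seed.
#' @return An object of class `random_forest` with the tree list, per-tree
#'   bootstrap indices, normalized `importance`, and an out-of-bag error
#'   estimate `oob_error` (majority vote over trees not trained on the
#'   patient; `NA` when `bootstrap = FALSE`).
#' @examples
#' fv <- data.frame(a = rep(0:1, each = 20), b = rbinom(40, 1, 0.5))
#' rf <- fit_forest(fv, labels = rep(0:1, each = 20), n_trees = 25, seed = 1)
#' rf$importance
#' @export
fit_forest <- function(features, labels, n_trees = 200,
                       mtry = NULL, min_leaf = 1L, bootstrap = TRUE,
                       seed = NULL) {
  x <- as_feature_matrix(features)
  y <- as_binary_labels(labels)
  stopifnot(nrow(x) == length(y), n_trees >= 1)
  p <- ncol(x)
  if (is.null(mtry)) mtry <- ceiling(sqrt(p))
  if (mtry > p) stop2("mtry (", mtry, ") exceeds the feature count (", p, ")")
  n <- nrow(x)
  with_seed(seed, {
    trees <- vector("list", n_trees)
    boot_idx <- vector("list", n_trees)
    imp <- matrix(0, n_trees, p, dimnames = list(NULL, colnames(x)))
    oob_votes <- matrix(0L, n, 2L)
    for (t in seq_len(n_trees)) {
      idx <- if (bootstrap) sample.int(n, n, replace = TRUE) else seq_len(n)
      tree <- grow_tree(x[idx, , drop = FALSE], y[idx],
                        min_leaf = as.integer(min_leaf), mtry = mtry)
      trees[[t]] <- tree
      boot_idx[[t]] <- idx
      imp[t, ] <- tree_importance(tree, colnames(x))
      if (bootstrap) {
        oob <- setdiff(seq_len(n), idx)
        if (length(oob) > 0) {
          leaf <- descend(tree, x[oob, , drop = FALSE])
          pred <- as.integer(tree$n1[leaf] / tree$n[leaf] >= 0.5)
          oob_votes[cbind(oob, pred + 1L)] <-
            oob_votes[cbind(oob, pred + 1L)] + 1L
        }
      }
    }
    mean_imp <- colMeans(imp)
    if (sum(mean_imp) > 0) mean_imp <- mean_imp / sum(mean_imp)
    seen <- rowSums(oob_votes) > 0
    oob_error <- if (bootstrap && any(seen)) {
      oob_pred <- ifelse(oob_votes[, 2] > oob_votes[, 1], 1L, 0L)
      mean(oob_pred[seen] != y[seen])
    } else {
      NA_real_
    }
    structure(
      list(trees = trees, boot_idx = boot_idx,
           feature_names = colnames(x), n_trees = n_trees, mtry = mtry,
           min_leaf = as.integer(min_leaf), bootstrap = bootstrap,
           importance = mean_imp, oob_error = oob_error, seed = seed),
      class = "random_forest"
    )
  })
}

#' @export
print.random_forest <- function(x, ...) {
  cat(sprintf("<random_forest> %d trees, mtry = %d%s\n", x$n_trees, x$mtry,
              if (is.na(x$oob_error)) ""
              else sprintf(", OOB error %.3f", x$oob_error)))
  top <- sort(x$importance, decreasing = TRUE)
  top <- top[top > 0]
  if (length(top) > 0) {
    cat("  importance:",
        paste(sprintf("%s=%.3f", names(top), top), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Predict from a fitted random forest
#'
#' @param object A `random_forest`.
#' @param newdata Feature `data.frame`/matrix.
#' @param type `"prob"` for the across-tree mean case-probability,
#'   `"class"` for the 0/1 label at the 0.5 threshold.
#' @param ... Unused.
#' @return Numeric or integer vector.
#' @export
predict.random_forest <- function(object, newdata,
                                  type = c("prob", "class"), ...) {
  type <- match.arg(type)
  x <- as_feature_matrix(newdata)
  missing_f <- setdiff(object$feature_names, colnames(x))
  if (length(missing_f) > 0) {
    stop2("newdata lacks feature(s): ", paste(missing_f, collapse = ", "))
  }
  x <- x[, object$feature_names, drop = FALSE]
  acc <- numeric(nrow(x))
  for (tree in object$trees) {
    leaf <- descend(tree, x)
    acc <- acc + tree$n1[leaf] / tree$n[leaf]
  }
  prob <- acc / object$n_trees
  if (type == "prob") prob else as.integer(prob >= 0.5)
}

#' Permutation importance of a fitted forest
#'
#' Alternative to the default Gini importance: the out-of-bag decrease in
#' accuracy when one feature's values are permuted, averaged over trees.
#'
#' @param forest A `random_forest` fitted with `bootstrap = TRUE`.
#' @param features,labels The training data the forest was fitted on.
#' @param seed RNG seed for the permutations.
#' @return Named numeric vector (not normalized; may contain small
#'   negatives for irrelevant features).
#' @export
permutation_importance <- function(forest, features, labels, seed = NULL) {
  stopifnot(inherits(forest, "random_forest"))
  if (!forest$bootstrap) stop2("permutation importance needs bootstrap trees")
  x <- as_feature_matrix(features)[, forest$feature_names, drop = FALSE]
  y <- as_binary_labels(labels)
  n <- nrow(x)
  with_seed(seed, {
    drop <- matrix(NA_real_, forest$n_trees, ncol(x),
                   dimnames = list(NULL, colnames(x)))
    for (t in seq_len(forest$n_trees)) {
      tree <- forest$trees[[t]]
      oob <- setdiff(seq_len(n), forest$boot_idx[[t]])
      if (length(oob) < 2) next
      xo <- x[oob, , drop = FALSE]
      leaf <- descend(tree, xo)
      base_acc <- mean(as.integer(tree$n1[leaf] / tree$n[leaf] >= 0.5) ==
                         y[oob])
      for (f in seq_len(ncol(x))) {
        xp <- xo
        xp[, f] <- xp[sample.int(length(oob)), f]
        leaf_p <- descend(tree, xp)
        perm_acc <- mean(as.integer(tree$n1[leaf_p] / tree$n[leaf_p] >= 0.5)
                         == y[oob])
        drop[t, f] <- base_acc - perm_acc
      }
    }
    colMeans(drop, na.rm = TRUE)
  })
}
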