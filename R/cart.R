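# Classification trees over binary clinical items, grown with Gini
# splitting and pruned by cost-complexity. Trees are stored flat (parallel
# vectors indexed by node id) so prediction vectorizes.

gini_impurity <- function(n1, n) {
  p <- n1 / n
  2 * p * (1 - p)
}

# Grow a classification tree on a 0/1 feature matrix.
# Returns parallel node vectors; `gain` holds each split's impurity decrease
# weighted by n_node / n_root (the Gini importance contribution).
grow_tree <- function(x, y, min_leaf = 1L, max_depth = Inf, mtry = NULL) {
  n_root <- length(y)
  p <- ncol(x)
  env <- new.env(parent = emptyenv())
  env$feature <- integer(0); env$left <- integer(0); env$right <- integer(0)
  env$n <- integer(0); env$n1 <- integer(0); env$gain <- numeric(0)
  new_node <- function() {
    i <- length(env$n) + 1L
    env$feature[i] <- NA_integer_; env$left[i] <- NA_integer_
    env$right[i] <- NA_integer_; env$n[i] <- 0L; env$n1[i] <- 0L
    env$gain[i] <- 0
    i
  }
  build <- function(idx, depth, avail) {
    node <- new_node()
    nn <- length(idx)
    n1 <- sum(y[idx])
    env$n[node] <- nn; env$n1[node] <- n1
    if (n1 == 0L || n1 == nn || depth >= max_depth || nn < 2L * min_leaf ||
        length(avail) == 0L) {
      return(node)
    }
    # With mtry set (forest mode) candidates are drawn from all features,
    # as in conventional random forests; a feature already used on the path
    # can be drawn but never wins (its repeated binary split has zero gain),
    # so the no-reuse invariant still holds.
    cand <- if (!is.null(mtry)) {
      if (mtry < p) sort(sample.int(p, mtry)) else seq_len(p)
    } else {
      avail
    }
    cand <- intersect(cand, avail)
    if (length(cand) == 0L) return(node)
    xs <- x[idx, cand, drop = FALSE]
    nR <- .colSums(xs, nn, length(cand))
    nR1 <- .colSums(xs * y[idx], nn, length(cand))
    nL <- nn - nR
    nL1 <- n1 - nR1
    ok <- nL >= min_leaf & nR >= min_leaf
    if (!any(ok)) return(node)
    parent_g <- gini_impurity(n1, nn)
    child_g <- ifelse(nL > 0, nL * gini_impurity(nL1, pmax(nL, 1L)), 0) +
      ifelse(nR > 0, nR * gini_impurity(nR1, pmax(nR, 1L)), 0)
    gains <- parent_g - child_g / nn
    gains[!ok] <- -Inf
    best <- which.max(gains)  # ties broken by declaration order
    if (gains[best] <= 1e-12) return(node)
    f <- cand[best]
    env$feature[node] <- f
    env$gain[node] <- gains[best] * nn / n_root
    go_right <- x[idx, f] == 1L
    avail2 <- setdiff(avail, f)  # binary feature: never reused on a path
    env$left[node] <- build(idx[!go_right], depth + 1L, avail2)
    env$right[node] <- build(idx[go_right], depth + 1L, avail2)
    node
  }
  root <- build(seq_len(n_root), 0L, seq_len(p))
  list(feature = env$feature, left = env$left, right = env$right,
       n = env$n, n1 = env$n1, gain = env$gain, root = root,
       n_root = n_root)
}

is_leaf <- function(tree) is.na(tree$feature)

# leaf index reached by each row of newx
descend <- function(tree, newx) {
  node <- rep.int(tree$root, nrow(newx))
  repeat {
    internal <- !is.na(tree$feature[node])
    if (!any(internal)) break
    i <- which(internal)
    f <- tree$feature[node[i]]
    goes_right <- newx[cbind(i, f)] == 1L
    node[i] <- ifelse(goes_right, tree$right[node[i]], tree$left[node[i]])
  }
  node
}

# number of leaves and training-misclassification risk of each subtree,
# computed bottom-up; risks are in units of root-sample fraction
subtree_stats <- function(tree) {
  k <- length(tree$n)
  leaves <- integer(k); risk <- numeric(k)
  node_risk <- pmin(tree$n1, tree$n - tree$n1) / tree$n_root
  # children always have larger ids than parents, so reverse order is
  # bottom-up
  for (i in rev(seq_len(k))) {
    if (is.na(tree$feature[i])) {
      leaves[i] <- 1L
      risk[i] <- node_risk[i]
    } else {
      leaves[i] <- leaves[tree$left[i]] + leaves[tree$right[i]]
      risk[i] <- risk[tree$left[i]] + risk[tree$right[i]]
    }
  }
  list(leaves = leaves, risk = risk, node_risk = node_risk)
}

# Weakest-link cost-complexity pruning: repeatedly collapse the internal
# node with the smallest per-leaf risk improvement g(t) while g(t) < alpha
# (a split must buy at least alpha error reduction per added leaf to stay;
# alpha = 0 therefore keeps the full-grown tree).
prune_tree <- function(tree, alpha) {
  if (alpha <= 0) return(tree)
  repeat {
    st <- subtree_stats(tree)
    internal <- which(!is.na(tree$feature))
    if (length(internal) == 0) break
    g <- (st$node_risk[internal] - st$risk[internal]) /
      (st$leaves[internal] - 1L)
    weakest <- internal[which.min(g)]
    if (min(g) >= alpha) break
    # collapse: descendants become unreachable; clear their gains too
    drop <- collect_descendants(tree, weakest)
    tree$feature[c(weakest, drop)] <- NA_integer_
    tree$gain[c(weakest, drop)] <- 0
    tree$left[weakest] <- NA_integer_
    tree$right[weakest] <- NA_integer_
  }
  tree
}

collect_descendants <- function(tree, node) {
  out <- integer(0)
  stack <- c(tree$left[node], tree$right[node])
  stack <- stack[!is.na(stack)]
  while (length(stack) > 0) {
    cur <- stack[1]; stack <- stack[-1]
    out <- c(out, cur)
    kids <- c(tree$left[cur], tree$right[cur])
    stack <- c(stack, kids[!is.na(kids)])
  }
  out
}

tree_importance <- function(tree, feature_names) {
  imp <- numeric(length(feature_names))
  internal <- which(!is.na(tree$feature))
  for (i in internal) imp[tree$feature[i]] <- imp[tree$feature[i]] + tree$gain[i]
  names(imp) <- feature_names
  imp
}

as_feature_matrix <- function(features) {
  if (is.data.frame(features)) {
    keep <- intersect(score_features, names(features))
    if (length(keep) == 0) keep <- names(features)
    features <- features[keep]
    m <- as.matrix(features)
  } else {
    m <- as.matrix(features)
  }
  if (is.null(colnames(m))) {
    colnames(m) <- paste0("f", seq_len(ncol(m)))
  }
  storage.mode(m) <- "integer"
  if (anyNA(m) || any(m != 0L & m != 1L)) {
    stop2("feature matrix must be complete and binary (0/1)")
  }
  m
}

as_binary_labels <- function(labels) {
  y <- as.integer(as.logical(labels))
  if (anyNA(y)) stop2("labels must be binary with no missing values")
  y
}

#' Fit a classification tree (CART) on binary items
#'
#' Greedy Gini-gain splitting over 0/1 features, with growth stopping at
#' node purity, `min_leaf`, `max_depth`, or feature exhaustion (a binary
#' feature is never reused along a path), followed by weakest-link
#' cost-complexity pruning. Ties in Gini gain are broken by feature
#' declaration order, so the fit is deterministic given its inputs.
#'
#' @param features `data.frame` or matrix of 0/1 items (e.g. from
#'   [derive_features()]); must be complete.
#' @param labels Binary outcome vector (logical or 0/1).
#' @param min_leaf Minimum patients per leaf (default 5).
#' @param complexity Cost-complexity parameter alpha in units of training
#'   misclassification fraction: a split is kept only if it buys at least
#'   `alpha` error reduction per added leaf (default 0.01). `complexity = 0`
#'   keeps the full-grown tree.
#' @param max_depth Optional depth cap (root = depth 0).
#' @return An object of class `cart_tree` with the flat node table, the
#'   feature names, and the normalized Gini `importance` of each feature in
#'   the pruned tree.
#' @examples
#' fv <- data.frame(a = c(0, 0, 1, 1), b = c(0, 1, 0, 1))
#' fit_cart(fv, labels = c(0, 0, 1, 1), min_leaf = 1, complexity = 0)
#' @export
fit_cart <- function(features, labels, min_leaf = 5L, complexity = 0.01,
                     max_depth = Inf) {
  x <- as_feature_matrix(features)
  y <- as_binary_labels(labels)
  stopifnot(nrow(x) == length(y), min_leaf >= 1, complexity >= 0)
  tree <- grow_tree(x, y, min_leaf = as.integer(min_leaf),
                    max_depth = max_depth)
  tree <- prune_tree(tree, complexity)
  imp <- tree_importance(tree, colnames(x))
  if (sum(imp) > 0) imp <- imp / sum(imp)
  structure(
    list(tree = tree, feature_names = colnames(x),
         min_leaf = as.integer(min_leaf), complexity = complexity,
         importance = imp),
    class = "cart_tree"
  )
}

#' @export
print.cart_tree <- function(x, ...) {
  n_int <- sum(!is.na(x$tree$feature))
  cat(sprintf("<cart_tree> %d split(s), %d training samples, cp = %g\n",
              n_int, x$tree$n_root, x$complexity))
  used <- x$importance[x$importance > 0]
  if (length(used) > 0) {
    cat("  importance:",
        paste(sprintf("%s=%.3f", names(sort(used, decreasing = TRUE)),
                      sort(used, decreasing = TRUE)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Predict from a fitted classification tree
#'
#' @param object A `cart_tree`.
#' @param newdata Feature `data.frame`/matrix with the training columns.
#' @param type `"prob"` for leaf case-probabilities, `"class"` for the 0/1
#'   majority label.
#' @param ... Unused.
#' @return Numeric vector of probabilities or integer labels.
#' @export
predict.cart_tree <- function(object, newdata, type = c("prob", "class"),
                              ...) {
  type <- match.arg(type)
  x <- as_feature_matrix(newdata)
  missing_f <- setdiff(object$feature_names, colnames(x))
  if (length(missing_f) > 0) {
    stop2("newdata lacks feature(s): ", paste(missing_f, collapse = ", "))
  }
  x <- x[, object$feature_names, drop = FALSE]
  leaf <- descend(object$tree, x)
  prob <- object$tree$n1[leaf] / object$tree$n[leaf]
  if (type == "prob") prob else as.integer(prob >= 0.5)
}

#' Training accuracy of a fitted tree
#'
#' @param fit A `cart_tree`.
#' @param features,labels Training data.
#' @return Fraction correctly classified.
#' @export
cart_accuracy <- function(fit, features, labels) {
  mean(predict(fit, features, type = "class") == as_binary_labels(labels))
}
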