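# From-scratch CART for binary classification with Gini impurity.
#
# Semantics fixed for reproducibility:
#   * splits are midpoints between consecutive distinct sorted values;
#     routing is "< threshold -> left, >= threshold -> right", so a printed
#     boundary like 7.4 reads "7.4 or larger goes to the positive branch";
#   * split quality is the count-weighted Gini decrease
#     n_parent*G_parent - n_L*G_L - n_R*G_R;
#   * ties are broken toward the lowest feature index, then the smallest
#     threshold;
#   * a split must decrease impurity by at least cp * n_root * G_root
#     (rpart-style relative complexity);
#   * leaf prediction is the majority class, ties toward the positive
#     (DILI) class.

#' Gini impurity of a binary class count pair
#'
#' @param class_counts numeric length-2 vector `(n_positive, n_negative)`.
#' @return impurity in `[0, 0.5]`: `1 - p+^2 - p-^2`.
#' @examples
#' gini_impurity(c(432, 220))
#' @export
gini_impurity <- function(class_counts) {
  if (length(class_counts) != 2L || any(class_counts < 0))
    stop("class_counts must be two non-negative counts")
  n <- sum(class_counts)
  if (n == 0) stop("gini_impurity of an empty node is undefined")
  1 - sum((class_counts / n)^2)
}

# count-weighted impurity decrease for all admissible splits of one sorted
# feature; returns list(threshold, decrease) vectors
.split_scan <- function(xs, ys, min_leaf) {
  n <- length(xs)
  cumpos <- cumsum(ys)
  pos <- cumpos[n]
  neg <- n - pos
  i <- seq_len(n - 1L)
  boundary <- xs[i] < xs[i + 1L]
  nl <- i
  ok <- boundary & nl >= min_leaf & (n - nl) >= min_leaf
  if (!any(ok)) return(NULL)
  nl <- nl[ok]
  pl <- cumpos[i][ok]
  nr <- n - nl
  pr <- pos - pl
  decrease <- (pl^2 + (nl - pl)^2) / nl + (pr^2 + (nr - pr)^2) / nr -
    (pos^2 + neg^2) / n
  list(threshold = (xs[i][ok] + xs[i + 1L][ok]) / 2, decrease = decrease)
}

#' Best axis-aligned split of a node
#'
#' Exhaustive search over every feature and every midpoint between
#' consecutive distinct sorted values, maximizing the count-weighted Gini
#' decrease. Deterministic tie-break: lowest feature index, then smallest
#' threshold.
#'
#' @param X numeric matrix (or data.frame) with named columns; no `NA`.
#' @param y binary labels (0/1), positive = DILI.
#' @param features candidate feature names (default all columns).
#' @param min_leaf minimum samples allowed in each child.
#' @return `NULL` if no admissible split decreases impurity, else a list
#'   `feature`, `threshold`, `decrease` (count-weighted).
#' @export
best_split <- function(X, y, features = colnames(X), min_leaf = 1L) {
  X <- as.matrix(X)
  if (anyNA(X[, features, drop = FALSE]) || anyNA(y))
    stop("missing values are not supported at fit time")
  if (nrow(X) < 2L) return(NULL)
  y <- as.integer(y)
  best <- NULL
  for (f in features) {
    o <- order(X[, f])
    sc <- .split_scan(X[o, f], y[o], min_leaf)
    if (is.null(sc)) next
    j <- which.max(sc$decrease)   # first max = smallest threshold
    if (is.null(best) || sc$decrease[j] > best$decrease)
      best <- list(feature = f, threshold = sc$threshold[j],
                   decrease = sc$decrease[j])
  }
  if (!is.null(best) && best$decrease <= 0) return(NULL)
  best
}

#' Grow a CART classification tree
#'
#' Recursive greedy growth with Gini impurity. Stopping rules: `max_depth`,
#' `min_split` (smallest node still considered for splitting), `min_leaf`
#' (smallest admissible child), and `cp` (a split must achieve a
#' count-weighted decrease of at least `cp * n * G_root`). Defaults mirror
#' the conventional CART implementation settings (`min_split` 20,
#' `min_leaf` 7, `cp` 0.01). Per-feature importance is the Mean Decrease in
#' Gini: the sum of count-weighted decreases of all splits on the feature,
#' divided by the number of training samples.
#'
#' @param X numeric matrix/data.frame, named columns, no `NA`.
#' @param y binary labels (0/1 or logical), positive = DILI.
#' @param max_depth maximum tree depth (root = depth 0).
#' @param min_split minimum node size to attempt a split.
#' @param min_leaf minimum child size.
#' @param cp complexity: minimum relative impurity decrease.
#' @return object of class `dili_tree`.
#' @examples
#' X <- data.frame(AMW = c(6, 6.5, 7, 8, 9, 10))
#' y <- c(0, 0, 0, 1, 1, 1)
#' fit <- grow_tree(X, y, min_split = 2, min_leaf = 1, cp = 0)
#' predict(fit, data.frame(AMW = c(7.4, 6.9)))
#' @export
grow_tree <- function(X, y, max_depth = 30L, min_split = 20L, min_leaf = 7L,
                      cp = 0.01) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (nrow(X) == 0L) stop("cannot grow a tree on empty input")
  if (anyNA(X) || anyNA(y))
    stop("missing values are not supported at fit time")
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("y must be binary 0/1")
  if (length(y) != nrow(X)) stop("X and y sizes differ")

  n_root <- nrow(X)
  counts_root <- c(sum(y), n_root - sum(y))
  g_root <- gini_impurity(counts_root)
  min_dec <- cp * n_root * g_root
  importance <- stats::setNames(numeric(ncol(X)), colnames(X))

  build <- function(idx, depth) {
    yy <- y[idx]
    counts <- c(sum(yy), length(yy) - sum(yy))
    node <- list(
      feature = NULL, threshold = NA_real_,
      counts = counts, gini = gini_impurity(counts),
      predicted = if (counts[1] >= counts[2]) 1L else 0L,
      left = NULL, right = NULL
    )
    if (depth >= max_depth || length(idx) < min_split ||
        counts[1] == 0L || counts[2] == 0L)
      return(node)
    s <- best_split(X[idx, , drop = FALSE], yy, min_leaf = min_leaf)
    if (is.null(s) || s$decrease < min_dec) return(node)
    importance[s$feature] <<- importance[s$feature] + s$decrease
    go_left <- X[idx, s$feature] < s$threshold
    node$feature <- s$feature
    node$threshold <- s$threshold
    node$left <- build(idx[go_left], depth + 1L)
    node$right <- build(idx[!go_left], depth + 1L)
    node
  }

  root <- build(seq_len(n_root), 0L)
  structure(list(
    root = root,
    params = list(max_depth = max_depth, min_split = min_split,
                  min_leaf = min_leaf, cp = cp),
    importance = importance / n_root,
    feature_names = colnames(X),
    n = n_root
  ), class = "dili_tree")
}

#' @export
print.dili_tree <- function(x, ...) {
  depth <- function(nd) if (is.null(nd$feature)) 0L else
    1L + max(depth(nd$left), depth(nd$right))
  leaves <- function(nd) if (is.null(nd$feature)) 1L else
    leaves(nd$left) + leaves(nd$right)
  cat("<dili_tree> n =", x$n, " depth =", depth(x$root),
      " leaves =", leaves(x$root), "\n")
  used <- names(x$importance)[x$importance > 0]
  if (length(used))
    cat("  splits on:", paste(used, collapse = ", "), "\n")
  invisible(x)
}

#' Predict with a CART tree
#'
#' Routes each sample left when its value is strictly below the node
#' threshold and right when it is greater than or equal (so a sample
#' sitting exactly on a printed boundary such as 7.4 takes the "or larger"
#' branch), then emits the leaf majority class.
#'
#' @param object a `dili_tree`.
#' @param newdata matrix/data.frame containing every feature the tree
#'   splits on.
#' @param ... unused.
#' @return integer vector of 0/1 predictions.
#' @export
predict.dili_tree <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  used <- .tree_features(object$root)
  missing <- setdiff(used, colnames(X))
  if (length(missing))
    stop("newdata lacks feature column(s): ", paste(missing, collapse = ", "))
  vapply(seq_len(nrow(X)), function(i) {
    nd <- object$root
    while (!is.null(nd$feature)) {
      nd <- if (X[i, nd$feature] < nd$threshold) nd$left else nd$right
    }
    nd$predicted
  }, 0L)
}

.tree_features <- function(nd) {
  if (is.null(nd$feature)) return(character(0))
  unique(c(nd$feature, .tree_features(nd$left), .tree_features(nd$right)))
}

#' Select tree depth by stratified k-fold cross-validation
#'
#' For every depth in the grid, fits a tree on each training fold and
#' scores the held-out fold; the depth with the best mean score wins, ties
#' going to the smallest depth (the simpler model). The score is balanced
#' accuracy by default, matching how model performance is reported
#' throughout the screening analysis; plain accuracy is available.
#'
#' @inheritParams grow_tree
#' @param depth_grid integer vector of candidate depths.
#' @param k number of folds.
#' @param seed integer seed driving the fold assignment.
#' @param score `"ba"` (balanced accuracy) or `"accuracy"`.
#' @param min_split,min_leaf,cp passed to [grow_tree()].
#' @return list with `depth` (chosen) and `table` (data.frame of
#'   depth, mean_score).
#' @export
select_depth_by_cv <- function(X, y, depth_grid = 1:8, k = 5L,
                               seed = 1L, score = c("ba", "accuracy"),
                               min_split = 20L, min_leaf = 7L, cp = 0.01) {
  score <- match.arg(score)
  X <- as.matrix(X)
  y <- as.integer(y)
  plan <- stratified_split(y, k, seed)
  means <- vapply(depth_grid, function(d) {
    vals <- vapply(seq_len(k), function(fold) {
      test <- plan$assignments == fold
      if (length(unique(y[test])) < 2L || length(unique(y[!test])) < 2L)
        stop("a CV fold lacks both classes; use fewer folds")
      fit <- grow_tree(X[!test, , drop = FALSE], y[!test], max_depth = d,
                       min_split = min_split, min_leaf = min_leaf, cp = cp)
      pred <- predict(fit, X[test, , drop = FALSE])
      cm <- confusion_matrix(y[test], pred)
      if (score == "ba") {
        (cm$TP / (cm$TP + cm$FN) + cm$TN / (cm$TN + cm$FP)) / 2
      } else {
        (cm$TP + cm$TN) / (cm$TP + cm$TN + cm$FP + cm$FN)
      }
    }, 0)
    mean(vals)
  }, 0)
  tab <- data.frame(depth = depth_grid, mean_score = means)
  list(depth = depth_grid[which.max(means)], table = tab)
}

#' The printed two-node screening rule
#'
#' The decision rule read off the final tree's first two nodes:
#' AMW >= 7.4 is DILI-positive; below that, MLOGP < -0.454 is
#' DILI-negative; the remaining region (low AMW, high or unknown MLOGP) is
#' indeterminate. In strict two-class mode indeterminate maps to negative,
#' which is exactly AMW-alone screening.
#'
#' @param amw_value numeric vector of AMW values.
#' @param mlogp_value optional numeric vector of MLOGP values (`NA`
#'   allowed).
#' @param threshold AMW boundary; the boundary value itself is positive.
#' @param mlogp_threshold MLOGP boundary.
#' @param strict if `TRUE`, collapse indeterminate to negative.
#' @return character vector in `{"positive","negative","indeterminate"}`.
#' @examples
#' rule_classifier(c(7.4, 7.0, 7.0), c(NA, -1, 0.5))
#' @export
rule_classifier <- function(amw_value, mlogp_value = NULL, threshold = 7.4,
                            mlogp_threshold = -0.454, strict = FALSE) {
  if (any(!is.finite(amw_value))) stop("amw_value must be finite")
  n <- length(amw_value)
  if (is.null(mlogp_value)) mlogp_value <- rep(NA_real_, n)
  if (length(mlogp_value) != n) stop("mlogp_value length mismatch")
  out <- ifelse(amw_value >= threshold, "positive",
         ifelse(!is.na(mlogp_value) & mlogp_value < mlogp_threshold,
                "negative", "indeterminate"))
  if (strict) out[out == "indeterminate"] <- "negative"
  out
}

#' Serialize a CART tree to JSON
#'
#' Lossless round trip: nodes as nested objects (feature, threshold,
#' counts, gini, predicted, children), plus params and the importance map.
#'
#' @param model a `dili_tree`.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly, if written to `path`).
#' @export
tree_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "dili_tree"))
  as_list <- function(nd) {
    out <- list(counts = nd$counts, gini = nd$gini, predicted = nd$predicted)
    if (!is.null(nd$feature)) {
      out$feature <- nd$feature
      out$threshold <- nd$threshold
      out$left <- as_list(nd$left)
      out$right <- as_list(nd$right)
    }
    out
  }
  payload <- list(root = as_list(model$root), params = model$params,
                  importance = as.list(model$importance),
                  feature_names = model$feature_names, n = model$n)
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = I(17),
                         pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Load a CART tree from JSON
#' @param x JSON string or file path produced by [tree_to_json()].
#' @return a `dili_tree`.
#' @export
tree_from_json <- function(x) {
  if (length(x) == 1L && file.exists(x)) x <- paste(readLines(x), collapse = "\n")
  payload <- jsonlite::fromJSON(x, simplifyVector = TRUE,
                                simplifyDataFrame = FALSE)
  from_list <- function(nd) {
    out <- list(feature = NULL, threshold = NA_real_,
                counts = as.integer(nd$counts), gini = nd$gini,
                predicted = as.integer(nd$predicted),
                left = NULL, right = NULL)
    if (!is.null(nd$feature)) {
      out$feature <- nd$feature
      out$threshold <- nd$threshold
      out$left <- from_list(nd$left)
      out$right <- from_list(nd$right)
    }
    out
  }
  structure(list(
    root = from_list(payload$root),
    params = payload$params,
    importance = unlist(payload$importance),
    feature_names = unlist(payload$feature_names),
    n = payload$n
  ), class = "dili_tree")
}
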