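# Independent oracles used across the suite. These deliberately share no
# search code with the package: splits are found by literal enumeration,
# AUC by pairwise concordance, confusion counts by a four-way tally. The
# only thing shared with the implementation is the *documented* tie rule
# (lowest feature index, then smallest threshold) and the count-weighted
# Gini decrease formula, both part of the contract.

extdata <- function(f) system.file("extdata", f, package = "diliamw")

# enumerate every (feature, midpoint) pair; strict > keeps the first
# (lowest feature, smallest threshold) among ties
oracle_best_split <- function(X, y, min_leaf = 1L) {
  X <- as.matrix(X)
  y <- as.integer(y)
  n <- nrow(X)
  pos <- sum(y); neg <- n - pos
  parent <- (pos^2 + neg^2) / n
  best <- NULL
  for (f in colnames(X)) {
    v <- sort(unique(X[, f]))
    if (length(v) < 2) next
    for (i in seq_len(length(v) - 1L)) {
      t <- (v[i] + v[i + 1L]) / 2
      left <- X[, f] < t
      nl <- sum(left); nr <- n - nl
      if (nl < min_leaf || nr < min_leaf) next
      pl <- sum(y[left]); pr <- pos - pl
      dec <- (pl^2 + (nl - pl)^2) / nl + (pr^2 + (nr - pr)^2) / nr - parent
      if (is.null(best) || dec > best$decrease)
        best <- list(feature = f, threshold = t, decrease = dec)
    }
  }
  if (!is.null(best) && best$decrease <= 0) return(NULL)
  best
}

# recursive reference CART (no vectorized scan, no shared code paths)
oracle_tree <- function(X, y, max_depth, min_split = 2L, min_leaf = 1L,
                        min_dec = 0) {
  X <- as.matrix(X)
  y <- as.integer(y)
  build <- function(rows, depth) {
    yy <- y[rows]
    counts <- c(sum(yy), length(yy) - sum(yy))
    nd <- list(feature = NULL, threshold = NA_real_, counts = counts)
    if (depth >= max_depth || length(rows) < min_split ||
        counts[1] == 0 || counts[2] == 0)
      return(nd)
    s <- oracle_best_split(X[rows, , drop = FALSE], yy, min_leaf)
    if (is.null(s) || s$decrease < min_dec) return(nd)
    nd$feature <- s$feature
    nd$threshold <- s$threshold
    left <- X[rows, s$feature] < s$threshold
    nd$left <- build(rows[left], depth + 1L)
    nd$right <- build(rows[!left], depth + 1L)
    nd
  }
  build(seq_len(nrow(X)), 0L)
}

# structural equality of a fitted dili_tree against an oracle tree
trees_match <- function(node, ref, tol = 1e-9) {
  if (is.null(ref$feature) || is.null(node$feature))
    return(is.null(ref$feature) && is.null(node$feature) &&
             all(node$counts == ref$counts))
  identical(node$feature, ref$feature) &&
    abs(node$threshold - ref$threshold) <= tol &&
    all(node$counts == ref$counts) &&
    trees_match(node$left, ref$left, tol) &&
    trees_match(node$right, ref$right, tol)
}

# AUC as the pairwise concordance probability, ties counted one half
oracle_auc <- function(scores, y) {
  sp <- scores[y == 1]; sn <- scores[y == 0]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# literal four-way tally
oracle_confusion <- function(y_true, y_pred) {
  out <- c(TP = 0, TN = 0, FP = 0, FN = 0)
  for (i in seq_along(y_true)) {
    out <- out + c(TP = y_true[i] == 1 && y_pred[i] == 1,
                   TN = y_true[i] == 0 && y_pred[i] == 0,
                   FP = y_true[i] == 0 && y_pred[i] == 1,
                   FN = y_true[i] == 1 && y_pred[i] == 0)
  }
  out
}

# random binary-classification instance with mixed continuous/discrete
# features (discrete columns exercise tie handling)
random_instance <- function(seed, n_max = 200L, p_max = 10L) {
  set.seed(seed)
  n <- sample(20:n_max, 1)
  p <- sample(2:p_max, 1)
  X <- matrix(rnorm(n * p), n, p)
  disc <- sample(p, max(1, p %/% 3))
  X[, disc] <- matrix(sample(0:4, n * length(disc), replace = TRUE),
                      n, length(disc))
  colnames(X) <- sprintf("f%02d", seq_len(p))
  beta <- rnorm(p)
  y <- as.integer(X %*% beta + rnorm(n) > 0)
  if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
  list(X = X, y = y)
}

# expand the printed contingency-table counts into per-drug records
table3_records <- function() {
  tab <- read.csv(extdata("table3_counts.csv"))
  amw <- rep(ifelse(tab$side == "ge", 8.0, 7.0), tab$n)
  cls <- rep(tab$dili_class, tab$n)
  data.frame(amw = amw, dili_class = cls,
             dili_label = as.integer(cls != "No"))
}
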