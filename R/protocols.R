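# Validation machinery: stratified group splitting, the nested
# 3-group/10-repeat protocol, and final-model construction with 5-fold CV
# depth selection. One global seed drives a documented chain of sub-seeds
# (derive_seed), so any single repeat/fold is re-derivable in isolation.

#' Derive a deterministic sub-seed
#'
#' Maps (seed, tag...) to a 31-bit integer with a small multiplicative
#' hash. Every source of randomness in the protocols draws its own
#' sub-seed through this chain, so runs are reproducible and individually
#' re-derivable.
#'
#' @param seed integer master seed.
#' @param ... integer tags (repeat index, fold index, ...).
#' @return integer in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, ...) {
  h <- as.double(seed) %% 2147483647
  for (tag in c(...)) {
    h <- (h * 48271 + as.double(tag) + 1) %% 2147483647
  }
  as.integer(h)
}

#' Stratified split into k groups
#'
#' Shuffles each class independently with a seeded RNG and deals samples
#' round-robin, so each group's class proportion matches the global
#' proportion to within one sample (e.g. the 432:220 DILI/no-DILI cohort
#' splits 3 ways as 144 positives and 73-74 negatives per group).
#'
#' @param y binary labels (0/1).
#' @param k number of groups.
#' @param seed integer seed.
#' @return object of class `split_plan`: list with `assignments` (integer
#'   vector in 1..k), `k`, `seed`, and `proportions` (per-group positive
#'   fraction).
#' @export
stratified_split <- function(y, k, seed = 1L) {
  y <- as.integer(y)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  for (cls in unique(y)) {
    if (sum(y == cls) < k)
      stop("class ", cls, " has fewer than k = ", k, " members")
  }
  assignments <- integer(length(y))
  rng <- .seeded_sampler(seed)
  for (cls in c(1L, 0L)) {
    idx <- which(y == cls)
    idx <- idx[rng(length(idx))]
    assignments[idx] <- rep_len(seq_len(k), length(idx))
  }
  props <- vapply(seq_len(k), function(g) mean(y[assignments == g] == 1L), 0)
  structure(list(assignments = assignments, k = k, seed = seed,
                 proportions = props), class = "split_plan")
}

# returns function(n) giving a permutation of 1..n, isolated from the
# caller's RNG state
.seeded_sampler <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
  function(n) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    out <- sample.int(n)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    out
  }
}

.metric_vec <- function(mt) {
  c(accuracy = mt$accuracy, sensitivity = mt$sensitivity,
    specificity = mt$specificity, balanced_accuracy = mt$balanced_accuracy,
    mcc = mt$mcc)
}

#' Nested cross-validation protocol
#'
#' The full validation loop of the screening analysis: per repeat, the
#' cohort is split into `outer_k` stratified groups; each group in turn is
#' held out as a test set while the remaining groups train a tree whose
#' depth is chosen by `inner_k`-fold stratified CV on the training data
#' only. Eq-metrics are recorded on both the training and the held-out
#' data for every run, and summarized as mean, sd and five-number
#' dispersion per metric across all repeats x folds.
#'
#' @param X numeric matrix/data.frame of descriptors.
#' @param y binary labels (1 = DILI).
#' @param repeats number of protocol repetitions (fresh outer split each).
#' @param outer_k outer group count.
#' @param inner_k folds for depth selection.
#' @param depth_grid candidate depths.
#' @param seed master seed; sub-seeds are derived per repeat and fold.
#' @param min_split,min_leaf,cp tree growth controls, see [grow_tree()].
#' @param verbose log fold-level progress to stderr.
#' @return object of class `protocol_result`: list with `runs` (data.frame
#'   of per repeat/fold/split metrics), `summary` (data.frame of mean, sd
#'   and quartiles per metric and split), and the call parameters.
#' @export
nested_cv <- function(X, y, repeats = 10L, outer_k = 3L, inner_k = 5L,
                      depth_grid = 1:8, seed = 1L, min_split = 20L,
                      min_leaf = 7L, cp = 0.01, verbose = FALSE) {
  X <- as.matrix(X)
  y <- as.integer(y)
  runs <- list()
  for (r in seq_len(repeats)) {
    plan <- stratified_split(y, outer_k, derive_seed(seed, r, 0L))
    for (fold in seq_len(outer_k)) {
      test <- plan$assignments == fold
      sel <- select_depth_by_cv(X[!test, , drop = FALSE], y[!test],
                                depth_grid = depth_grid, k = inner_k,
                                seed = derive_seed(seed, r, fold),
                                min_split = min_split, min_leaf = min_leaf,
                                cp = cp)
      fit <- grow_tree(X[!test, , drop = FALSE], y[!test],
                       max_depth = sel$depth, min_split = min_split,
                       min_leaf = min_leaf, cp = cp)
      for (split in c("train", "test")) {
        rows <- if (split == "train") !test else test
        mt <- eq_metrics(confusion_matrix(
          y[rows], predict(fit, X[rows, , drop = FALSE])))
        runs[[length(runs) + 1L]] <- data.frame(
          repeat_ = r, fold = fold, split = split, depth = sel$depth,
          t(.metric_vec(mt)))
      }
      if (verbose)
        message(sprintf("repeat %d fold %d: depth %d", r, fold, sel$depth))
    }
  }
  runs <- do.call(rbind, runs)
  metrics <- c("accuracy", "sensitivity", "specificity",
               "balanced_accuracy", "mcc")
  summary <- do.call(rbind, lapply(c("train", "test"), function(sp) {
    do.call(rbind, lapply(metrics, function(m) {
      v <- runs[runs$split == sp, m]
      q <- stats::quantile(v, c(0, 0.25, 0.5, 0.75, 1), names = FALSE,
                           na.rm = TRUE)
      data.frame(split = sp, metric = m, mean = mean(v, na.rm = TRUE),
                 sd = stats::sd(v, na.rm = TRUE), min = q[1], q1 = q[2],
                 median = q[3], q3 = q[4], max = q[5])
    }))
  }))
  structure(list(runs = runs, summary = summary,
                 params = list(repeats = repeats, outer_k = outer_k,
                               inner_k = inner_k, depth_grid = depth_grid,
                               seed = seed, min_split = min_split,
                               min_leaf = min_leaf, cp = cp)),
            class = "protocol_result")
}

#' @export
print.protocol_result <- function(x, ...) {
  cat("<protocol_result>", x$params$repeats, "repeats x",
      x$params$outer_k, "outer folds\n")
  s <- x$summary[x$summary$split == "test", c("metric", "mean", "sd")]
  s$mean <- round_half_away(s$mean, 3); s$sd <- round_half_away(s$sd, 3)
  print(s, row.names = FALSE)
  invisible(x)
}

#' Fit the final screening tree on the full cohort
#'
#' Depth is chosen by stratified `inner_k`-fold CV on all data, the tree is
#' then fitted on all data. Both resubstitution metrics (tree evaluated on
#' its own training data, as in the printed confusion matrix) and the CV
#' aggregate metrics from the depth-selection folds are reported, labeled
#' explicitly.
#'
#' @inheritParams nested_cv
#' @param inner_k folds for depth selection.
#' @return list: `model` (`dili_tree`), `depth`, `cm` (resubstitution
#'   confusion matrix), `resubstitution` (metrics_report), `cv_table`
#'   (per-depth CV scores), `cv_score` (mean CV balanced accuracy at the
#'   chosen depth).
#' @export
final_model <- function(X, y, inner_k = 5L, depth_grid = 1:8, seed = 1L,
                        min_split = 20L, min_leaf = 7L, cp = 0.01) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) {
    # pure labels: no depth to select, the tree is a single leaf
    fit <- grow_tree(X, y, max_depth = 0L, min_split = min_split,
                     min_leaf = min_leaf, cp = cp)
    cm <- confusion_matrix(y, predict(fit, X))
    return(list(model = fit, depth = 0L, cm = cm,
                resubstitution = eq_metrics(cm), cv_table = NULL,
                cv_score = NA_real_))
  }
  sel <- select_depth_by_cv(X, y, depth_grid = depth_grid, k = inner_k,
                            seed = derive_seed(seed, 0L, 0L),
                            min_split = min_split, min_leaf = min_leaf,
                            cp = cp)
  fit <- grow_tree(X, y, max_depth = sel$depth, min_split = min_split,
                   min_leaf = min_leaf, cp = cp)
  cm <- confusion_matrix(y, predict(fit, X))
  list(model = fit, depth = sel$depth, cm = cm,
       resubstitution = eq_metrics(cm), cv_table = sel$table,
       cv_score = sel$table$mean_score[sel$table$depth == sel$depth])
}
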