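# CART learner: split search, growth, prediction, importance, depth
# selection, the printed two-node rule, and JSON serialization.

test_that("gini_impurity follows the binary definition", {
  expect_identical(gini_impurity(c(10, 0)), 0)
  expect_identical(gini_impurity(c(5, 5)), 0.5)
  expect_equal(gini_impurity(c(432, 220)), 0.4471, tolerance = 1e-4)
  expect_error(gini_impurity(c(0, 0)), "empty")
})

test_that("best_split maximizes count-weighted decrease with midpoints", {
  X <- cbind(f = c(1, 2, 3, 10, 11, 12))
  y <- c(0, 0, 0, 1, 1, 1)
  s <- best_split(X, y)
  expect_equal(s$threshold, 6.5)
  expect_equal(s$decrease, 6 * 0.5)     # n_parent * G_parent fully removed
  expect_null(best_split(cbind(f = rep(2, 6)), y))       # constant feature
  expect_null(best_split(X, rep(1L, 6)))                 # pure labels
  # the perfectly separating feature wins over a noisy one
  X2 <- cbind(noisy = c(5, 1, 4, 2, 3, 6), clean = c(0, 0, 0, 1, 1, 1))
  s2 <- best_split(X2, y)
  expect_identical(s2$feature, "clean")
})

test_that("root split equals brute-force enumeration on random instances", {
  for (seed in 1:12) {
    inst <- random_instance(seed, n_max = 150, p_max = 8)
    ref <- oracle_best_split(inst$X, inst$y)
    got <- best_split(inst$X, inst$y)
    if (is.null(ref)) {
      expect_null(got, label = paste("seed", seed))
    } else {
      expect_identical(got$feature, ref$feature, label = paste("seed", seed))
      expect_equal(got$threshold, ref$threshold, tolerance = 1e-12)
      expect_equal(got$decrease, ref$decrease, tolerance = 1e-9)
    }
  }
})

test_that("fixed-depth trees match the independent reference learner", {
  for (seed in 101:106) {
    inst <- random_instance(seed, n_max = 120, p_max = 5)
    fit <- grow_tree(inst$X, inst$y, max_depth = 3, min_split = 2,
                     min_leaf = 1, cp = 0)
    ref <- oracle_tree(inst$X, inst$y, max_depth = 3)
    expect_true(trees_match(fit$root, ref), label = paste("seed", seed))
  }
})

test_that("growth contracts: separability, purity, empty input", {
  X <- cbind(AMW = c(6, 6.5, 7, 8, 9, 10))
  y <- c(0, 0, 0, 1, 1, 1)
  fit <- grow_tree(X, y, min_split = 2, min_leaf = 1, cp = 0)
  expect_identical(predict(fit, X), as.integer(y))
  expect_null(fit$root$left$feature)    # depth-1 suffices
  pure <- grow_tree(X, rep(1L, 6), min_split = 2, min_leaf = 1, cp = 0)
  expect_null(pure$root$feature)
  expect_true(all(pure$importance == 0))
  expect_error(grow_tree(X[0, , drop = FALSE], integer(0)), "empty")
  expect_error(grow_tree(cbind(a = c(1, NA)), c(0, 1)), "missing")
})

test_that("sample order does not change the fitted tree", {
  inst <- random_instance(7, n_max = 120, p_max = 5)
  fit1 <- grow_tree(inst$X, inst$y, max_depth = 4, min_split = 5,
                    min_leaf = 2, cp = 0)
  set.seed(11)
  perm <- sample(nrow(inst$X))
  fit2 <- grow_tree(inst$X[perm, , drop = FALSE], inst$y[perm],
                    max_depth = 4, min_split = 5, min_leaf = 2, cp = 0)
  expect_true(trees_match(fit1$root, fit2$root))
  expect_equal(fit1$importance, fit2$importance)
})

test_that("training accuracy is monotone in allowed depth", {
  inst <- random_instance(21, n_max = 150, p_max = 6)
  accs <- vapply(1:6, function(d) {
    fit <- grow_tree(inst$X, inst$y, max_depth = d, min_split = 2,
                     min_leaf = 1, cp = 0)
    mean(predict(fit, inst$X) == inst$y)
  }, 0)
  expect_true(all(diff(accs) >= 0))
})

test_that("importance conserves the tree's total normalized decrease", {
  for (seed in c(3, 13)) {
    inst <- random_instance(seed, n_max = 150, p_max = 6)
    fit <- grow_tree(inst$X, inst$y, max_depth = 4, min_split = 5,
                     min_leaf = 2, cp = 0)
    leaf_term <- function(nd) {
      if (is.null(nd$feature)) sum(nd$counts) * gini_impurity(nd$counts)
      else leaf_term(nd$left) + leaf_term(nd$right)
    }
    n <- fit$n
    total <- (n * gini_impurity(fit$root$counts) - leaf_term(fit$root)) / n
    expect_equal(sum(fit$importance), total, tolerance = 1e-12)
    expect_true(all(fit$importance >= 0))
    # features never split on have importance exactly 0
    used <- names(fit$importance)[fit$importance > 0]
    expect_true(all(used %in% colnames(inst$X)))
  }
})

test_that("prediction routes boundary values to the >= branch", {
  X <- cbind(AMW = c(6, 7, 7.4, 8))
  y <- c(0, 0, 1, 1)
  fit <- grow_tree(X, y, min_split = 2, min_leaf = 1, cp = 0)
  expect_equal(fit$root$threshold, 7.2)
  expect_identical(predict(fit, cbind(AMW = fit$root$threshold)), 1L)
  expect_error(predict(fit, cbind(other = 1)), "AMW")
  # leaf ties break toward the positive class
  tie <- grow_tree(cbind(a = c(1, 1)), c(0, 1), min_split = 10)
  expect_identical(predict(tie, cbind(a = 5)), 1L)
})

test_that("depth selection recovers a depth-1 generating rule", {
  set.seed(500)
  n <- 500
  x1 <- rnorm(n)
  y <- as.integer(x1 > 0)            # large-margin depth-1 rule
  X <- cbind(signal = x1, junk1 = rnorm(n), junk2 = rnorm(n))
  sel <- select_depth_by_cv(X, y, depth_grid = 1:5, k = 5, seed = 9)
  expect_identical(sel$depth, 1L)
  # single-depth grid returns that depth
  expect_identical(select_depth_by_cv(X, y, depth_grid = 3L, seed = 1)$depth, 3L)
  # determinism
  s1 <- select_depth_by_cv(X, y, depth_grid = 1:3, seed = 4)
  s2 <- select_depth_by_cv(X, y, depth_grid = 1:3, seed = 4)
  expect_identical(s1$table, s2$table)
})

test_that("rule_classifier implements the printed node semantics", {
  expect_identical(rule_classifier(7.4), "positive")      # boundary inclusive
  expect_identical(rule_classifier(7.0, -1.0), "negative")
  expect_identical(rule_classifier(7.0, 0.5), "indeterminate")
  expect_identical(rule_classifier(7.0), "indeterminate") # MLOGP absent
  expect_identical(rule_classifier(7.0, 0.5, strict = TRUE), "negative")
  expect_identical(rule_classifier(c(3.2, 7.4, 9.0), strict = TRUE),
                   c("negative", "positive", "positive"))
  expect_error(rule_classifier(Inf), "finite")
})

test_that("JSON serialization round-trips losslessly", {
  inst <- random_instance(31, n_max = 100, p_max = 4)
  fit <- grow_tree(inst$X, inst$y, max_depth = 3, min_split = 5,
                   min_leaf = 2, cp = 0)
  path <- tempfile(fileext = ".json")
  tree_to_json(fit, path)
  back <- tree_from_json(path)
  expect_true(trees_match(back$root, fit$root, tol = 0))
  expect_equal(back$importance, fit$importance)
  expect_equal(back$params, fit$params)
  expect_identical(predict(back, inst$X), predict(fit, inst$X))
})
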