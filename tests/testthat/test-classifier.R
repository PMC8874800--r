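# small separable toy problem used across classifier tests
toy_problem <- function(n_per = 40, sd = 0.15, seed = 1) {
  set.seed(seed)
  centers <- list(a = c(0, 0), b = c(2, 0), c = c(0, 2))
  x <- do.call(rbind, lapply(centers, function(mu)
    cbind(stats::rnorm(n_per, mu[1], sd), stats::rnorm(n_per, mu[2], sd))))
  list(x = data.frame(f1 = x[, 1], f2 = x[, 2]),
       y = factor(rep(names(centers), each = n_per)))
}

test_that("training is deterministic and separates a toy problem", {
  toy <- toy_problem()
  m1 <- bagged_trees(toy$x, toy$y, n_trees = 15, seed = 5)
  m2 <- bagged_trees(toy$x, toy$y, n_trees = 15, seed = 5)
  expect_identical(m1$inbag, m2$inbag)
  expect_identical(predict(m1, toy$x), predict(m2, toy$x))
  expect_equal(mean(predict(m1, toy$x) == toy$y), 1)

  # every bootstrap sample has training-set size, drawn with replacement
  expect_true(all(vapply(m1$inbag, length, 1L) == nrow(toy$x)))
  expect_true(any(vapply(m1$inbag, anyDuplicated, 1L) > 0))
})

test_that("a single unbagged tree reproduces a hand-built partition", {
  # 8 enumerable points: class splits at f1 = 0.5 then f2 = 0.5
  x <- data.frame(f1 = c(0, 0, 0.2, 0.1, 1, 1, 0.9, 0.8),
                  f2 = c(0, 1, 0.1, 0.9, 0, 0.2, 1, 0.9))
  y <- factor(c("lo", "hi", "lo", "hi", "rr", "rr", "rr", "rr"))
  m <- bagged_trees(x, y, n_trees = 1, seed = 1, bootstrap = FALSE)
  grid <- expand.grid(f1 = c(0.05, 0.95), f2 = c(0.05, 0.95))
  # hand-derived leaves: right half all "rr"; left half splits on f2
  want <- factor(c("lo", "rr", "hi", "rr"), levels = levels(y))
  expect_identical(predict(m, grid), want)
})

test_that("majority vote and tie-breaks follow class order", {
  toy <- toy_problem()
  m <- bagged_trees(toy$x, toy$y, n_trees = 7, seed = 2)
  votes <- predict(m, toy$x[1:5, ], type = "votes")
  expect_identical(dim(votes), c(5L, 3L))
  expect_equal(rowSums(votes), rep(7, 5))
  # vote counting equals a hand count over per-tree predictions
  per_tree <- vapply(m$trees, function(tr)
    as.character(predict(tr, toy$x[1:5, ], type = "class")), character(5))
  hand <- t(apply(per_tree, 1, function(v) table(factor(v, m$classes))))
  expect_equal(unname(votes), unname(hand), ignore_attr = TRUE)

  # an exact 2-2 tie goes to the first class in canonical order
  mv <- vrmotion:::majority_vote(
    matrix(c("b", "b", "c", "c"), 1, 4), classes = c("a", "b", "c"))
  expect_identical(as.character(mv$class), "b")
  mv2 <- vrmotion:::majority_vote(
    matrix(c("c", "b", "c", "b"), 1, 4), classes = c("a", "b", "c"))
  expect_identical(as.character(mv2$class), "b")
})

test_that("out-of-bag fraction concentrates near exp(-1)", {
  toy <- toy_problem(n_per = 70)
  m <- bagged_trees(toy$x, toy$y, n_trees = 60, seed = 3)
  expect_lt(abs(oob_fraction(m) - exp(-1)), 0.03)
})

test_that("stratified k-fold evaluation is reproducible and near-perfect on separable data", {
  toy <- toy_problem(n_per = 50)
  ev <- kfold_evaluate(toy$x, toy$y, k = 5, n_trees = 10, seed = 7)
  expect_gte(ev$accuracy, 0.95)
  # folds of equal size, stratified by class
  expect_true(all(table(ev$folds) == 30))
  expect_true(all(table(ev$folds, toy$y) == 10))
  # confusion rows sum to class support; accuracy = trace/total
  expect_equal(unname(rowSums(ev$confusion)), rep(50, 3))
  expect_equal(ev$accuracy, sum(diag(ev$confusion)) / sum(ev$confusion))
  ev2 <- kfold_evaluate(toy$x, toy$y, k = 5, n_trees = 10, seed = 7)
  expect_identical(ev$folds, ev2$folds)
  expect_equal(ev$confusion, ev2$confusion)
})

test_that("label-shuffled data scores at chance level", {
  toy <- toy_problem(n_per = 60)
  set.seed(8)
  y_shuf <- sample(toy$y)
  ev <- kfold_evaluate(toy$x, y_shuf, k = 5, n_trees = 20, seed = 8)
  expect_lt(abs(ev$accuracy - 1 / 3), 0.12)
})

test_that("oob importance ranks informative features above noise", {
  set.seed(9)
  n <- 240
  informative <- rep(c(0, 1, 2), each = n / 3) + stats::rnorm(n, sd = 0.15)
  x <- data.frame(signal = informative, noise = stats::rnorm(n))
  y <- factor(rep(c("a", "b", "c"), each = n / 3))
  m <- bagged_trees(x, y, n_trees = 40, seed = 9)
  imp <- oob_importance(m, x, y)
  expect_identical(imp$feature, c("signal", "noise"))
  expect_gt(imp$importance_sum[1], 5 * max(imp$importance_sum[2], 0.5))
  expect_lt(abs(imp$importance_mean[2]), 0.05)

  # duplicating the informative feature: trees break the tied split in
  # favour of the first-listed column, so the duplicate carries ~zero
  # permutation importance while the original keeps its rank (paired run)
  x2 <- data.frame(signal = informative, copy = informative,
                   noise = stats::rnorm(n))
  m2 <- bagged_trees(x2, y, n_trees = 40, seed = 9)
  imp2 <- oob_importance(m2, x2, y)
  expect_gt(imp2$importance_sum[1], 5 * abs(imp2$importance_sum[2]))
  expect_lt(abs(imp2$importance_mean[2]), 0.05)
})

test_that("ensemble never loses to its majority-class baseline in training", {
  toy <- toy_problem(n_per = 30, sd = 1.5)  # heavily overlapping classes
  m <- bagged_trees(toy$x, toy$y, n_trees = 20, seed = 10)
  acc <- mean(predict(m, toy$x) == toy$y)
  baseline <- max(table(toy$y)) / length(toy$y)
  expect_gte(acc, baseline)
})

test_that("bagged trees agree with an independent bagging implementation", {
  skip_if_not_installed("randomForest")
  toy <- toy_problem(n_per = 50, sd = 0.5, seed = 12)
  ours <- kfold_evaluate(toy$x, toy$y, k = 5, n_trees = 50, seed = 12)
  rf <- randomForest::randomForest(toy$x, toy$y, ntree = 50,
                                   mtry = ncol(toy$x))  # mtry = p: bagging
  rf_acc <- 1 - mean(rf$err.rate[50, "OOB"])
  expect_lt(abs(ours$accuracy - rf_acc), 0.08)
})
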