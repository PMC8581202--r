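test_that("accuracy is the exact count ratio", {
  expect_identical(accuracy(list(TP = 1, TN = 1, FP = 1, FN = 1)), 0.5)
  expect_equal(accuracy(list(TP = 70, TN = 65, FP = 5, FN = 0)), 135 / 140)
  expect_error(accuracy(list(TP = 0, TN = 0, FP = 0, FN = 0)), "zero total")
  # indicator-mean oracle on random predictions
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(5:200, 1)
    truth <- sample(c(-1, 1), n, replace = TRUE)
    pred <- sample(c(-1, 1), n, replace = TRUE)
    expect_identical(accuracy(confusion_counts(truth, pred)),
                     mean(truth == pred))
  }
})

test_that("half split is stratified, disjoint, exhaustive, reproducible", {
  fm <- generate_gaussian_features(140, 2, separation = 1, seed = 2)   # 280 trials
  sp <- split_half(fm, seed = 11)
  expect_identical(nrow(sp$train$X), 140L)
  expect_identical(nrow(sp$test$X), 140L)
  expect_identical(sum(sp$train$y == 1), 70L)   # train half class-balanced
  expect_identical(sum(sp$train$y == -1), 70L)
  expect_identical(sort(c(sp$train_idx, sp$test_idx)), seq_len(280L))
  expect_length(intersect(sp$train_idx, sp$test_idx), 0L)
  sp2 <- split_half(fm, seed = 11)
  expect_identical(sp$train_idx, sp2$train_idx)
  expect_false(identical(split_half(fm, seed = 12)$train_idx, sp$train_idx))
})

test_that("odd per-class counts send the extra sample to the test half", {
  set.seed(4)
  fm <- feature_matrix(matrix(rnorm(22), 11, 2), c(rep(1, 5), rep(-1, 6)))
  sp <- split_half(fm, seed = 1)
  expect_identical(sum(sp$train$y == 1), 2L)
  expect_identical(sum(sp$train$y == -1), 3L)
  expect_identical(nrow(sp$test$X), 6L)
  expect_error(split_half(feature_matrix(matrix(1:2, 2, 1), c(1, -1))),
               "2 samples per class")
})

test_that("trial sets split the same way as feature matrices", {
  ts <- tiny_trial_set(n_per_class = 4L, seed = 3L)
  sp <- split_half(ts, seed = 5)
  expect_identical(n_trials(sp$train), 4L)
  expect_identical(sort(c(sp$train_idx, sp$test_idx)), 1:8)
})

test_that("grid search covers the grid, records failures, and picks the max", {
  fm <- generate_gaussian_features(40, 3, separation = 5, seed = 7)
  gs <- grid_search(fm, hidden = list(c(4), c(6, 3)), lr = c(0.05, 0.1),
                    lambda = 0.1, iters = 60, seed = 2)
  expect_identical(nrow(gs$results), 4L)
  expect_identical(gs$best$accuracy, max(gs$results$accuracy, na.rm = TRUE))
  # single cell: that cell is best
  g1 <- grid_search(fm, hidden = list(c(4)), lr = 0.07, lambda = 0.1,
                    iters = 60, seed = 2)
  expect_identical(nrow(g1$results), 1L)
  expect_identical(g1$best$accuracy, g1$results$accuracy[1])
  # reproducibility, tie-breaks included
  gs2 <- grid_search(fm, hidden = list(c(4), c(6, 3)), lr = c(0.05, 0.1),
                     lambda = 0.1, iters = 60, seed = 2)
  expect_identical(gs$results, gs2$results)
  expect_identical(gs$best, gs2$best)
  expect_error(grid_search(fm, hidden = list()), "empty grid")
})

test_that("a failing cell is recorded and the search continues", {
  fm <- generate_gaussian_features(20, 2, separation = 4, seed = 9)
  gs <- grid_search(fm, hidden = list(c(3), c(0)), lr = 0.07, lambda = 0.1,
                    iters = 40, seed = 1)
  expect_identical(sum(is.na(gs$results$accuracy)), 1L)
  expect_identical(sum(!is.na(gs$results$error)), 1L)
  expect_false(is.na(gs$best$accuracy))
})

test_that("best grid accuracy dominates the default-config run it contains", {
  fm <- generate_gaussian_features(60, 4, separation = 5, seed = 13)
  base <- grid_search(fm, hidden = list(c(11, 6)), lr = 0.07, lambda = 0.1,
                      iters = 100, seed = 3)
  wider <- grid_search(fm, hidden = list(c(11, 6), c(5)), lr = c(0.05, 0.07),
                       lambda = 0.1, iters = 100, seed = 3)
  expect_gte(wider$best$accuracy, base$best$accuracy)
})

test_that("greedy layer-width search sweeps one layer at a time", {
  fm <- generate_gaussian_features(40, 3, separation = 5, seed = 15)
  ls <- layer_width_search(fm, widths = c(3, 5), max_depth = 2, iters = 50,
                           seed = 4)
  expect_identical(dim(ls$accuracy), c(2L, 2L))
  expect_length(ls$selected_widths, 2L)
  expect_true(ls$selected_widths[1] %in% c(3, 5))
  expect_identical(ls$best_hidden,
                   ls$selected_widths[seq_len(ls$best_depth)])
  expect_equal(ls$best_accuracy, max(apply(ls$accuracy, 1, max)),
               ignore_attr = TRUE)
})
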