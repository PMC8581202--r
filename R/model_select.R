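#' Confusion counts for two-class predictions
#'
#' Tallies predictions against truth with `+1` as the positive class:
#' TP (predicted and truly positive), TN, FP (predicted positive, truly
#' negative), FN.
#'
#' @param truth,pred label vectors in `{-1, +1}`, equal length.
#' @return A list of class `confusion_counts` with integer fields `TP`,
#'   `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(truth, pred) {
  if (length(truth) != length(pred)) stop("truth and pred lengths differ")
  if (!all(truth %in% c(-1, 1)) || !all(pred %in% c(-1, 1)))
    stop("labels must be -1 or +1")
  structure(list(TP = sum(truth == 1 & pred == 1),
                 TN = sum(truth == -1 & pred == -1),
                 FP = sum(truth == -1 & pred == 1),
                 FN = sum(truth == 1 & pred == -1)),
            class = "confusion_counts")
}

#' Classification accuracy
#'
#' `Acc = (TP + TN) / (TP + TN + FN + FP)`, evaluated from the integer
#' counts so the ratio is exact before any floating-point rounding.
#'
#' @param counts a [confusion_counts()] object, or a list with integer
#'   fields `TP`, `TN`, `FP`, `FN`.
#' @return Scalar in `[0, 1]`.
#' @export
#' @examples
#' accuracy(confusion_counts(c(1, 1, -1, -1), c(1, -1, -1, -1)))
accuracy <- function(counts) {
  cnt <- as.integer(c(counts$TP, counts$TN, counts$FP, counts$FN))
  if (anyNA(cnt) || any(cnt < 0)) stop("counts must be non-negative integers")
  total <- sum(cnt)
  if (total == 0L) stop("zero total count")
  (cnt[1L] + cnt[2L]) / total
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion counts: TP=%d TN=%d FP=%d FN=%d (accuracy %.4f)\n",
              x$TP, x$TN, x$FP, x$FN, accuracy(x)))
  invisible(x)
}

#' Stratified random half split
#'
#' Splits a [trial_set()] or [feature_matrix()] into equal train and test
#' halves with the training half exactly class-balanced, reproducibly
#' from `seed`. With an odd per-class count the extra sample goes to the
#' test half. The two index sets are disjoint and exhaustive.
#'
#' @param x a `trial_set` or `feature_matrix`.
#' @param seed integer seed.
#' @return A list with `train`, `test` (same class as `x`) and the
#'   integer index vectors `train_idx`, `test_idx`.
#' @export
split_half <- function(x, seed = 1L) {
  labels <- if (inherits(x, "trial_set")) x$labels
            else if (inherits(x, "feature_matrix")) x$y
            else stop("x must be a trial_set or feature_matrix")
  if (min(table(labels)) < 2L) stop("need at least 2 samples per class")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  train_idx <- integer(0)
  for (cl in c(1, -1)) {
    idx <- which(labels == cl)
    train_idx <- c(train_idx, sort(sample(idx, floor(length(idx) / 2))))
  }
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_along(labels), train_idx)
  take <- function(obj, idx) {
    if (inherits(obj, "trial_set")) {
      obj$data <- obj$data[idx, , , drop = FALSE]
      obj$labels <- obj$labels[idx]
      obj
    } else feature_matrix(obj$X[idx, , drop = FALSE], obj$y[idx])
  }
  list(train = take(x, train_idx), test = take(x, test_idx),
       train_idx = train_idx, test_idx = test_idx)
}

#' Grid search over classifier hyperparameters
#'
#' Trains one [idnn()] per grid cell on the training half of a stratified
#' random half split and scores held-out [accuracy()] on the test half.
#' The grid is the cross product of the architecture, learning-rate and
#' lambda lists. The best cell attains the maximum test accuracy; ties
#' are broken by fewer hidden layers, then fewer total units, then lower
#' learning rate, then lower lambda.
#'
#' Per-cell training failures are caught, recorded in the `error` column
#' and skipped; if every cell fails, an error is raised.
#'
#' @param fm a [feature_matrix()].
#' @param hidden list of integer vectors of hidden-layer widths.
#' @param lr numeric vector of learning rates.
#' @param lambda numeric vector of margin-mean weights.
#' @param C slack penalty (scalar).
#' @param iters pretraining iterations per cell (default 2500).
#' @param seed seed for the half split and every fit (fully
#'   reproducible, tie-breaks included).
#' @return An object of class `grid_search_result`: a data frame
#'   `results` (one row per cell: depth, units, lr, lambda, accuracy,
#'   error), `best` (the winning row), and the split indices.
#' @export
grid_search <- function(fm, hidden = list(c(11L, 6L)), lr = 0.07,
                        lambda = 0.1, C = 1, iters = 2500L, seed = 1L) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (!length(hidden) || !length(lr) || !length(lambda))
    stop("empty grid")
  sp <- split_half(fm, seed = seed)
  cells <- expand.grid(h = seq_along(hidden), lr = lr, lambda = lambda,
                       KEEP.OUT.ATTRS = FALSE)
  res <- data.frame(
    depth = vapply(hidden, length, 0L)[cells$h],
    units = vapply(hidden, paste, "", collapse = "-")[cells$h],
    total_units = vapply(hidden, sum, 0)[cells$h],
    lr = cells$lr, lambda = cells$lambda,
    accuracy = NA_real_, error = NA_character_,
    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cells))) {
    h <- hidden[[cells$h[i]]]
    fit_try <- tryCatch(
      idnn(sp$train, hidden = h, lr = cells$lr[i], iters = iters,
           C = C, lambda = cells$lambda[i], seed = seed),
      error = function(e) e)
    if (inherits(fit_try, "error")) {
      res$error[i] <- conditionMessage(fit_try)
      next
    }
    pred <- predict(fit_try, sp$test)
    res$accuracy[i] <- accuracy(confusion_counts(sp$test$y, pred))
  }
  if (all(is.na(res$accuracy))) stop("every grid cell failed to train")
  ord <- order(-res$accuracy, res$depth, res$total_units, res$lr, res$lambda,
               na.last = TRUE)
  structure(list(results = res[ord, ],
                 best = res[ord[1L], ],
                 train_idx = sp$train_idx, test_idx = sp$test_idx,
                 seed = as.integer(seed)),
            class = "grid_search_result")
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat(sprintf("grid search: %d cells, %d trained\n",
              nrow(x$results), sum(!is.na(x$results$accuracy))))
  cat("best cell:\n")
  print(x$best, row.names = FALSE)
  invisible(x)
}

#' Greedy layer-by-layer width search
#'
#' Mirrors the tabulated protocol for choosing an architecture: for each
#' depth from 1 up, sweep the newest layer's width over `widths` while
#' every earlier layer keeps its already-selected best width, scoring
#' held-out accuracy at each cell. Returns the full accuracy matrix
#' (depth x width), the per-depth selected widths, and the overall best
#' architecture (max accuracy; ties favour fewer layers).
#'
#' @param fm a [feature_matrix()].
#' @param widths candidate widths for each layer (default 5:12).
#' @param max_depth deepest stack to try (default 5).
#' @param lr,lambda,C,iters,seed passed to [idnn()] / the split.
#' @return A list of class `layer_search_result`: `accuracy` matrix,
#'   `selected_widths`, `best_depth`, `best_hidden`, `best_accuracy`.
#' @export
layer_width_search <- function(fm, widths = 5:12, max_depth = 5L,
                               lr = 0.07, lambda = 0.1, C = 1,
                               iters = 2500L, seed = 1L) {
  stopifnot(inherits(fm, "feature_matrix"), length(widths) >= 1L,
            max_depth >= 1L)
  sp <- split_half(fm, seed = seed)
  acc <- matrix(NA_real_, max_depth, length(widths),
                dimnames = list(paste0("layer", seq_len(max_depth)), widths))
  selected <- integer(0)
  for (depth in seq_len(max_depth)) {
    for (j in seq_along(widths)) {
      h <- c(selected, widths[j])
      fit_try <- tryCatch(
        idnn(sp$train, hidden = h, lr = lr, iters = iters, C = C,
             lambda = lambda, seed = seed),
        error = function(e) NULL)
      if (is.null(fit_try)) next
      pred <- predict(fit_try, sp$test)
      acc[depth, j] <- accuracy(confusion_counts(sp$test$y, pred))
    }
    if (all(is.na(acc[depth, ]))) stop(sprintf("depth %d: all widths failed", depth))
    selected <- c(selected, widths[which.max(acc[depth, ])])
  }
  per_depth_best <- apply(acc, 1L, max, na.rm = TRUE)
  best_depth <- which.max(per_depth_best)     # which.max takes the first tie
  structure(list(accuracy = acc, selected_widths = selected,
                 best_depth = best_depth,
                 best_hidden = selected[seq_len(best_depth)],
                 best_accuracy = per_depth_best[best_depth]),
            class = "layer_search_result")
}

#' @export
print.layer_search_result <- function(x, ...) {
  cat("greedy layer-width search (held-out accuracy):\n")
  print(round(x$accuracy, 4))
  cat(sprintf("selected architecture: (%s), depth %d, accuracy %.4f\n",
              paste(x$best_hidden, collapse = ", "), x$best_depth,
              x$best_accuracy))
  invisible(x)
}
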