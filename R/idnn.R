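#' Fit the hybrid network/SVM classifier
#'
#' Fits a two-class classifier in which a small fully connected network
#' serves as an explicit kernel map and a large-margin-distribution SVM
#' ([lmsvm()]) replaces the output layer. Training is staged:
#'
#' \describe{
#'   \item{Stage A}{The hidden stack plus a temporary two-unit output
#'     head is trained by full-batch gradient descent on the one-hot MSE
#'     loss for `iters` iterations.}
#'   \item{Stage B}{The temporary head is discarded; every training
#'     input is mapped through the hidden stack and the SVM head is
#'     fitted on the mapped features.}
#'   \item{Stage C (optional)}{With `joint_finetune = TRUE`, additional
#'     gradient steps on the combined SVM primal objective are
#'     backpropagated through the map (off by default).}
#' }
#'
#' With `hidden = integer(0)` the map is the identity and the model
#' reduces to a plain linear [lmsvm()] on the (normalized) input
#' features.
#'
#' Defaults follow the selected operating point for cue-paced
#' motor-imagery EEG: two hidden layers of (11, 6) sigmoid units,
#' learning rate 0.07, 2500 iterations, `lambda = 0.1`.
#'
#' @param x `N x d` feature matrix or a [feature_matrix()].
#' @param y labels in `{-1, +1}` (ignored when `x` is a
#'   `feature_matrix`).
#' @param hidden integer vector of hidden-layer widths (default
#'   `c(11, 6)`); `integer(0)` for no map.
#' @param lr learning rate for the network pretraining (default 0.07).
#' @param iters pretraining iterations (default 2500).
#' @param C,lambda SVM head hyperparameters (defaults 1 and 0.1).
#' @param activation hidden activation, `"sigmoid"` (default), `"relu"`
#'   or `"identity"`.
#' @param normalize z-score the inputs with training statistics
#'   (default `TRUE`).
#' @param joint_finetune run Stage C? Default `FALSE`.
#' @param finetune_iters,finetune_lr Stage C step count and rate.
#' @param seed integer seed controlling weight initialization; the whole
#'   fit is deterministic given it.
#' @return An object of class `idnn` with elements `phi` (the
#'   [dnn_init()] hidden stack, or `NULL`), `head` (the [lmsvm()] fit),
#'   `normalizer`, `config`, `train_accuracy`, `loss_history`.
#' @export
#' @examples
#' fm <- generate_gaussian_features(50, 4, separation = 4, seed = 2)
#' fit <- idnn(fm, hidden = c(5), iters = 200, seed = 1)
#' fit
idnn <- function(x, y = NULL, hidden = c(11L, 6L), lr = 0.07, iters = 2500L,
                 C = 1, lambda = 0.1, activation = "sigmoid",
                 normalize = TRUE, joint_finetune = FALSE,
                 finetune_iters = 200L, finetune_lr = 0.01, seed = 1L) {
  xy <- as_xy(x, y)
  fm <- feature_matrix(xy$X, xy$y)
  if (length(unique(fm$y)) < 2L) stop("both classes must be present")
  if (length(hidden) && any(hidden < 1L)) stop("hidden widths must be >= 1")
  stopifnot(lr > 0, iters >= 0, C > 0, lambda >= 0)

  normalizer <- if (normalize) zscore_fit(fm) else NULL
  fmz <- if (normalize) zscore_apply(normalizer, fm) else fm
  d <- ncol(fmz$X)

  loss_history <- numeric(0)
  phi <- NULL
  if (length(hidden)) {
    # Stage A: pretrain map + temporary 2-unit head on one-hot MSE
    full <- dnn_init(c(d, hidden, 2L), activation = activation, seed = seed)
    full <- dnn_train(full, fmz$X, labels_to_onehot(fmz$y),
                      lr = lr, iters = iters)
    loss_history <- attr(full, "loss_history")
    r <- length(hidden)
    phi <- structure(list(W = full$W[seq_len(r)], b = full$b[seq_len(r)],
                          activation = activation,
                          layer_sizes = full$layer_sizes[seq_len(r + 1L)]),
                     class = "dnn_params")
  }

  # Stage B: map training data, fit the SVM head
  Phi <- if (is.null(phi)) fmz$X else {
    acts <- dnn_forward(phi, fmz$X)
    acts[[length(acts)]]
  }
  head <- lmsvm(Phi, fmz$y, C = C, lambda = lambda)

  model <- structure(
    list(phi = phi, head = head, normalizer = normalizer,
         config = list(hidden = as.integer(hidden), lr = lr,
                       iters = as.integer(iters), C = C, lambda = lambda,
                       activation = activation, normalize = normalize,
                       joint_finetune = joint_finetune,
                       finetune_iters = as.integer(finetune_iters),
                       finetune_lr = finetune_lr, seed = as.integer(seed)),
         loss_history = loss_history),
    class = "idnn")

  if (joint_finetune && length(hidden))
    model <- finetune_idnn(model, fmz, finetune_iters, finetune_lr)

  model$train_accuracy <- mean(predict_mapped(model, fmz$X) == fmz$y)
  model
}

# Stage C: subgradient steps on the SVM primal, chained through the map.
finetune_idnn <- function(model, fmz, iters, lr) {
  phi <- model$phi; head <- model$head
  N <- nrow(fmz$X); y <- fmz$y
  r <- length(phi$W)
  for (it in seq_len(iters)) {
    acts <- dnn_forward(phi, fmz$X)
    Phi <- acts[[r]]
    f <- as.vector(Phi %*% head$w) + head$b
    xi <- pmax(0, 1 - y * f)
    # head gradients of the primal
    gw <- head$w - 2 * head$C * as.vector(crossprod(Phi, xi * y)) -
      (head$lambda / N) * as.vector(crossprod(Phi, y))
    gb <- -2 * head$C * sum(xi * y) - (head$lambda / N) * sum(y)
    # gradient w.r.t. the mapped features, backpropagated into the stack
    dPhi <- outer(-2 * head$C * xi * y - head$lambda * y / N, head$w)
    delta <- dPhi * act_deriv_from_a(Phi, phi$activation)
    for (h in r:1) {
      A_prev <- if (h == 1L) fmz$X else acts[[h - 1L]]
      W_old <- phi$W[[h]]
      phi$W[[h]] <- phi$W[[h]] - lr * crossprod(delta, A_prev)
      phi$b[[h]] <- phi$b[[h]] - lr * colSums(delta)
      if (h > 1L)
        delta <- (delta %*% W_old) *
          act_deriv_from_a(acts[[h - 1L]], phi$activation)
    }
    head$w <- head$w - lr * gw
    head$b <- head$b - lr * gb
  }
  # refresh head diagnostics on the finetuned map
  Phi <- dnn_forward(phi, fmz$X)[[r]]
  f <- as.vector(Phi %*% head$w) + head$b
  head$margin_mean <- mean(y * f)
  head$slacks <- pmax(0, 1 - y * f)
  head$objective <- lmsvm_objective(head$w, head$b, Phi, y, head$C, head$lambda)
  model$phi <- phi
  model$head <- head
  model
}

# predictions on already-normalized inputs
predict_mapped <- function(model, Xz, type = "class") {
  Phi <- if (is.null(model$phi)) Xz else {
    acts <- dnn_forward(model$phi, Xz)
    acts[[length(acts)]]
  }
  predict(model$head, Phi, type = type)
}

#' Predict from a fitted hybrid classifier
#'
#' Applies the stored normalizer, the network map and the SVM decision
#' function; deterministic.
#'
#' @param object an [idnn()] fit.
#' @param newdata matrix or [feature_matrix()] with the training feature
#'   dimension.
#' @param type `"class"` (labels in `{-1, +1}`, default) or `"score"`.
#' @param ... unused.
#' @return Numeric vector of labels or decision scores.
#' @export
predict.idnn <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "feature_matrix")) newdata$X else as.matrix(newdata)
  if (!is.null(object$normalizer)) {
    dummy <- feature_matrix(X, rep(1, nrow(X)))
    X <- zscore_apply(object$normalizer, dummy)$X
  }
  d_in <- if (is.null(object$phi)) length(object$head$w)
          else object$phi$layer_sizes[1L]
  if (ncol(X) != d_in)
    stop(sprintf("model expects %d input features, newdata has %d",
                 d_in, ncol(X)))
  predict_mapped(object, X, type = type)
}

#' @export
print.idnn <- function(x, ...) {
  cfg <- x$config
  arch <- if (length(cfg$hidden))
    paste(cfg$hidden, collapse = ", ") else "none (identity map)"
  cat("hybrid network/SVM classifier\n")
  cat(sprintf("  hidden layers: %s; activation: %s\n", arch, cfg$activation))
  cat(sprintf("  pretraining: lr = %g, %d iterations; head: C = %g, lambda = %g\n",
              cfg$lr, cfg$iters, cfg$C, cfg$lambda))
  cat(sprintf("  training accuracy: %.4f; head mean margin: %.4f\n",
              x$train_accuracy, x$head$margin_mean))
  invisible(x)
}

#' @export
summary.idnn <- function(object, ...) {
  out <- list(model = object,
              final_loss = if (length(object$loss_history))
                utils::tail(object$loss_history, 1L) else NA_real_)
  class(out) <- "summary.idnn"
  out
}

#' @export
print.summary.idnn <- function(x, ...) {
  print(x$model)
  if (is.finite(x$final_loss))
    cat(sprintf("  final pretraining MSE loss: %.6g\n", x$final_loss))
  print(x$model$head)
  invisible(x)
}

#' Plot the pretraining loss curve
#'
#' @param x an [idnn()] fit with a nonempty loss history.
#' @param ... passed to [graphics::plot()].
#' @export
plot.idnn <- function(x, ...) {
  if (!length(x$loss_history))
    stop("no loss history recorded (identity map or iters = 0)")
  graphics::plot(seq_along(x$loss_history), x$loss_history, type = "l",
                 xlab = "iteration", ylab = "batch-mean MSE loss",
                 main = "network pretraining", ...)
  invisible(x)
}

#' @export
coef.idnn <- function(object, ...) coef(object$head)

#' Save / load a fitted hybrid classifier
#'
#' Serializes the full model (map, head, normalizer, config) to a single
#' RDS file; loading restores an object giving identical predictions.
#'
#' @param model an [idnn()] fit.
#' @param path file path.
#' @return `write_idnn` returns `path` invisibly; `read_idnn` the model.
#' @export
write_idnn <- function(model, path) {
  stopifnot(inherits(model, "idnn"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_idnn
#' @export
read_idnn <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "idnn")) stop("file does not hold an idnn model")
  model
}
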