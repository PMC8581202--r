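# Feed-forward network used as an explicit kernel map: the hidden stack
# output is handed to the large-margin SVM head instead of a softmax
# layer. Written as plain matrix recurrences so the gradients can be
# verified against finite differences.

act_forward <- function(z, activation) {
  switch(activation,
         sigmoid = 1 / (1 + exp(-z)),
         relu = pmax(z, 0),
         identity = z,
         stop(sprintf("unknown activation '%s'", activation)))
}

# derivative sigma'(z) expressed through the activation value a = sigma(z)
act_deriv_from_a <- function(a, activation) {
  switch(activation,
         sigmoid = a * (1 - a),
         relu = (a > 0) * 1,
         identity = array(1, dim = dim(a) %||% length(a)),
         stop(sprintf("unknown activation '%s'", activation)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Initialize feed-forward network parameters
#'
#' Creates per-layer weight matrices `W[[h]]` (`n_h x n_{h-1}`) and bias
#' vectors `b[[h]]` for a fully connected network. Weights are drawn
#' uniformly on `(-1, 1)/sqrt(fan_in)`; biases start at zero.
#'
#' @param layer_sizes integer vector, input width followed by each layer's
#'   width, e.g. `c(6, 11, 6, 2)` for a 6-feature input, hidden layers of
#'   11 and 6 units and a 2-unit output.
#' @param activation `"sigmoid"` (default), `"relu"` or `"identity"`,
#'   applied at every layer.
#' @param seed integer seed for the weight draw.
#' @return An object of class `dnn_params` with elements `W`, `b`,
#'   `activation`, `layer_sizes`.
#' @export
dnn_init <- function(layer_sizes, activation = "sigmoid", seed = 1L) {
  stopifnot(length(layer_sizes) >= 2L, all(layer_sizes >= 1L))
  act_forward(0, activation)    # validates the name
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  H <- length(layer_sizes) - 1L
  W <- vector("list", H); b <- vector("list", H)
  for (h in seq_len(H)) {
    n_in <- layer_sizes[h]; n_out <- layer_sizes[h + 1L]
    W[[h]] <- matrix(stats::runif(n_out * n_in, -1, 1) / sqrt(n_in), n_out, n_in)
    b[[h]] <- rep(0, n_out)
  }
  structure(list(W = W, b = b, activation = activation,
                 layer_sizes = as.integer(layer_sizes)),
            class = "dnn_params")
}

#' @export
print.dnn_params <- function(x, ...) {
  cat(sprintf("feed-forward network: %s (%s activation, %d parameters)\n",
              paste(x$layer_sizes, collapse = " -> "), x$activation,
              sum(vapply(x$W, length, 0)) + sum(vapply(x$b, length, 0))))
  invisible(x)
}

#' Forward propagation
#'
#' Evaluates `a^h = sigma(W^h a^{h-1} + b^h)` layer by layer for a batch
#' of inputs. The last activation is the network output; when the network
#' is used as a kernel map it is the mapped feature vector.
#'
#' @param params a [dnn_init()] parameter set.
#' @param X numeric matrix `N x d` (or a single vector of length `d`).
#' @return A list of per-layer activation matrices `a^1 .. a^H`, each
#'   `N x n_h`.
#' @export
dnn_forward <- function(params, X) {
  stopifnot(inherits(params, "dnn_params"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (ncol(X) != params$layer_sizes[1L])
    stop(sprintf("input has %d features, network expects %d",
                 ncol(X), params$layer_sizes[1L]))
  H <- length(params$W)
  acts <- vector("list", H)
  A <- X
  for (h in seq_len(H)) {
    Z <- tcrossprod(A, params$W[[h]])
    Z <- sweep(Z, 2L, params$b[[h]], "+")
    A <- act_forward(Z, params$activation)
    acts[[h]] <- A
  }
  acts
}

#' Mean-squared-error loss
#'
#' For a single sample, `J = ||a^H - y||^2 / 2`; for a batch (matrix
#' inputs), the mean of the per-sample losses.
#'
#' @param aH network output, vector or `N x m` matrix.
#' @param y target, same shape.
#' @return Non-negative scalar; zero iff `aH == y`.
#' @export
mse_loss <- function(aH, y) {
  if (!identical(dim(aH) %||% length(aH), dim(y) %||% length(y)))
    stop("output and target dimensions differ")
  if (is.null(dim(aH))) return(sum((aH - y)^2) / 2)
  mean(rowSums((aH - y)^2) / 2)
}

#' Backpropagation gradients of the MSE loss
#'
#' Computes the gradient of the (batch-mean) MSE loss with respect to
#' every weight matrix and bias vector via the standard recurrences: the
#' output-layer error is `delta^H = (a^H - y) * sigma'(z^H)` and
#' propagates as `delta^h = (W^{h+1})' delta^{h+1} * sigma'(z^h)`
#' (elementwise products), with layer gradients
#' `dW^h = delta^h (a^{h-1})'` and `db^h = delta^h`.
#'
#' @param params a [dnn_init()] parameter set.
#' @param X input batch, `N x d` matrix or vector.
#' @param Y target batch matching the output layer width.
#' @return A list of class `dnn_gradients` with `dW`, `db` mirroring the
#'   parameter shapes, plus the batch `loss`.
#' @export
dnn_backprop <- function(params, X, Y) {
  stopifnot(inherits(params, "dnn_params"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (is.null(dim(Y))) Y <- matrix(Y, nrow = 1L)
  N <- nrow(X)
  if (nrow(Y) != N) stop("X and Y batch sizes differ")
  H <- length(params$W)
  acts <- dnn_forward(params, X)
  if (ncol(Y) != ncol(acts[[H]]))
    stop(sprintf("targets have %d columns, output layer has %d",
                 ncol(Y), ncol(acts[[H]])))
  dW <- vector("list", H); db <- vector("list", H)
  delta <- (acts[[H]] - Y) * act_deriv_from_a(acts[[H]], params$activation)
  for (h in H:1) {
    A_prev <- if (h == 1L) X else acts[[h - 1L]]
    dW[[h]] <- crossprod(delta, A_prev) / N      # delta^h (a^{h-1})', batch mean
    db[[h]] <- colMeans(delta)
    if (h > 1L)
      delta <- (delta %*% params$W[[h]]) *
        act_deriv_from_a(acts[[h - 1L]], params$activation)
  }
  structure(list(dW = dW, db = db, loss = mse_loss(acts[[H]], Y)),
            class = "dnn_gradients")
}

#' Train a network by full-batch gradient descent
#'
#' Runs `iters` gradient-descent steps on the batch-mean MSE loss,
#' recording the loss at every iteration. With `batch_size` set,
#' mini-batches are drawn instead (off by default; the reference
#' procedure is full-batch).
#'
#' @param params initial parameters from [dnn_init()].
#' @param X training inputs, `N x d`.
#' @param Y training targets, `N x m` (e.g. one-hot rows).
#' @param lr learning rate, `> 0`.
#' @param iters number of update steps, `>= 0`; with `iters = 0` the
#'   initialization is returned unchanged.
#' @param batch_size optional mini-batch size; `NULL` (default) uses the
#'   full batch every step.
#' @param seed seed for mini-batch sampling (unused in full-batch mode).
#' @return Updated `dnn_params` with an attached numeric vector
#'   `attr(, "loss_history")` of length `iters`.
#' @export
dnn_train <- function(params, X, Y, lr = 0.07, iters = 2500L,
                      batch_size = NULL, seed = 1L) {
  stopifnot(inherits(params, "dnn_params"), lr > 0, iters >= 0)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (is.null(dim(Y))) Y <- matrix(Y, nrow = 1L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  loss_hist <- numeric(iters)
  H <- length(params$W)
  for (it in seq_len(iters)) {
    if (is.null(batch_size)) {
      g <- dnn_backprop(params, X, Y)
    } else {
      idx <- sample.int(nrow(X), min(batch_size, nrow(X)))
      g <- dnn_backprop(params, X[idx, , drop = FALSE], Y[idx, , drop = FALSE])
    }
    if (!is.finite(g$loss))
      stop(sprintf("non-finite training loss at iteration %d", it))
    for (h in seq_len(H)) {
      params$W[[h]] <- params$W[[h]] - lr * g$dW[[h]]
      params$b[[h]] <- params$b[[h]] - lr * g$db[[h]]
    }
    loss_hist[it] <- g$loss
  }
  attr(params, "loss_history") <- loss_hist
  params
}

#' One-hot encode two-class labels
#'
#' Maps label `+1` (left) to row `(1, 0)` and `-1` (right) to `(0, 1)`;
#' the target coding used when pretraining the kernel-map network with a
#' temporary two-unit output head.
#'
#' @param y labels in `{-1, +1}`.
#' @return An `N x 2` 0/1 matrix.
#' @export
labels_to_onehot <- function(y) {
  if (!all(y %in% c(-1, 1))) stop("labels must be -1 or +1")
  cbind(left = as.numeric(y > 0), right = as.numeric(y < 0))
}
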