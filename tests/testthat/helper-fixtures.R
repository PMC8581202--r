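# Shared fixtures: random classifier instances and a finite-difference
# gradient checker, all built in code at test time.

# random small SVM instance with both classes present
random_svm_instance <- function(seed, n_max = 50L, d_max = 5L) {
  set.seed(seed)
  N <- sample(6:n_max, 1L)
  d <- sample(seq_len(d_max), 1L)
  Phi <- matrix(rnorm(N * d), N, d)
  y <- sign(rnorm(N)); y[y == 0] <- 1
  if (length(unique(y)) < 2L) y[1L] <- -y[1L]
  list(Phi = Phi, y = y,
       C = runif(1, 0.1, 3),
       lambda = sample(c(0, runif(1, 0, 2)), 1L))
}

# central finite-difference check of dnn_backprop over every parameter;
# returns the max of |analytic - numeric| / max(1, |numeric|). The loss is
# only piecewise smooth under relu: entries whose +/- eps evaluations
# straddle a kink (detected by the difference quotient being unstable in
# eps) are excluded, since no derivative comparison is defined there.
fd_gradcheck <- function(params, X, Y, eps = 1e-6) {
  H <- length(params$W)
  out_of <- function(p) {
    acts <- dnn_forward(p, X)
    mse_loss(acts[[H]], Y)
  }
  fd_at <- function(field, h, idx, e) {
    pp <- params; pm <- params
    pp[[field]][[h]][idx] <- pp[[field]][[h]][idx] + e
    pm[[field]][[h]][idx] <- pm[[field]][[h]][idx] - e
    (out_of(pp) - out_of(pm)) / (2 * e)
  }
  g <- dnn_backprop(params, X, Y)
  ga <- list(W = g$dW, b = g$db)
  worst <- 0
  for (h in seq_len(H)) {
    for (field in c("W", "b")) {
      for (idx in seq_along(params[[field]][[h]])) {
        fd <- fd_at(field, h, idx, eps)
        err <- abs(ga[[field]][[h]][idx] - fd) / max(1, abs(fd))
        if (err > 1e-7) {
          fd2 <- fd_at(field, h, idx, eps / 10)
          if (abs(fd - fd2) / max(1, abs(fd)) > 1e-5) next   # kink crossing
          err <- abs(ga[[field]][[h]][idx] - fd2) / max(1, abs(fd2))
        }
        worst <- max(worst, err)
      }
    }
  }
  worst
}

# random small network + batch for gradient checking
random_net_case <- function(seed, activations = c("sigmoid", "relu", "identity")) {
  set.seed(seed)
  act <- sample(activations, 1L)
  sizes <- c(sample(2:5, 1L), sample(2:6, sample(1:3, 1L), replace = TRUE),
             sample(1:3, 1L))
  p <- dnn_init(sizes, activation = act, seed = seed + 1000L)
  # jitter the zero-initialized biases: an all-zero relu layer would put
  # downstream pre-activations exactly on the kink
  p$b <- lapply(p$b, function(v) v + rnorm(length(v), sd = 0.3))
  X <- matrix(rnorm(4L * sizes[1L]), 4L)
  Y <- matrix(runif(4L * sizes[length(sizes)]), 4L)
  list(params = p, X = X, Y = Y, activation = act)
}

tiny_trial_set <- function(n_per_class = 3L, seed = 7L) {
  generate_mi_trials(synth_config(n_per_class = n_per_class, seed = seed))
}
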