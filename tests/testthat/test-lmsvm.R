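test_that("margin_mean is the mean signed functional margin", {
  expect_identical(margin_mean(w = 1, b = 0, Phi = matrix(1), y = 1), 1)
  expect_identical(margin_mean(1, 1, matrix(c(1, -3)), c(1, -1)), 2)
  set.seed(1)
  Phi <- matrix(rnorm(40), 10, 4); w <- rnorm(4); b <- rnorm(1)
  y <- rep(c(1, -1), 5)
  direct <- sum(vapply(1:10, function(i) y[i] * (sum(Phi[i, ] * w) + b), 0)) / 10
  expect_equal(margin_mean(w, b, Phi, y), direct, tolerance = 1e-12)
  expect_error(margin_mean(w, b, Phi[0, , drop = FALSE], numeric(0)), "empty")
})

test_that("objective matches term-by-term recomputation", {
  set.seed(2)
  N <- 8; Phi <- matrix(rnorm(N * 3), N, 3); y <- rep(c(1, -1), 4)
  # zero model, lambda 0: every slack is 1, objective C*N
  expect_equal(lmsvm_objective(rep(0, 3), 0, Phi, y, C = 2.5, lambda = 0),
               2.5 * N)
  # separable with margins >= 1: slacks vanish
  w <- c(10, 0, 0); Phi_sep <- matrix(c(1, -1), 2, 1); y_sep <- c(1, -1)
  expect_equal(lmsvm_objective(10, 0, Phi_sep, y_sep, C = 1, lambda = 0.3),
               0.5 * 100 - 0.3 * 10)
  # random instance vs direct summation
  w <- rnorm(3); b <- rnorm(1); C <- 1.4; lam <- 0.6
  f <- as.vector(Phi %*% w) + b
  direct <- 0.5 * sum(w^2) + C * sum(pmax(0, 1 - y * f)^2) - lam * mean(y * f)
  expect_equal(lmsvm_objective(w, b, Phi, y, C, lam), direct, tolerance = 1e-12)
})

test_that("the two-point problem has its closed-form solution", {
  # stationarity of w^2/2 + 2C(1-w)^2 - lam*w gives w = (4C+lam)/(1+4C)
  # while the hinge is active (w < 1, i.e. lam < 1); for lam >= 1 the
  # slacks vanish and w^2/2 - lam*w is minimized at w = lam
  Phi <- matrix(c(1, -1), 2, 1); y <- c(1, -1)
  for (C in c(0.5, 1, 4)) {
    for (lam in c(0, 0.5, 2)) {
      expect_w <- if (lam < 1) (4 * C + lam) / (1 + 4 * C) else lam
      fit <- lmsvm(Phi, y, C = C, lambda = lam)
      expect_equal(fit$w, expect_w, tolerance = 1e-6,
                   label = sprintf("bfgs w (C=%g, lam=%g)", C, lam))
      expect_equal(fit$b, 0, tolerance = 1e-6)
      expect_equal(fit$margin_mean, expect_w, tolerance = 1e-6)
      qp <- lmsvm_qp(Phi, y, C = C, lambda = lam)
      expect_equal(qp$w, expect_w, tolerance = 1e-6,
                   label = sprintf("qp w (C=%g, lam=%g)", C, lam))
    }
  }
})

test_that("primal solver and active-set reference agree on random instances", {
  for (seed in 1:20) {
    inst <- random_svm_instance(seed)
    a <- lmsvm(inst$Phi, inst$y, C = inst$C, lambda = inst$lambda)
    b <- lmsvm_qp(inst$Phi, inst$y, C = inst$C, lambda = inst$lambda)
    expect_lt(abs(a$objective - b$objective), 1e-5)
    expect_equal(a$w, b$w, tolerance = 1e-3)
  }
})

test_that("stored diagnostics are recomputable from w and b", {
  inst <- random_svm_instance(33)
  fit <- lmsvm(inst$Phi, inst$y, C = inst$C, lambda = inst$lambda)
  expect_equal(fit$margin_mean,
               margin_mean(fit$w, fit$b, inst$Phi, inst$y), tolerance = 1e-12)
  expect_true(all(fit$slacks >= 0))
  expect_equal(fit$objective,
               lmsvm_objective(fit$w, fit$b, inst$Phi, inst$y,
                               inst$C, inst$lambda), tolerance = 1e-10)
})

test_that("label flip maps the optimum to its negation, objective unchanged", {
  inst <- random_svm_instance(5)
  a <- lmsvm(inst$Phi, inst$y, C = inst$C, lambda = inst$lambda)
  b <- lmsvm(inst$Phi, -inst$y, C = inst$C, lambda = inst$lambda)
  expect_equal(b$w, -a$w, tolerance = 1e-5)
  expect_equal(b$b, -a$b, tolerance = 1e-5)
  expect_equal(b$objective, a$objective, tolerance = 1e-8)
})

test_that("training margin mean is non-decreasing in lambda", {
  fm <- generate_gaussian_features(25, 3, separation = 2, seed = 12)
  gam <- vapply(c(0, 0.01, 0.1, 1, 10),
                function(l) lmsvm(fm, C = 1, lambda = l)$margin_mean, 0)
  expect_true(all(diff(gam) >= -1e-8))
  # the margin-distribution claim in its testable form
  expect_gte(gam[3], gam[1] - 1e-8)
})

test_that("prediction applies sign with the documented zero tie-break", {
  m <- structure(list(w = c(0, 0), b = 3, feature_names = NULL),
                 class = "lmsvm")
  expect_identical(predict(m, matrix(rnorm(10), 5, 2)), rep(1, 5))
  m0 <- structure(list(w = c(1, 0), b = 0, feature_names = NULL),
                  class = "lmsvm")
  expect_identical(predict(m0, matrix(c(0, 0), 1, 2)), 1)   # score 0 -> +1
  # negating the model negates every score
  inst <- random_svm_instance(9)
  fit <- lmsvm(inst$Phi, inst$y, C = 1, lambda = 0.1)
  neg <- fit; neg$w <- -fit$w; neg$b <- -fit$b
  expect_equal(predict(neg, inst$Phi, type = "score"),
               -predict(fit, inst$Phi, type = "score"), tolerance = 1e-12)
  expect_error(predict(fit, matrix(0, 2, ncol(inst$Phi) + 1)), "features")
})

test_that("degenerate inputs are rejected", {
  expect_error(lmsvm(matrix(1:4, 4, 1), rep(1, 4)), "both classes")
  expect_error(lmsvm_qp(matrix(1:4, 4, 1), rep(1, 4)), "both classes")
  expect_error(lmsvm_qp(matrix(rnorm(800), 400, 2),
                        rep(c(1, -1), 200), max_n = 300), "limited")
})
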