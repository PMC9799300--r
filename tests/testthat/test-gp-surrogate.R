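test_that("kernel closed forms and limits hold", {
  expect_equal(rq_kernel(c(0, 0), c(0, 0), l = 1, alpha = 1), 1)
  # ||x - x2|| = sqrt(2): (1 + 2/2)^(-1) = 0.5
  expect_equal(rq_kernel(c(0, 0), c(1, 1), l = 1, alpha = 1), 0.5)
  # alpha -> infinity: squared-exponential limit
  d <- 0.7
  expect_equal(rq_kernel(c(0, 0), c(d, 0), l = 1.3, alpha = 1e6),
               exp(-d^2 / (2 * 1.3^2)), tolerance = 1e-5)
  expect_equal(white_kernel(c(1, 2), c(1, 2), 0.3), 0.3)
  expect_equal(white_kernel(c(1, 2), c(1, 2.0001), 0.3), 0)
  # additive combination on identical inputs
  k_same <- rq_kernel(c(1, 1), c(1, 1), 1, 1) + white_kernel(c(1, 1), c(1, 1), 0.2)
  expect_equal(k_same, 1.2)
  # symmetry and monotone decrease in distance
  set.seed(1)
  for (i in 1:10) {
    x <- rnorm(2); y <- rnorm(2)
    expect_equal(rq_kernel(x, y, 0.8, 2), rq_kernel(y, x, 0.8, 2))
  }
  ds <- seq(0, 3, by = 0.5)
  ks <- vapply(ds, function(d) rq_kernel(c(0, 0), c(d, 0), 1, 2), numeric(1))
  expect_true(all(diff(ks) < 0))
  expect_true(all(ks > 0 & ks <= 1))
})

test_that("kernel Gram matrices are symmetric positive semi-definite", {
  set.seed(12)
  for (i in 1:5) {
    X <- matrix(runif(40, -2, 2), 20, 2)
    K <- grnabc:::rq_kernel_matrix(X, X, l = runif(1, 0.3, 3), alpha = runif(1, 0.3, 5))
    expect_equal(K, t(K), tolerance = 1e-12)
    expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  }
})

test_that("GP predictions agree with a dense closed-form oracle", {
  set.seed(13)
  X <- cbind(runif(40, -2.4, 1.2), runif(40, -0.6, 1.2))
  y <- sin(X[, 1]) + 0.5 * X[, 2] + rnorm(40, 0, 0.05)
  surr <- train_surrogate(X, y, restarts = 3, seed = 2)
  Xq <- cbind(runif(10, -2.4, 1.2), runif(10, -0.6, 1.2))
  p <- predict(surr, Xq)
  o <- gp_dense_oracle(surr, Xq)
  expect_equal(p$mean, o$mean, tolerance = 1e-6)
  expect_equal(p$sd, o$sd, tolerance = 1e-6)
  expect_true(all(p$sd >= 0))
})

test_that("training reaches at least the unoptimised likelihood and interpolates", {
  set.seed(14)
  X <- cbind(runif(60, -2, 1), runif(60, -0.5, 1))
  y_lin <- 0.3 + 0.7 * X[, 1] - 0.2 * X[, 2] # noise-free linear surface
  surr <- train_surrogate(X, y_lin, restarts = 5, seed = 3)
  Xq <- cbind(runif(20, -1.5, 0.5), runif(20, -0.3, 0.8)) # mid-domain
  p <- predict(surr, Xq)
  truth <- 0.3 + 0.7 * Xq[, 1] - 0.2 * Xq[, 2]
  expect_lt(max(abs(p$mean - truth) / (abs(truth) + 0.1)), 0.01)
  # duplicated input with conflicting targets forces a positive noise level
  Xd <- rbind(X, X[1, , drop = FALSE])
  yd <- c(y_lin, y_lin[1] + 0.5)
  surr_d <- train_surrogate(Xd, yd, restarts = 3, seed = 4)
  expect_gt(surr_d$hyperparams$gamma_noise, 1e-6)
  # degenerate and invalid inputs are rejected
  expect_error(train_surrogate(matrix(1, 5, 2), rep(1, 5)), "degenerate")
  expect_error(train_surrogate(X[1:5, ], c(1, 2, NA, 4, 5)), "non-finite")
})

test_that("hyperparameter recovery on a synthetic GP draw is within a factor of two", {
  set.seed(15)
  n <- 200
  X <- cbind(runif(n, -2.4, 1.2), runif(n, -0.6, 1.2))
  l_true <- 0.8
  K <- grnabc:::rq_kernel_matrix(X, X, l = l_true, alpha = 2)
  diag(K) <- diag(K) + 1e-8
  y <- drop(t(chol(K)) %*% rnorm(n)) + rnorm(n, 0, sqrt(0.05))
  surr <- train_surrogate(X, y, restarts = 5, seed = 5)
  expect_gt(surr$hyperparams$l, l_true / 2)
  expect_lt(surr$hyperparams$l, l_true * 2)
  expect_gt(surr$hyperparams$gamma_noise, 0.01)
})

test_that("predictions are invariant to training-data permutation", {
  set.seed(16)
  X <- cbind(runif(30, -2, 1), runif(30, -0.5, 1))
  y <- cos(X[, 1]) + X[, 2] + rnorm(30, 0, 0.02)
  perm <- sample(30)
  s1 <- train_surrogate(X, y, restarts = 3, seed = 6)
  s2 <- train_surrogate(X[perm, ], y[perm], restarts = 3, seed = 6)
  Xq <- cbind(runif(8, -1.8, 0.8), runif(8, -0.4, 0.9))
  expect_equal(predict(s1, Xq)$mean, predict(s2, Xq)$mean, tolerance = 1e-4)
  expect_equal(predict(s1, Xq)$sd, predict(s2, Xq)$sd, tolerance = 1e-4)
})

test_that("predictive structure behaves at and away from the training data", {
  set.seed(17)
  X <- cbind(c(-2, -1, 0, 1), c(0, 0.5, 1, -0.5))
  y <- c(0.2, 0.4, 0.1, 0.9)
  surr <- train_surrogate(X, y, restarts = 3, seed = 7)
  p_train <- predict(surr, X)
  expect_true(all(abs(p_train$mean - y) <=
                    3 * sqrt(surr$hyperparams$gamma_noise) * surr$y_sd + 1e-6))
  # more certain at data than midway between distant points
  p_mid <- predict(surr, c(-1.5, 0.25))
  expect_lte(predict(surr, X[1, ])$sd, p_mid$sd + 1e-9)
  # far away: mean reverts to the training mean, sd to the prior amplitude
  p_far <- predict(surr, c(60, 60))
  expect_equal(p_far$mean, mean(y), tolerance = 1e-3)
  expect_equal(p_far$sd, surr$y_sd * sqrt(1 + surr$hyperparams$gamma_noise),
               tolerance = 1e-3)
})

test_that("sampled distances are truncated-normal draws around the prediction", {
  set.seed(18)
  X <- cbind(runif(25, -2, 1), runif(25, -0.5, 1))
  y <- 2 + sin(2 * X[, 1]) + rnorm(25, 0, 0.1)
  surr <- train_surrogate(X, y, restarts = 3, seed = 8)
  th <- c(-0.5, 0.3)
  p <- predict(surr, th)
  draws <- sample_distance(surr, matrix(rep(th, 5000), ncol = 2, byrow = TRUE))
  expect_true(all(draws >= 0))
  # truncation mass is negligible here, so the MC mean matches the prediction
  expect_lt(abs(mean(draws) - p$mean), 4 * p$sd / sqrt(5000))
})

test_that("surrogates round-trip through the JSON archive", {
  set.seed(19)
  X <- cbind(runif(20, -2, 1), runif(20, -0.5, 1))
  y <- X[, 1]^2 + rnorm(20, 0, 0.05)
  surr <- train_surrogate(X, y, restarts = 2, seed = 9)
  f <- withr::local_tempfile(fileext = ".json")
  save_surrogate(surr, f)
  back <- load_surrogate(f)
  Xq <- cbind(runif(5, -2, 1), runif(5, -0.5, 1))
  expect_equal(predict(back, Xq)$mean, predict(surr, Xq)$mean, tolerance = 1e-9)
  expect_equal(predict(back, Xq)$sd, predict(surr, Xq)$sd, tolerance = 1e-9)
  diag <- surrogate_diagnostic(surr, seed = 2)
  expect_true(is.logical(diag$flagged))
  expect_length(diag$z, 4)
})
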