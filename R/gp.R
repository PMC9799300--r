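# Gaussian-process surrogate of a distance metric over (log10 D,
# log10 chi). Kernel: rational quadratic plus white noise,
#   k1(x,x') = (1 + d(x,x')^2 / (2 alpha l^2))^(-alpha)
#   k2(x,x') = gamma_noise if x == x' else 0
#   k = k1 + k2,
# with hyperparameters fitted by maximising the log marginal likelihood
# with L-BFGS-B (multi-restart). Targets are standardised internally; the
# predictive distribution includes the fitted white-noise variance, so
# sampled distances reproduce the stochastic scatter of the measured
# distances around their mean — the stochastic particle-acceptance aspect
# of ABC.

#' Rational-quadratic kernel
#'
#' `k1(x, x') = (1 + ||x - x'||^2 / (2 alpha l^2))^(-alpha)`: a scale
#' mixture of squared exponentials; value in (0, 1\], symmetric,
#' decreasing in the distance, and approaching `exp(-d^2 / (2 l^2))` as
#' `alpha -> Inf`.
#'
#' @param x,x2 numeric vectors (same length).
#' @param l length-scale (> 0), in log-parameter units.
#' @param alpha scale-mixture exponent (> 0).
#' @return Kernel value.
#' @export
rq_kernel <- function(x, x2, l, alpha) {
  check_positive(l, "l"); check_positive(alpha, "alpha")
  d2 <- sum((x - x2)^2)
  (1 + d2 / (2 * alpha * l^2))^(-alpha)
}

#' White-noise kernel
#'
#' `k2(x, x') = gamma_noise` on identical inputs, 0 otherwise.
#'
#' @param x,x2 numeric vectors.
#' @param gamma_noise noise level (>= 0).
#' @export
white_kernel <- function(x, x2, gamma_noise) {
  if (gamma_noise < 0) stop_domain("`gamma_noise` must be >= 0")
  if (isTRUE(all(x == x2))) gamma_noise else 0
}

# cross-covariance matrix under the RQ kernel
rq_kernel_matrix <- function(X, Y, l, alpha) {
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  d2[d2 < 0] <- 0
  (1 + d2 / (2 * alpha * l^2))^(-alpha)
}

JITTER <- 1e-10

#' Train a GP surrogate of distance values over (log10 D, log10 chi)
#'
#' @param inputs n x 2 matrix of (log10 D, log10 chi) training locations
#'   (n >= 2).
#' @param distances n-vector of measured distance values (finite).
#' @param restarts number of L-BFGS-B restarts from random initial
#'   hyperparameters (log-uniform draws).
#' @param seed optional integer seed for the restart draws.
#' @return An object of class `distance_surrogate` with the training set,
#'   fitted hyperparameters (`l`, `alpha`, `gamma_noise`), the achieved
#'   log marginal likelihood and a cached Cholesky factorisation for O(n)
#'   predictive evaluations per query.
#' @export
train_surrogate <- function(inputs, distances, restarts = 5, seed = NULL) {
  X <- as.matrix(inputs)
  y <- as.numeric(distances)
  n <- nrow(X)
  if (n < 2L) stop_domain("need at least 2 training points")
  if (ncol(X) != 2L) stop_domain("inputs must be an n x 2 matrix of (log10 D, log10 chi)")
  if (any(!is.finite(X)) || any(!is.finite(y))) stop_domain("non-finite training data")
  if (all(duplicated(X)[-1])) stop_domain("degenerate training set: all inputs identical")

  y_mean <- mean(y)
  y_sd <- sd(y)
  if (!is.finite(y_sd) || y_sd == 0) y_sd <- 1
  ys <- (y - y_mean) / y_sd

  neg_loglik <- function(logpar) {
    l <- exp(logpar[1]); alpha <- exp(logpar[2]); gam <- exp(logpar[3])
    K <- rq_kernel_matrix(X, X, l, alpha)
    diag(K) <- diag(K) + gam + JITTER
    U <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(U)) return(1e10)
    a <- backsolve(U, backsolve(U, ys, transpose = TRUE))
    as.numeric(0.5 * sum(ys * a) + sum(log(diag(U))) + 0.5 * n * log(2 * pi))
  }

  lower <- log(c(1e-2, 1e-2, 1e-8))
  upper <- log(c(1e2, 1e3, 1e2))
  inits <- list(log(c(1, 1, 0.1)))
  if (restarts > 1) {
    extra <- withr::with_seed(
      if (is.null(seed)) 0L else as.integer(seed),
      lapply(seq_len(restarts - 1), function(i) {
        runif(3, lower, pmin(upper, log(c(10, 10, 1))))
      })
    )
    inits <- c(inits, extra)
  }

  best <- NULL
  for (init in inits) {
    fit <- tryCatch(
      optim(init, neg_loglik, method = "L-BFGS-B", lower = lower, upper = upper),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop_domain("GP hyperparameter optimisation failed")
  # never worse than the (unoptimised) first initial point
  if (best$value > neg_loglik(inits[[1]])) {
    best <- list(par = inits[[1]], value = neg_loglik(inits[[1]]))
  }

  l <- exp(best$par[1]); alpha <- exp(best$par[2]); gam <- exp(best$par[3])
  K <- rq_kernel_matrix(X, X, l, alpha)
  diag(K) <- diag(K) + gam + JITTER
  U <- chol(K)
  alpha_vec <- backsolve(U, backsolve(U, ys, transpose = TRUE))
  structure(
    list(X = X, y = y, y_mean = y_mean, y_sd = y_sd,
         hyperparams = list(l = l, alpha = alpha, gamma_noise = gam),
         chol_U = U, alpha_vec = alpha_vec,
         log_marginal_likelihood = -best$value),
    class = "distance_surrogate"
  )
}

#' @export
print.distance_surrogate <- function(x, ...) {
  hp <- x$hyperparams
  cat(sprintf(
    "GP distance surrogate: n=%d, l=%.3g, alpha=%.3g, gamma_noise=%.3g, logML=%.2f\n",
    nrow(x$X), hp$l, hp$alpha, hp$gamma_noise, x$log_marginal_likelihood))
  invisible(x)
}

#' Predictive mean and standard deviation of a distance surrogate
#'
#' Standard GP prediction with the fitted kernel; the predictive variance
#' includes the white-noise term, so it describes a *measured* distance at
#' the query point rather than only the latent mean. Far from all
#' training points the mean reverts to the training mean and the sd to
#' the prior amplitude.
#'
#' @param object a `distance_surrogate`.
#' @param theta query points: a length-2 vector or an m x 2 matrix of
#'   (log10 D, log10 chi).
#' @param ... unused.
#' @return List with numeric vectors `mean` and `sd`.
#' @export
predict.distance_surrogate <- function(object, theta, ...) {
  Xq <- if (is.null(dim(theta))) matrix(theta, ncol = 2) else as.matrix(theta)
  hp <- object$hyperparams
  Ks <- rq_kernel_matrix(object$X, Xq, hp$l, hp$alpha) # n x m
  mu <- drop(crossprod(Ks, object$alpha_vec))
  v <- backsolve(object$chol_U, Ks, transpose = TRUE)
  var <- (1 + hp$gamma_noise + JITTER) - colSums(v^2)
  var[var < 1e-24] <- 1e-24
  list(mean = object$y_mean + object$y_sd * mu,
       sd = object$y_sd * sqrt(var))
}

#' Sample stochastic distances from a surrogate
#'
#' Draws from `Normal(mean(theta), sd(theta))` truncated below at 0 —
#' distances are non-negative. When `sd = 0` the mean is returned
#' deterministically.
#'
#' @param surrogate a `distance_surrogate`.
#' @param theta query points as in [predict.distance_surrogate()].
#' @return Numeric vector of non-negative sampled distances (one per row).
#' @export
sample_distance <- function(surrogate, theta) {
  p <- predict(surrogate, theta)
  m <- length(p$mean)
  lo <- pnorm(0, p$mean, p$sd)
  u <- runif(m, lo, 1)
  d <- qnorm(u, p$mean, p$sd)
  d[p$sd == 0] <- p$mean[p$sd == 0]
  pmax(d, 0)
}

#' Held-out goodness-of-fit diagnostic for a surrogate
#'
#' Refits the surrogate's hyperparameters on a training split and
#' standardises the held-out residuals; the fit is flagged when more than
#' `flag_frac` of held-out points fall outside |z| > 3.
#'
#' @param surrogate a `distance_surrogate`.
#' @param holdout_frac fraction of points held out.
#' @param seed integer seed for the split.
#' @param flag_frac flagging threshold on the |z| > 3 fraction.
#' @return List with `z` (held-out standardized residuals), `frac_extreme`
#'   and logical `flagged`.
#' @export
surrogate_diagnostic <- function(surrogate, holdout_frac = 0.2, seed = 1L,
                                 flag_frac = 0.05) {
  n <- nrow(surrogate$X)
  n_hold <- max(1L, floor(holdout_frac * n))
  idx <- withr::with_seed(as.integer(seed), sample.int(n, n_hold))
  fit <- train_surrogate(surrogate$X[-idx, , drop = FALSE],
                         surrogate$y[-idx], restarts = 3, seed = seed)
  p <- predict(fit, surrogate$X[idx, , drop = FALSE])
  z <- (surrogate$y[idx] - p$mean) / p$sd
  frac <- mean(abs(z) > 3)
  list(z = z, frac_extreme = frac, flagged = frac > flag_frac)
}

#' Save / load a surrogate (versioned JSON archive)
#'
#' Stores inputs, targets and hyperparameters; the Cholesky cache is
#' rebuilt on load, so re-runs need no retraining.
#'
#' @param surrogate a `distance_surrogate`.
#' @param path JSON file path.
#' @export
save_surrogate <- function(surrogate, path) {
  obj <- list(
    schema_version = 1L,
    inputs = unname(surrogate$X),
    targets = surrogate$y,
    y_mean = surrogate$y_mean, y_sd = surrogate$y_sd,
    hyperparams = surrogate$hyperparams,
    log_marginal_likelihood = surrogate$log_marginal_likelihood
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_surrogate
#' @export
load_surrogate <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema_version) || obj$schema_version != 1L) {
    stop_domain("unsupported surrogate schema version")
  }
  X <- matrix(as.numeric(obj$inputs), ncol = 2)
  hp <- obj$hyperparams
  y <- as.numeric(obj$targets)
  ys <- (y - obj$y_mean) / obj$y_sd
  K <- rq_kernel_matrix(X, X, hp$l, hp$alpha)
  diag(K) <- diag(K) + hp$gamma_noise + JITTER
  U <- chol(K)
  structure(
    list(X = X, y = y, y_mean = obj$y_mean, y_sd = obj$y_sd,
         hyperparams = list(l = hp$l, alpha = hp$alpha,
                            gamma_noise = hp$gamma_noise),
         chol_U = U,
         alpha_vec = backsolve(U, backsolve(U, ys, transpose = TRUE)),
         log_marginal_likelihood = obj$log_marginal_likelihood),
    class = "distance_surrogate"
  )
}
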