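# Independent oracles used across test files. These deliberately avoid the
# package's own code paths: features are re-implemented with plain loops,
# the Kolmogorov statistic is evaluated by brute force over a value grid,
# GP predictions come from a dense solve(), and first-passage times come
# from a vectorised Brownian walker with bridge-crossing detection.

# ---- reference time-series features (loop-based re-implementations) ----
ref_feature <- function(x, name) {
  n <- length(x)
  mu <- sum(x) / n
  run_len <- function(cond) {
    best <- 0; cur <- 0
    for (i in seq_len(n)) {
      if (cond[i]) cur <- cur + 1 else cur <- 0
      if (cur > best) best <- cur
    }
    best
  }
  cm <- function(k) {
    tot <- 0
    for (v in x) tot <- tot + (v - mu)^k
    tot / n
  }
  switch(name,
    sum = sum(x),
    abs_energy = { t <- 0; for (v in x) t <- t + v * v; t },
    mean_abs_change = {
      t <- 0
      for (i in 2:n) t <- t + abs(x[i] - x[i - 1])
      t / (n - 1)
    },
    mean_change = (x[n] - x[1]) / (n - 1),
    median = stats::median(x),
    mean = mu,
    length = n,
    standard_deviation = sqrt(cm(2)),
    skewness = if (cm(2) == 0) 0 else cm(3) / cm(2)^1.5,
    kurtosis = if (cm(2) == 0) 0 else cm(4) / cm(2)^2 - 3,
    longest_strike_below_mean = run_len(x < mu),
    longest_strike_above_mean = run_len(x > mu),
    last_location_of_maximum = max(seq_len(n)[x == max(x)]) / n,
    first_location_of_maximum = (min(seq_len(n)[x == max(x)]) - 1) / n,
    last_location_of_minimum = max(seq_len(n)[x == min(x)]) / n,
    first_location_of_minimum = (min(seq_len(n)[x == min(x)]) - 1) / n,
    maximum = max(x),
    minimum = min(x),
    stop("unknown feature in reference implementation: ", name)
  )
}

# ---- brute-force two-sample Kolmogorov statistic on integer samples ----
brute_ks <- function(a, b) {
  grid <- seq(min(c(a, b)), max(c(a, b)))
  best <- 0
  for (v in grid) {
    d <- abs(sum(a <= v) / length(a) - sum(b <= v) / length(b))
    if (d > best) best <- d
  }
  best
}

# ---- dense closed-form GP predictions (independent linear algebra) ----
gp_dense_oracle <- function(surr, Xq) {
  X <- surr$X
  hp <- surr$hyperparams
  n <- nrow(X)
  k1 <- function(a, b) {
    d2 <- sum((a - b)^2)
    (1 + d2 / (2 * hp$alpha * hp$l^2))^(-hp$alpha)
  }
  K <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) K[i, j] <- k1(X[i, ], X[j, ])
  diag(K) <- diag(K) + hp$gamma_noise + 1e-10
  Ki <- solve(K)
  ys <- (surr$y - surr$y_mean) / surr$y_sd
  m <- nrow(Xq)
  mu <- numeric(m); sd_ <- numeric(m)
  for (q in 1:m) {
    ks <- vapply(1:n, function(i) k1(X[i, ], Xq[q, ]), numeric(1))
    mu[q] <- surr$y_mean + surr$y_sd * sum(ks * (Ki %*% ys))
    v <- (1 + hp$gamma_noise + 1e-10) - drop(t(ks) %*% Ki %*% ks)
    sd_[q] <- surr$y_sd * sqrt(max(v, 1e-24))
  }
  list(mean = mu, sd = sd_)
}

# ---- Brownian walker mean first-passage time oracle -------------------
# Absorbing sphere of radius `a`; walkers start uniformly (by volume) in
# [start_lo, start_hi]; optional reflecting outer wall. Crossing within a
# step is detected with the Brownian-bridge probability
# exp(-d1*d2/(D*dt)), which removes most time-discretisation bias.
fpt_mc_oracle <- function(D, dt, n, a, from_inside, start_lo, start_hi,
                          R_reflect = NULL, max_steps = 2e5) {
  u <- runif(n)
  rho <- (start_lo^3 + u * (start_hi^3 - start_lo^3))^(1 / 3)
  dir <- matrix(rnorm(3 * n), n)
  dir <- dir / sqrt(rowSums(dir^2))
  pos <- dir * rho
  nr <- rho
  s <- sqrt(2 * D * dt)
  alive <- rep(TRUE, n)
  tfp <- numeric(n)
  steps <- 0
  while (any(alive) && steps < max_steps) {
    steps <- steps + 1
    idx <- which(alive)
    k <- length(idx)
    d1 <- abs(nr[idx] - a)
    p <- pos[idx, , drop = FALSE] + matrix(rnorm(3 * k, 0, s), k)
    nr1 <- sqrt(rowSums(p^2))
    if (!is.null(R_reflect)) {
      over <- nr1 > R_reflect
      if (any(over)) {
        f <- (2 * R_reflect - nr1[over]) / nr1[over]
        p[over, ] <- p[over, ] * f
        nr1[over] <- abs(2 * R_reflect - nr1[over])
      }
    }
    crossed <- if (from_inside) nr1 >= a else nr1 <= a
    pb <- exp(-d1 * abs(nr1 - a) / (D * dt))
    absorbed <- crossed | (runif(k) < pb)
    tfp[idx[absorbed]] <- steps * dt
    alive[idx[absorbed]] <- FALSE
    keep <- !absorbed
    pos[idx[keep], ] <- p[keep, , drop = FALSE]
    nr[idx[keep]] <- nr1[keep]
  }
  mean(tfp)
}

# ---- exact no-feedback compartment means (linear-system oracle) -------
# mRNA: d/dt (Mn, Mc) = (mu, 0) + A (Mn, Mc) with hops and degradation;
# protein mean = kappa * Mc / gamma (degradation is uniform in space).
cbm_nofeedback_means <- function(D, chi = 1, r = 2.5, R = 6) {
  mu <- 3 * chi; kappa <- 1 * chi; gamma <- 0.04 * chi
  rates <- compartment_rates(D, r, R)
  A <- rbind(c(-(gamma + rates$k_exit), rates$k_entry),
             c(rates$k_exit, -(gamma + rates$k_entry)))
  m <- solve(-A, c(mu, 0))
  list(mRNA = sum(m), P = kappa * m[2] / gamma)
}

# ---- small deterministic ensembles for distance/operator tests --------
toy_ensemble <- function(trajs, times = NULL, species = c("mRNA", "P"),
                         model = "WMM", D = 0.6, chi = 1) {
  if (is.null(times)) times <- seq_len(nrow(trajs[[1]]))
  trajectory_ensemble(trajs, times, species, model, D, chi)
}

# quick WMM ensembles for dataset tests
quick_ensemble <- function(n_traj = 3, n_samples = 12, seed = 1,
                           D = 0.6, chi = 1, model = "wmm") {
  simulate_ensemble(make_parameters(chi, D), model, n_traj,
                    sim_config(t_burn = 50, n_samples = n_samples,
                               dt_sample = 2), seed = seed)
}
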