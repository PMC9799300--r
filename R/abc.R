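# Likelihood-free posterior estimation over (D, chi): plain ABC rejection
# and the sequential Monte Carlo (SMC) variant with adaptive, quantile-
# based acceptance thresholds and a Gaussian perturbation kernel adapted
# to the previous population's weighted covariance in log10-parameter
# space. Distances come either from a GP surrogate (the pipeline's mode —
# zero simulator calls) or from direct simulation (desk-scale validation).

#' SMC configuration
#'
#' @param population particles per generation (>= 10).
#' @param generations number of SMC generations.
#' @param quantile adaptive-threshold level in (0, 1): each generation's
#'   epsilon is this quantile (default: the median) of the previous
#'   generation's accepted distances; the first generation uses the same
#'   quantile of a 1000-draw prior distance pilot.
#' @param kernel_scale multiplier on the weighted empirical covariance for
#'   the multivariate-normal perturbation kernel (default 2).
#' @param final_epsilon optional hard threshold; generations stop early
#'   once epsilon falls below it.
#' @param max_draws_per_gen proposal budget per generation, as a multiple
#'   of the population size.
#' @param pilot_draws prior draws used to set the first generation's
#'   epsilon.
#' @param seed optional integer seed.
#' @return An object of class `smc_config`.
#' @export
smc_config <- function(population = 200, generations = 8, quantile = 0.5,
                       kernel_scale = 2, final_epsilon = NULL,
                       max_draws_per_gen = 2000, pilot_draws = 1000,
                       seed = NULL) {
  if (population < 10) stop_domain("`population` must be >= 10")
  if (quantile <= 0 || quantile >= 1) stop_domain("`quantile` must be in (0, 1)")
  structure(
    list(population = as.integer(population),
         generations = as.integer(generations),
         quantile = quantile, kernel_scale = kernel_scale,
         final_epsilon = final_epsilon,
         max_draws_per_gen = max_draws_per_gen,
         pilot_draws = as.integer(pilot_draws),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "smc_config"
  )
}

new_posterior <- function(samples, weights, distances = NULL,
                          epsilon_trace = numeric(0),
                          acceptance_trace = numeric(0), provenance = NULL) {
  colnames(samples) <- c("D", "chi")
  structure(
    list(samples = samples, weights = weights / sum(weights),
         distances = distances, epsilon_trace = epsilon_trace,
         acceptance_trace = acceptance_trace, provenance = provenance),
    class = "abc_posterior"
  )
}

#' @export
print.abc_posterior <- function(x, ...) {
  wm <- posterior_mean(x)
  cat(sprintf("ABC posterior: %d samples, weighted mean D=%.3g chi=%.3g\n",
              nrow(x$samples), wm["D"], wm["chi"]))
  if (length(x$epsilon_trace)) {
    cat("  epsilon trace:", paste(signif(x$epsilon_trace, 3), collapse = " -> "), "\n")
  }
  invisible(x)
}

#' Weighted posterior mean in linear or log10 scale
#'
#' @param posterior an `abc_posterior`.
#' @param log10_scale average in log10 space (geometric mean) when `TRUE`.
#' @export
posterior_mean <- function(posterior, log10_scale = FALSE) {
  s <- posterior$samples
  w <- posterior$weights
  if (log10_scale) {
    c(D = sum(w * log10(s[, "D"])), chi = sum(w * log10(s[, "chi"])))
  } else {
    c(D = sum(w * s[, "D"]), chi = sum(w * s[, "chi"]))
  }
}

#' Weighted credible interval box for (D, chi)
#'
#' Marginal weighted quantile intervals at level `level`, computed in
#' log10 space.
#'
#' @param posterior an `abc_posterior`.
#' @param level credible level (default 0.9).
#' @return 2 x 2 matrix: rows D, chi; columns lower, upper (linear scale).
#' @export
credible_box <- function(posterior, level = 0.9) {
  a <- (1 - level) / 2
  wq <- function(x, w, p) {
    o <- order(x)
    cw <- cumsum(w[o])
    x[o][pmin(length(x), findInterval(p, cw) + 1L)]
  }
  s <- posterior$samples; w <- posterior$weights
  out <- rbind(
    D = wq(s[, "D"], w, c(a, 1 - a)),
    chi = wq(s[, "chi"], w, c(a, 1 - a))
  )
  colnames(out) <- c("lower", "upper")
  out
}

#' ABC rejection sampling
#'
#' Draws parameters from the prior, computes (or emulates) the distance to
#' the observed data and accepts draws with distance <= epsilon, until
#' `n_accept` acceptances or the trial cap is exhausted.
#'
#' @param prior a `grn_prior`.
#' @param distance_fn `function(theta_matrix) -> numeric`: vectorised
#'   distance of each (D, chi) row to the observed data.
#' @param epsilon acceptance threshold (> 0).
#' @param n_accept required number of accepted samples.
#' @param seed optional integer seed.
#' @param max_trials trial cap; reaching it with zero acceptances is an
#'   explicit error with diagnostics.
#' @return An `abc_posterior` with equal weights.
#' @export
abc_rejection <- function(prior, distance_fn, epsilon, n_accept, seed = NULL,
                          max_trials = 1e6) {
  check_positive(epsilon, "epsilon")
  run <- function() {
    acc <- matrix(numeric(0), ncol = 2)
    dists <- numeric(0)
    trials <- 0
    batch <- max(1000L, n_accept)
    while (nrow(acc) < n_accept && trials < max_trials) {
      th <- prior_sample(prior, batch)
      d <- distance_fn(as.matrix(th))
      keep <- which(d <= epsilon)
      acc <- rbind(acc, as.matrix(th)[keep, , drop = FALSE])
      dists <- c(dists, d[keep])
      trials <- trials + batch
    }
    if (nrow(acc) == 0) {
      stop_domain(sprintf(
        "ABC rejection failed: 0 acceptances in %d trials (epsilon=%g, min distance seen=%g)",
        trials, epsilon, min(d)))
    }
    keep <- seq_len(min(nrow(acc), n_accept))
    new_posterior(acc[keep, , drop = FALSE],
                  rep(1 / length(keep), length(keep)),
                  distances = dists[keep],
                  acceptance_trace = nrow(acc) / trials)
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

# weighted quantile (type-7-like on the weighted ECDF)
weighted_quantile <- function(x, w, p) {
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  cw <- cumsum(w)
  x[min(length(x), findInterval(p, cw) + 1L)]
}

# log density of a centred bivariate normal with covariance S (up to the
# constant; used only in ratios with a common kernel)
dmvnorm2 <- function(dx, U_inv_t) {
  z <- dx %*% U_inv_t
  exp(-0.5 * rowSums(z^2))
}

#' ABC-SMC posterior estimation
#'
#' Sequential importance sampling with adaptive thresholds: generation 1
#' samples the prior against an epsilon set to the configured quantile of
#' a 1000-draw pilot; later generations resample the previous population
#' by weight, perturb in log10-parameter space with a multivariate-normal
#' kernel (covariance = `kernel_scale` times the weighted empirical
#' covariance), reject proposals outside the prior box, and accept when
#' the (possibly surrogate-sampled) distance falls below the quantile of
#' the previous generation's accepted distances. Importance weights follow
#' the standard SMC correction; with a log-uniform prior the prior density
#' is constant in log space and cancels up to normalisation.
#'
#' @param prior a `grn_prior`.
#' @param distance_fn vectorised distance function as in [abc_rejection()].
#' @param config an `smc_config`.
#' @return An `abc_posterior` (weights sum to 1, non-increasing epsilon
#'   trace, per-generation acceptance rates).
#' @export
abc_smc <- function(prior, distance_fn, config) {
  stopifnot(inherits(config, "smc_config"))
  run <- function() {
    N <- config$population
    # pilot for the initial threshold
    pilot <- prior_sample(prior, config$pilot_draws)
    pilot_d <- distance_fn(as.matrix(pilot))
    eps <- as.numeric(quantile(pilot_d, config$quantile, na.rm = TRUE))
    eps_trace <- numeric(0)
    acc_trace <- numeric(0)
    log_lo <- log10(c(prior$D_bounds[1], prior$chi_bounds[1]))
    log_hi <- log10(c(prior$D_bounds[2], prior$chi_bounds[2]))

    samples <- NULL; weights <- NULL; dists <- NULL
    for (gen in seq_len(config$generations)) {
      if (gen > 1) {
        eps_new <- weighted_quantile(dists, weights, config$quantile)
        eps <- min(eps, eps_new)
      }
      eps_trace <- c(eps_trace, eps)
      acc_s <- matrix(NA_real_, N, 2) # log10 coords
      acc_d <- numeric(N)
      n_acc <- 0L
      n_try <- 0L
      budget <- config$max_draws_per_gen * N
      if (gen > 1) {
        prev_log <- log10(samples)
        S <- config$kernel_scale *
          cov.wt(prev_log, wt = weights, method = "ML")$cov
        S <- S + diag(1e-10, 2)
        U <- chol(S)
        U_inv_t <- backsolve(U, diag(2)) # S^(-1/2) action for kernel ratios
      }
      while (n_acc < N && n_try < budget) {
        m <- min(4L * N, budget - n_try)
        if (gen == 1) {
          th_log <- cbind(runif(m, log_lo[1], log_hi[1]),
                          runif(m, log_lo[2], log_hi[2]))
        } else {
          idx <- sample.int(N, m, replace = TRUE, prob = weights)
          th_log <- prev_log[idx, , drop = FALSE] +
            MASS::mvrnorm(m, c(0, 0), S)
          inside <- th_log[, 1] >= log_lo[1] & th_log[, 1] <= log_hi[1] &
            th_log[, 2] >= log_lo[2] & th_log[, 2] <= log_hi[2]
          th_log <- th_log[inside, , drop = FALSE]
        }
        n_try <- n_try + m
        if (nrow(th_log) == 0) next
        d <- distance_fn(10^th_log)
        keep <- which(d <= eps)
        if (length(keep)) {
          take <- keep[seq_len(min(length(keep), N - n_acc))]
          rows <- n_acc + seq_along(take)
          acc_s[rows, ] <- th_log[take, , drop = FALSE]
          acc_d[rows] <- d[take]
          n_acc <- n_acc + length(take)
        }
      }
      if (n_acc < N) {
        stop_domain(sprintf(
          "SMC generation %d stalled: %d/%d accepted within the proposal budget (epsilon=%g; trace: %s)",
          gen, n_acc, N, eps, paste(signif(eps_trace, 3), collapse = ", ")))
      }
      acc_rate <- N / n_try
      acc_trace <- c(acc_trace, acc_rate)
      if (gen == 1) {
        new_w <- rep(1 / N, N)
      } else {
        denom <- vapply(seq_len(N), function(i) {
          dx <- sweep(prev_log, 2, acc_s[i, ])
          sum(weights * dmvnorm2(-dx, U_inv_t))
        }, numeric(1))
        new_w <- 1 / pmax(denom, 1e-300) # log-uniform prior: constant numerator
        new_w <- new_w / sum(new_w)
      }
      ess <- 1 / sum(new_w^2)
      if (ess < 5) {
        stop_domain(sprintf(
          "SMC population collapsed at generation %d (ESS=%.2f; epsilon trace: %s)",
          gen, ess, paste(signif(eps_trace, 3), collapse = ", ")))
      }
      samples <- 10^acc_s
      weights <- new_w
      dists <- acc_d
      if (!is.null(config$final_epsilon) && eps <= config$final_epsilon) break
    }
    new_posterior(samples, weights, distances = dists,
                  epsilon_trace = eps_trace, acceptance_trace = acc_trace)
  }
  if (is.null(config$seed)) run() else withr::with_seed(config$seed, run())
}

#' Run one inference task (surrogate or direct mode)
#'
#' Surrogate mode wires [sample_distance()] into [abc_smc()]; no simulator
#' call happens during SMC (the simulator-call counter is recorded in the
#' posterior's provenance so this is checkable). Direct mode simulates an
#' ensemble at every proposed parameter point with the requested model and
#' computes the metric against the observed ensemble — tractable only at
#' desk scale.
#'
#' @param observed the observed `trajectory_ensemble`.
#' @param model inference model tag (`"wmm"`, `"cbm"`, `"spatial"`).
#' @param metric a `distance_spec`.
#' @param surrogate a trained `distance_surrogate` (surrogate mode), or
#'   `NULL` with `direct = TRUE`.
#' @param config an `smc_config`.
#' @param direct use direct simulation instead of the surrogate.
#' @param sim_options list for direct mode: `n_traj`, `config`
#'   (a `sim_config`), `seed`.
#' @return An `abc_posterior` with provenance (hashes, simulator-call
#'   counts).
#' @export
run_inference <- function(observed, model, metric, surrogate = NULL,
                          config = smc_config(), direct = FALSE,
                          sim_options = list()) {
  calls_before <- sim_call_count()
  if (direct) {
    n_traj <- sim_options$n_traj %||% 4L
    sconfig <- sim_options$config %||% sim_config(t_burn = 300, n_samples = 20)
    sseed <- sim_options$seed %||% 1L
    dist_fn0 <- distance_function(metric)
    counter <- new.env(); counter$i <- 0L
    distance_fn <- function(theta) {
      apply(theta, 1, function(row) {
        counter$i <- counter$i + 1L
        params <- make_parameters(chi = row[2], D = row[1])
        sim <- simulate_ensemble(params, model, n_traj, sconfig,
                                 seed = derive_seed(sseed, "direct", counter$i))
        dist_fn0(observed, sim)
      })
    }
  } else {
    if (is.null(surrogate)) {
      stop_domain("surrogate mode requires a trained surrogate (or set direct = TRUE)")
    }
    distance_fn <- function(theta) sample_distance(surrogate, log10(theta))
  }
  post <- abc_smc(prior_spec(), distance_fn, config)
  post$provenance <- list(
    mode = if (direct) "direct" else "surrogate",
    model = toupper(model), metric = metric$name,
    observed_hash = content_hash(observed$trajectories),
    surrogate_hash = if (!direct) content_hash(surrogate$y) else NULL,
    smc_config = unclass(config),
    simulator_calls = sim_call_count() - calls_before
  )
  post
}

#' Posterior samples to CSV (columns D, chi, weight)
#'
#' @param posterior an `abc_posterior`.
#' @param path CSV path; a JSON provenance sidecar is written alongside.
#' @export
posterior_to_csv <- function(posterior, path) {
  df <- data.frame(D = posterior$samples[, "D"],
                   chi = posterior$samples[, "chi"],
                   weight = posterior$weights)
  write.csv(df, path, row.names = FALSE)
  side <- sub("\\.csv$", ".json", path)
  jsonlite::write_json(
    list(epsilon_trace = posterior$epsilon_trace,
         acceptance_trace = posterior$acceptance_trace,
         provenance = posterior$provenance),
    side, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname posterior_to_csv
#' @export
posterior_from_csv <- function(path) {
  df <- read.csv(path)
  side <- sub("\\.csv$", ".json", path)
  extra <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE) else NULL
  new_posterior(as.matrix(df[, c("D", "chi")]), df$weight,
                epsilon_trace = extra$epsilon_trace %||% numeric(0),
                acceptance_trace = extra$acceptance_trace %||% numeric(0),
                provenance = extra$provenance)
}
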