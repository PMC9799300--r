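test_that("rejection with a zero distance returns the prior", {
  post <- abc_rejection(prior_spec(), function(th) rep(0, nrow(th)),
                        epsilon = 1, n_accept = 2000, seed = 21)
  expect_equal(sum(post$weights), 1)
  expect_true(all(prior_contains(prior_spec(), post$samples[, "D"],
                                 post$samples[, "chi"])))
  expect_gt(stats::ks.test(log(post$samples[, "D"]), "punif",
                           log(0.0039), log(16))$p.value, 0.01)
  expect_gt(stats::ks.test(log(post$samples[, "chi"]), "punif",
                           log(0.25), log(16))$p.value, 0.01)
})

test_that("rejection acceptance region and rates behave as constructed", {
  theta0 <- c(0.6, 1)
  dfn <- function(th) sqrt(rowSums(sweep(log10(th), 2, log10(theta0))^2))
  post <- abc_rejection(prior_spec(), dfn, epsilon = 0.3, n_accept = 300, seed = 22)
  expect_true(all(dfn(post$samples) <= 0.3))
  # a distance that is itself U(0,1): acceptance fraction ~ the threshold
  post_u <- abc_rejection(prior_spec(), function(th) runif(nrow(th)),
                          epsilon = 0.3, n_accept = 3000, seed = 23)
  expect_lt(abs(post_u$acceptance_trace - 0.3), 0.03)
  # zero acceptances within the trial cap is an explicit failure
  expect_error(
    abc_rejection(prior_spec(), function(th) rep(1, nrow(th)),
                  epsilon = 0.5, n_accept = 10, seed = 24, max_trials = 4000),
    "0 acceptances")
})

test_that("SMC satisfies its population contracts", {
  dfn <- function(th) sqrt(rowSums(sweep(log10(th), 2, log10(c(0.6, 1)))^2))
  cfg <- smc_config(population = 150, generations = 6, seed = 25)
  post <- abc_smc(prior_spec(), dfn, cfg)
  expect_equal(sum(post$weights), 1)
  expect_true(all(post$weights >= 0))
  expect_true(all(diff(post$epsilon_trace) <= 1e-12))
  expect_true(all(prior_contains(prior_spec(), post$samples[, "D"],
                                 post$samples[, "chi"])))
  expect_length(post$epsilon_trace, 6)
  # identical config + seed: identical posterior
  post2 <- abc_smc(prior_spec(), dfn, cfg)
  expect_identical(post$samples, post2$samples)
  expect_identical(post$weights, post2$weights)
})

test_that("SMC recovers the minimiser of a deterministic convex distance", {
  theta0 <- c(D = 0.6, chi = 1)
  dfn <- function(th) sqrt(rowSums(sweep(log10(th), 2, log10(theta0))^2))
  post <- abc_smc(prior_spec(), dfn,
                  smc_config(population = 200, generations = 8, seed = 26))
  wm <- posterior_mean(post, log10_scale = TRUE)
  expect_lt(abs(wm["D"] - log10(0.6)), 0.1)
  expect_lt(abs(wm["chi"] - log10(1)), 0.1)
})

test_that("with a theta-independent distance SMC returns the prior", {
  post <- abc_smc(prior_spec(), function(th) runif(nrow(th)),
                  smc_config(population = 400, generations = 4, seed = 27))
  # importance-weighted samples are uniform in log space
  idx <- sample(nrow(post$samples), 400, replace = TRUE, prob = post$weights)
  expect_gt(stats::ks.test(unique(log(post$samples[idx, "D"])), "punif",
                           log(0.0039), log(16))$p.value, 0.01)
})

test_that("surrogate-mode inference runs without any simulator call", {
  obs <- quick_ensemble(n_traj = 4, n_samples = 10, seed = 31)
  grid <- make_grid(3, 3)
  training <- generate_grid_data(grid, "wmm", 4,
                                 sim_config(t_burn = 50, n_samples = 10,
                                            dt_sample = 2), seed = 32)
  metric <- distance_spec("kolmogorov")
  surr <- train_distance_surrogate(obs, training, metric, splits = 2,
                                   restarts = 3, seed = 33)
  before <- sim_call_count()
  post <- run_inference(obs, "wmm", metric, surrogate = surr,
                        config = smc_config(population = 100, generations = 4,
                                            seed = 34))
  expect_identical(sim_call_count(), before)
  expect_identical(post$provenance$simulator_calls, 0L)
  expect_equal(post$provenance$mode, "surrogate")
  expect_error(run_inference(obs, "wmm", metric, surrogate = NULL),
               "surrogate")
  # csv round trip of the posterior with provenance sidecar
  f <- withr::local_tempfile(fileext = ".csv")
  posterior_to_csv(post, f)
  back <- posterior_from_csv(f)
  expect_equal(back$samples, post$samples, tolerance = 1e-12)
  expect_equal(back$epsilon_trace, post$epsilon_trace, tolerance = 1e-12)
})

test_that("direct-mode inference agrees with surrogate mode at desk scale", {
  sconfig <- sim_config(t_burn = 80, n_samples = 8, dt_sample = 3)
  obs <- simulate_ensemble(make_parameters(1, 0.6), "wmm", 3, sconfig, seed = 41)
  grid <- make_grid(4, 4)
  training <- generate_grid_data(grid, "wmm", 4, sconfig, seed = 42)
  metric <- distance_spec("naive_stats")
  surr <- train_distance_surrogate(obs, training, metric, splits = 2,
                                   restarts = 3, seed = 43)
  post_s <- run_inference(obs, "wmm", metric, surrogate = surr,
                          config = smc_config(population = 60, generations = 3,
                                              seed = 44))
  post_d <- run_inference(obs, "wmm", metric,
                          config = smc_config(population = 60, generations = 3,
                                              pilot_draws = 150, seed = 44),
                          direct = TRUE,
                          sim_options = list(n_traj = 3, config = sconfig,
                                             seed = 45))
  expect_gt(post_d$provenance$simulator_calls, 0)
  ms <- posterior_mean(post_s, log10_scale = TRUE)
  md <- posterior_mean(post_d, log10_scale = TRUE)
  expect_lt(max(abs(ms - md)), 0.5)
})

test_that("self-inference error decreases with the observed ensemble size", {
  # the pipeline's core sanity direction: 64-trajectory observations are
  # easier to invert than 4-trajectory observations
  grid <- make_grid(4, 4)
  cfg <- sim_config(t_burn = 150, n_samples = 12, dt_sample = 5)
  metric <- distance_spec("kolmogorov")
  theta0 <- c(0.6, 1)
  err_for <- function(n_obs, seed) {
    obs <- simulate_ensemble(make_parameters(theta0[2], theta0[1]), "wmm",
                             n_obs, cfg, seed = seed)
    training <- generate_grid_data(grid, "wmm", 8, cfg,
                                   seed = derive_seed(seed, "train"))
    surr <- train_distance_surrogate(obs, training, metric, splits = 2,
                                     restarts = 3, seed = seed)
    post <- run_inference(obs, "wmm", metric, surrogate = surr,
                          config = smc_config(population = 120,
                                              generations = 5, seed = seed))
    expected_log_error(post, theta0)
  }
  errs <- vapply(1:3, function(s) {
    c(small = err_for(4, 600 + s), large = err_for(64, 700 + s))
  }, numeric(2))
  expect_lt(mean(errs["large", ]), mean(errs["small", ]))
})
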