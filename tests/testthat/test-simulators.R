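test_that("the effective association rate has the Collins-Kimball structure", {
  sigma <- molar_to_volumetric(1e9) / (4 * pi * 0.6) # kD = ka at D = 0.6
  # unit conversion oracle: 1e9 M^-1 min^-1 = 1.661 um^3/min per pair
  expect_equal(molar_to_volumetric(1e9), 1.661, tolerance = 1e-3)
  expect_equal(sigma, 0.2202, tolerance = 1e-3)
  # kD = ka -> harmonic combination gives ka/2
  expect_equal(effective_association_rate(1e9, 0.6, sigma), 5e8, tolerance = 1e-9)
  # reaction-limited limit: D -> infinity recovers ka
  expect_equal(effective_association_rate(1e9, 1e9, sigma), 1e9, tolerance = 1e-6)
  # bounded by both rates and monotone in D
  Ds <- c(0.01, 0.1, 1, 10)
  ks <- vapply(Ds, function(D) effective_association_rate(1e9, D, sigma), numeric(1))
  expect_true(all(diff(ks) > 0))
  kDs <- vapply(Ds, function(D) volumetric_to_molar(4 * pi * sigma * D), numeric(1))
  expect_true(all(ks <= pmin(1e9, kDs) + 1e-6))
})

test_that("compartment transfer rates match their first-passage closed forms", {
  cr <- compartment_rates(0.6, 2.5, 6.0)
  expect_equal(cr$k_exit, 1.44, tolerance = 1e-12)
  # independent recomputation of the shell-averaged entry time by
  # numerical quadrature of the stated tau(rho)
  tau <- function(rho) (1 / 0.6) * ((6^3 / 3) * (1 / 2.5 - 1 / rho) - (rho^2 - 2.5^2) / 6)
  w <- function(rho) 3 * rho^2 / (6^3 - 2.5^3)
  tau_bar <- stats::integrate(function(rho) tau(rho) * w(rho), 2.5, 6)$value
  expect_equal(cr$k_entry, 1 / tau_bar, tolerance = 1e-8)
  expect_equal(cr$k_entry, 0.060, tolerance = 1e-2)
  # both rates exactly linear in D
  cr2 <- compartment_rates(1.2, 2.5, 6.0)
  expect_equal(cr2$k_exit, 2 * cr$k_exit)
  expect_equal(cr2$k_entry, 2 * cr$k_entry)
  expect_error(compartment_rates(0.6, 6.0, 2.5), "smaller")
})

test_that("all three simulators replay bitwise-identically for a fixed seed", {
  p <- make_parameters(1, 0.6)
  cfg <- sim_config(t_burn = 60, n_samples = 5, dt_sample = 2, seed = 77)
  for (model in c("wmm", "cbm", "spatial")) {
    sim <- simulator_for(model)
    a <- sim(p, cfg)
    b <- sim(p, cfg)
    expect_identical(a$counts, b$counts)
    expect_equal(a$times, 60 + 0:4 * 2)
  }
})

test_that("WMM stationary means match the linear birth-death moments with feedback off", {
  p0 <- make_parameters(1, 0.6)
  p0$ka <- 0
  per_traj <- sapply(1:24, function(i) {
    tr <- simulate_wmm(p0, sim_config(t_burn = 300, n_samples = 25,
                                      dt_sample = 10, seed = 300 + i))
    colMeans(tr$counts)
  })
  for (s in 1:2) {
    est <- mean(per_traj[s, ])
    se <- stats::sd(per_traj[s, ]) / sqrt(ncol(per_traj))
    expect_lt(abs(est - c(75, 1875)[s]), 3 * se)
  }
})

test_that("CBM whole-cell means match the exact compartment-ODE solution (feedback off)", {
  # protein mean = kappa E[mRNA_cyt] / gamma is sensitive to the hop rates
  for (D in c(0.6, 3)) {
    p0 <- make_parameters(1, D)
    p0$ka <- 0
    per_traj <- sapply(1:16, function(i) {
      tr <- simulate_cbm(p0, sim_config(t_burn = 300, n_samples = 25,
                                        dt_sample = 10, seed = 400 + i))
      colMeans(tr$counts)
    })
    expect_2 <- cbm_nofeedback_means(D)
    for (s in 1:2) {
      est <- mean(per_traj[s, ])
      se <- stats::sd(per_traj[s, ]) / sqrt(ncol(per_traj))
      truth <- c(expect_2$mRNA, expect_2$P)[s]
      expect_lt(abs(est - truth), 3.5 * se)
    }
  }
})

test_that("Brownian steps have variance 2 D dt per axis and respect the cell wall", {
  set.seed(5)
  # free diffusion, no reflection: displacement variance after n steps
  n_steps <- 40
  paths <- grnabc:::cpp_brownian_paths(0.6, 0.01, n_steps, 20000, -1)
  v_expect <- 2 * 0.6 * n_steps * 0.01
  for (ax in 1:3) {
    v <- mean(paths[, ax]^2)
    se <- stats::sd(paths[, ax]^2) / sqrt(nrow(paths))
    expect_lt(abs(v - v_expect), 4 * se)
  }
  # reflecting wall: no excursion beyond R, ever
  paths_r <- grnabc:::cpp_brownian_paths(5, 0.01, 2000, 500, 6)
  expect_true(all(paths_r[, 4] <= 6))
})

test_that("spatial simulator reproduces the location-free mRNA mean", {
  # total transcription/degradation do not depend on position, so the
  # stationary mRNA mean is mu/gamma = 75 at any D when feedback is off
  p0 <- make_parameters(1, 1)
  p0$ka <- 0
  per_traj <- sapply(1:6, function(i) {
    tr <- simulate_spatial(p0, sim_config(t_burn = 150, n_samples = 10,
                                          dt_sample = 3, seed = 500 + i))
    mean(tr$counts[, "mRNA"])
  })
  se <- stats::sd(per_traj) / sqrt(length(per_traj))
  expect_lt(abs(mean(per_traj) - 75), 4 * se)
})

test_that("binding radius calibration is monotone with the Smoluchowski continuum limit", {
  k_eff <- 1.661 # um^3/min
  expect_identical(binding_radius(0, 0.6, 0.01), 0)
  s1 <- binding_radius(k_eff, 0.6, 0.01)
  s2 <- binding_radius(2 * k_eff, 0.6, 0.01)
  expect_gt(s2, s1)
  # dt -> 0 with react-on-contact approaches k_eff/(4 pi D)
  s_small <- binding_radius(k_eff, 0.6, 5e-4)
  sigma_smol <- k_eff / (4 * pi * 0.6)
  expect_lt(abs(s_small - sigma_smol) / sigma_smol, 0.12)
  expect_lt(abs(s1 - sigma_smol) / sigma_smol, 0.5)
})

test_that("simulation config enforces the fixed-step resolution contract", {
  expect_error(sim_config(dt_sample = 1, dt_bd = 0.05), "dt_sample/100")
  expect_error(sim_config(t_burn = -1), "positive")
  # copy-number cap signals runaway parameters instead of truncating
  p <- make_parameters(16, 16)
  expect_error(
    simulate_wmm(p, sim_config(t_burn = 100, n_samples = 2, dt_sample = 5,
                               seed = 1, count_cap = 40)),
    "cap")
})
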