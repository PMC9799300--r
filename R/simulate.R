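# Three simulators of the same network at increasing spatial fidelity:
#  - WMM: whole cell well-mixed, exact SSA (Gillespie direct method);
#  - CBM: nucleus + cytoplasm each well-mixed, coupled by first-passage
#    derived hop rates, exact SSA over compartment-resolved species;
#  - SPATIAL: fixed-time-step Brownian dynamics of every mRNA/protein
#    molecule in the spherical cell, gene fixed at the origin, binding
#    within a calibrated reaction radius.
# All emit whole-cell copy-number time series of (mRNA, P).

#' Simulation configuration
#'
#' @param t_burn burn-in duration in minutes, discarded so sampled
#'   trajectories are decorrelated from the (empty) initial condition.
#' @param n_samples number of recorded samples (>= 1).
#' @param dt_sample sampling interval in minutes (10 at full scale: one
#'   sample every ten minutes).
#' @param dt_bd Brownian-dynamics time step in minutes; must satisfy
#'   `dt_bd <= dt_sample / 100`.
#' @param seed optional integer seed for reproducible trajectories.
#' @param count_cap overflow guard: simulation aborts with an error if the
#'   total copy number exceeds this cap (signals runaway parameters; never
#'   silently truncates).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(t_burn = 500, n_samples = 100, dt_sample = 10,
                       dt_bd = 0.01, seed = NULL, count_cap = 1e7) {
  check_positive(t_burn, "t_burn")
  check_positive(dt_sample, "dt_sample")
  check_positive(dt_bd, "dt_bd")
  if (!is.numeric(n_samples) || n_samples < 1) stop_domain("`n_samples` must be >= 1")
  if (dt_bd > dt_sample / 100) {
    stop_domain("`dt_bd` must be <= dt_sample/100 (fixed-step resolution contract)")
  }
  structure(
    list(t_burn = t_burn, n_samples = as.integer(n_samples),
         dt_sample = dt_sample, dt_bd = dt_bd,
         seed = if (is.null(seed)) NULL else as.integer(seed),
         count_cap = count_cap),
    class = "sim_config"
  )
}

#' Convert a molar rate to a volumetric per-pair rate
#'
#' `k_vol = k / NA * 1e15` converts M^-1 min^-1 to um^3 min^-1 per molecule
#' pair (1 um^3 = 1e-15 L). 1e9 M^-1 min^-1 = 1.661 um^3 min^-1.
#'
#' @param k_molar rate in M^-1 min^-1.
#' @return Rate in um^3 min^-1.
#' @export
molar_to_volumetric <- function(k_molar) k_molar / AVOGADRO * UM3_PER_L

#' @rdname molar_to_volumetric
#' @param k_vol rate in um^3 min^-1.
#' @export
volumetric_to_molar <- function(k_vol) k_vol * AVOGADRO / UM3_PER_L

#' Default gene-protein reaction radius (um)
#'
#' The Smoluchowski radius matching the intrinsic binding rate at the base
#' diffusion constant D = 0.6 um^2/min: sigma = ka_vol / (4 pi * 0.6)
#' (about 0.22 um). Fixed property of the gene-protein pair; the
#' diffusion dependence of the association enters through
#' [effective_association_rate()].
#'
#' @param params a `grn_params`.
#' @export
reaction_radius <- function(params) {
  molar_to_volumetric(params$ka) / (4 * pi * 0.6)
}

#' Diffusion-limited effective association rate (Collins-Kimball)
#'
#' Combines the intrinsic rate `ka` with the Smoluchowski diffusion-limited
#' rate `kD = 4 pi sigma D` (expressed in M^-1 min^-1) harmonically:
#' `k_eff = ka * kD / (ka + kD)`. `k_eff <= min(ka, kD)` and is monotone
#' increasing in D; for `kD = ka` it equals `ka / 2`.
#'
#' @param ka intrinsic association rate, M^-1 min^-1.
#' @param D relative diffusion constant, um^2 min^-1.
#' @param sigma reaction radius, um.
#' @return Effective rate in M^-1 min^-1.
#' @export
effective_association_rate <- function(ka, D, sigma) {
  check_positive(ka, "ka"); check_positive(D, "D"); check_positive(sigma, "sigma")
  kD <- volumetric_to_molar(4 * pi * sigma * D)
  ka * kD / (ka + kD)
}

#' Nucleus/cytoplasm transfer rates from first-passage analysis
#'
#' Hitting-time analysis of a Brownian molecule in the two-sphere cell
#' geometry:
#' \itemize{
#'   \item exit (nucleus to cytoplasm): the mean first-passage time from a
#'     uniform start inside the nucleus to its boundary is `r^2 / (15 D)`,
#'     so `k_exit = 15 D / r^2`;
#'   \item entry (cytoplasm to nucleus): for a molecule in the shell
#'     `[r, R]` with a reflecting outer wall, the first-passage time to the
#'     inner sphere from radius `rho` is
#'     `tau(rho) = (1/D) * ((R^3/3) (1/r - 1/rho) - (rho^2 - r^2)/6)`;
#'     `k_entry` is the reciprocal of its average under the uniform shell
#'     weight `3 rho^2 / (R^3 - r^3)`.
#' }
#' Both rates are exactly linear in D.
#'
#' @param D diffusion constant, um^2 min^-1.
#' @param r nucleus radius, um.
#' @param R cell radius, um; r must be smaller than R.
#' @return List with `k_exit` and `k_entry` (min^-1).
#' @examples
#' compartment_rates(0.6, 2.5, 6.0)$k_exit  # 1.44
#' @export
compartment_rates <- function(D, r, R) {
  check_positive(D, "D"); check_positive(r, "r"); check_positive(R, "R")
  if (r >= R) stop_domain("nucleus radius `r` must be smaller than cell radius `R`")
  k_exit <- 15 * D / r^2
  # shell-averaged closed form of the mean first-passage time to the nucleus
  A <- R^3 / 3
  num <- A * ((R^3 - r^3) / r - 1.5 * (R^2 - r^2)) -
    (1 / 6) * (0.6 * (R^5 - r^5) - r^2 * (R^3 - r^3))
  tau_out <- num / (D * (R^3 - r^3))
  list(k_exit = k_exit, k_entry = 1 / tau_out)
}

new_trajectory <- function(times, counts, model, params) {
  colnames(counts) <- c("mRNA", "P")
  structure(
    list(times = times, counts = counts, model = model,
         D = params$D, chi = params$chi),
    class = "grn_trajectory"
  )
}

#' @export
print.grn_trajectory <- function(x, ...) {
  cat(sprintf("%s trajectory at (D=%g, chi=%g): %d samples, final mRNA=%d P=%d\n",
              x$model, x$D, x$chi, length(x$times),
              x$counts[nrow(x$counts), 1], x$counts[nrow(x$counts), 2]))
  invisible(x)
}

sample_times <- function(config) {
  config$t_burn + (seq_len(config$n_samples) - 1L) * config$dt_sample
}

#' Simulate the well-mixed model (exact SSA)
#'
#' Gillespie direct-method realisation of the six-channel network with the
#' whole cell as one homogeneous volume; the bimolecular gene-protein
#' propensity is `k_eff / (NA * V_cell)` per pair. Counts are recorded at
#' `t_burn + i * dt_sample`.
#'
#' @param params a `grn_params`.
#' @param config a `sim_config`.
#' @return A `grn_trajectory` (times; integer counts of mRNA and free P).
#' @export
simulate_wmm <- function(params, config) {
  stopifnot(inherits(params, "grn_params"), inherits(config, "sim_config"))
  bump_sim_calls()
  kb <- binding_propensity_constant(params, cell_volume_um3(params$R))
  run <- function() {
    cpp_ssa_wmm(kb, params$kd, params$mu, params$kappa, params$gamma,
                config$t_burn, config$n_samples, config$dt_sample,
                config$count_cap)
  }
  counts <- if (is.null(config$seed)) run() else withr::with_seed(config$seed, run())
  new_trajectory(sample_times(config), counts, "WMM", params)
}

#' Simulate the compartment-based model (exact SSA)
#'
#' SSA over `{G_free, G_bound, mRNA_nuc, mRNA_cyt, P_nuc, P_cyt}`:
#' transcription in the nucleus, translation from cytoplasmic mRNA only,
#' gene-protein binding with nuclear protein at propensity
#' `k_eff / (NA * V_nuc)` per pair, unbinding releasing nuclear protein,
#' degradation everywhere, and two-way diffusive hops for both mobile
#' species at the [compartment_rates()] rates. Reported counts are
#' whole-cell sums.
#'
#' @inheritParams simulate_wmm
#' @return A `grn_trajectory`.
#' @export
simulate_cbm <- function(params, config) {
  stopifnot(inherits(params, "grn_params"), inherits(config, "sim_config"))
  bump_sim_calls()
  kb <- binding_propensity_constant(params, cell_volume_um3(params$r))
  rates <- compartment_rates(params$D, params$r, params$R)
  run <- function() {
    cpp_ssa_cbm(kb, params$kd, params$mu, params$kappa, params$gamma,
                rates$k_exit, rates$k_entry,
                config$t_burn, config$n_samples, config$dt_sample,
                config$count_cap)
  }
  counts <- if (is.null(config$seed)) run() else withr::with_seed(config$seed, run())
  new_trajectory(sample_times(config), counts, "CBM", params)
}

#' Calibrated binding radius for the Brownian-dynamics simulator
#'
#' Returns the radius `sigma_b` such that an irreversible
#' absorb-on-end-of-step association of a uniformly distributed pair
#' reproduces the volumetric rate `k_eff` at time step `dt_bd`. Calibration
#' is a bisection against a pair-lifetime Monte-Carlo in a finite
#' reflecting sphere, with the finite-domain bias divided out using the
#' closed-form mean first-passage time of the same geometry, so the
#' remaining dependence is exactly the finite-time-step effect being
#' calibrated for. Monotone increasing in `k_eff`; in the continuum limit
#' (`dt_bd -> 0`) it approaches the Smoluchowski radius
#' `k_eff / (4 pi D_rel)`. Results are memoised and the calibration RNG is
#' isolated so simulator replay is deterministic.
#'
#' @param k_eff target volumetric association rate, um^3 min^-1.
#' @param D_rel relative diffusion constant of the pair, um^2 min^-1.
#' @param dt_bd Brownian-dynamics time step, min.
#' @param n_pairs Monte-Carlo pairs per bisection evaluation.
#' @param tol relative bisection tolerance on the radius.
#' @return Binding radius in um.
#' @export
binding_radius <- function(k_eff, D_rel, dt_bd, n_pairs = 1500, tol = 0.01) {
  if (k_eff == 0) return(0)
  check_positive(k_eff, "k_eff"); check_positive(D_rel, "D_rel")
  check_positive(dt_bd, "dt_bd")
  key <- content_hash(list(k_eff, D_rel, dt_bd, n_pairs, tol))
  cached <- the$radius_cache[[key]]
  if (!is.null(cached)) return(cached)

  sigma_smol <- k_eff / (4 * pi * D_rel)
  # in the large-step regime the radius must sweep enough volume per step
  sigma_sweep <- (3 * k_eff * dt_bd / (4 * pi))^(1 / 3)
  # measured volumetric rate at radius sigma under time step dt, corrected
  # for the finite calibration sphere
  rate_at <- function(sigma, seed) {
    L <- max(6 * sigma, 8 * sqrt(2 * D_rel * dt_bd))
    tau_mc <- withr::with_seed(seed, cpp_pair_lifetime(sigma, D_rel, dt_bd, L, n_pairs))
    V_shell <- (4 / 3) * pi * (L^3 - sigma^3)
    tau_cont <- shell_mfpt(D_rel, sigma, L)
    k_cont <- V_shell / tau_cont          # continuum rate in the finite sphere
    k_inf <- 4 * pi * sigma * D_rel       # continuum rate, infinite bath
    (V_shell / tau_mc) * (k_inf / k_cont) # remove finite-domain bias
  }
  base_seed <- derive_seed(0L, "binding_radius", key)
  lo <- 0.25 * min(sigma_smol, sigma_sweep)
  hi <- 4 * max(sigma_smol, sigma_sweep)
  f <- function(sigma, it) rate_at(sigma, derive_seed(base_seed, it)) - k_eff
  flo <- f(lo, "lo"); fhi <- f(hi, "hi")
  if (flo > 0 || fhi < 0) {
    stop_domain("binding radius calibration infeasible at this time step ",
                "(no bracketing root; decrease dt_bd)")
  }
  for (it in seq_len(25)) {
    mid <- 0.5 * (lo + hi)
    if ((hi - lo) / mid < tol) break
    if (f(mid, it) > 0) hi <- mid else lo <- mid
  }
  sigma_b <- 0.5 * (lo + hi)
  the$radius_cache[[key]] <- sigma_b
  sigma_b
}

# mean first-passage time to the inner absorbing sphere for a uniform
# start in the shell [a, L] with reflecting outer wall (same closed form
# as compartment entry, with general radii)
shell_mfpt <- function(D, a, L) {
  A <- L^3 / 3
  num <- A * ((L^3 - a^3) / a - 1.5 * (L^2 - a^2)) -
    (1 / 6) * (0.6 * (L^5 - a^5) - a^2 * (L^3 - a^3))
  num / (D * (L^3 - a^3))
}

#' Simulate the spatial particle model (fixed-step Brownian dynamics)
#'
#' Every mRNA and protein molecule takes independent Gaussian steps with
#' per-axis variance `2 D dt_bd`, reflecting at the cell wall `|x| = R`;
#' the nuclear membrane is freely permeable and the gene sits fixed at the
#' origin. Per step: degradation of each molecule with probability
#' `1 - exp(-gamma dt)`; transcription (gene free) places new mRNA at the
#' gene; translation for each cytoplasmic mRNA (`|x| > r`) places new
#' protein at the mRNA's position; a free gene absorbs the closest protein
#' whose end-of-step distance to the origin is below the calibrated
#' [binding_radius()]; unbinding (rate `kd`) releases the protein just
#' outside the binding radius. Event order within a step: diffuse,
#' degrade, transcribe, translate, bind, unbind. Reported counts are
#' whole-cell totals at the sample times.
#'
#' @inheritParams simulate_wmm
#' @return A `grn_trajectory`.
#' @export
simulate_spatial <- function(params, config) {
  stopifnot(inherits(params, "grn_params"), inherits(config, "sim_config"))
  bump_sim_calls()
  k_eff_vol <- if (params$ka <= 0) 0 else molar_to_volumetric(
    effective_association_rate(params$ka, params$D, reaction_radius(params))
  )
  sigma_b <- binding_radius(k_eff_vol, params$D, config$dt_bd)
  run <- function() {
    cpp_bd_sim(params$D, params$R, params$r, sigma_b, (1 + 1e-3) * sigma_b,
               params$kd, params$mu, params$kappa, params$gamma,
               config$dt_bd, config$t_burn, config$n_samples,
               config$dt_sample, config$count_cap)
  }
  counts <- if (is.null(config$seed)) run() else withr::with_seed(config$seed, run())
  new_trajectory(sample_times(config), counts, "SPATIAL", params)
}

#' Dispatch a simulator by model tag
#'
#' @param model one of `"wmm"`, `"cbm"`, `"spatial"` (case-insensitive).
#' @return The matching `simulate_*` function.
#' @export
simulator_for <- function(model) {
  switch(tolower(model),
    wmm = simulate_wmm,
    cbm = simulate_cbm,
    spatial = simulate_spatial,
    stop_domain("unknown model tag: ", model)
  )
}
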