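# Distance metrics between an observed and a simulated trajectory
# ensemble: L2 on expected summary statistics (naive or optimized set),
# the Kolmogorov distance on count distributions per (time, species), and
# the Kolmogorov-on-statistics variant.

#' Specify a distance metric
#'
#' @param name one of `"naive_stats"`, `"optimized_stats"`,
#'   `"kolmogorov"`, `"kolmogorov_stats"`, or `"custom_stats"` (requires
#'   `features`).
#' @param features feature names for `custom_stats`/`kolmogorov_stats`
#'   (defaults: the optimized set for `kolmogorov_stats`).
#' @param normalize logical; when `TRUE` the statistic-based L2 distances
#'   z-score each component by the per-trajectory standard deviation of
#'   that feature in the *observed* ensemble (off by default: the plain
#'   L2 norm on raw statistics).
#' @return An object of class `distance_spec`.
#' @export
distance_spec <- function(name = c("naive_stats", "optimized_stats",
                                   "kolmogorov", "kolmogorov_stats",
                                   "custom_stats"),
                          features = NULL, normalize = FALSE) {
  name <- match.arg(name)
  features <- switch(name,
    naive_stats = naive_feature_names(),
    optimized_stats = optimized_feature_names(),
    kolmogorov = NULL,
    kolmogorov_stats = features %||% optimized_feature_names(),
    custom_stats = {
      if (is.null(features)) stop_domain("`custom_stats` requires `features`")
      features
    }
  )
  structure(list(name = name, features = features, normalize = normalize),
            class = "distance_spec")
}

#' L2 distance between two summary-statistic vectors
#'
#' Euclidean norm of the difference; symmetric, non-negative, zero iff the
#' vectors are equal. The two vectors must carry identical key sets.
#'
#' @param obs,sim named numeric vectors (from [stat_vector()]).
#' @param scale optional named vector of per-key scales (z-scoring).
#' @return Non-negative real.
#' @export
l2_stats_distance <- function(obs, sim, scale = NULL) {
  if (is.null(names(obs)) || is.null(names(sim)) ||
      !setequal(names(obs), names(sim))) {
    stop_domain("feature vectors must share an identical key set")
  }
  sim <- sim[names(obs)]
  d <- obs - sim
  if (!is.null(scale)) {
    scale <- scale[names(obs)]
    scale[!is.finite(scale) | scale == 0] <- 1
    d <- d / scale
  }
  sqrt(sum(d^2))
}

# exact two-sample Kolmogorov statistic on integer-valued samples
ks_stat <- function(a, b) {
  v <- sort(unique(c(a, b)))
  Fa <- vapply(v, function(x) mean(a <= x), numeric(1))
  Fb <- vapply(v, function(x) mean(b <= x), numeric(1))
  max(abs(Fa - Fb))
}

#' Average Kolmogorov distance between two ensembles
#'
#' For every (time, species) pair, the empirical CDFs of the counts over
#' trajectories are compared by the Kolmogorov statistic
#' `sup_x |F_obs(x) - F_sim(x)|` (exact on the integer counts, equivalent
#' to a unit-bin histogram CDF); the result is the average over all
#' (time, species) pairs. Bounded in \[0, 1\].
#'
#' @param obs,sim `trajectory_ensemble`s sharing times and species.
#' @return A real in \[0, 1\].
#' @export
kolmogorov_distance <- function(obs, sim) {
  stopifnot(inherits(obs, "trajectory_ensemble"),
            inherits(sim, "trajectory_ensemble"))
  if (!isTRUE(all.equal(obs$times, sim$times)) ||
      !identical(obs$species, sim$species)) {
    stop_domain("ensembles must share sampling times and species")
  }
  n_t <- length(obs$times)
  at <- function(ens, t, s) {
    vapply(ens$trajectories, function(m) m[t, s], numeric(1))
  }
  total <- 0
  for (s in seq_along(obs$species)) {
    for (t in seq_len(n_t)) {
      total <- total + ks_stat(at(obs, t, s), at(sim, t, s))
    }
  }
  total / (n_t * length(obs$species))
}

#' Kolmogorov distance on per-trajectory summary statistics
#'
#' For every (species, feature) pair, compare the distribution over
#' trajectories of the feature value by the Kolmogorov statistic, then
#' average over all pairs. Needs at least two trajectories per side.
#'
#' @param obs,sim `trajectory_ensemble`s sharing species.
#' @param features feature names (default: the optimized set).
#' @return A real in \[0, 1\].
#' @export
kolmogorov_on_statistics <- function(obs, sim, features = optimized_feature_names()) {
  if (n_trajectories(obs) < 2L || n_trajectories(sim) < 2L) {
    stop_domain("kolmogorov_on_statistics needs >= 2 trajectories per ensemble")
  }
  if (!identical(obs$species, sim$species)) {
    stop_domain("ensembles must share species")
  }
  mo <- stat_matrix(obs, features)
  ms <- stat_matrix(sim, features)
  mean(vapply(seq_len(nrow(mo)), function(i) ks_stat(mo[i, ], ms[i, ]), numeric(1)))
}

#' Build an ensemble-to-ensemble distance function from a spec
#'
#' @param spec a `distance_spec`.
#' @return `function(obs, sim) -> distance`. For statistic-based metrics
#'   with `normalize = TRUE`, scales are the per-trajectory feature
#'   standard deviations of the observed ensemble.
#' @export
distance_function <- function(spec) {
  stopifnot(inherits(spec, "distance_spec"))
  switch(spec$name,
    kolmogorov = function(obs, sim) kolmogorov_distance(obs, sim),
    kolmogorov_stats = function(obs, sim) {
      kolmogorov_on_statistics(obs, sim, spec$features)
    },
    # naive_stats / optimized_stats / custom_stats
    function(obs, sim) {
      vo <- stat_vector(obs, spec$features)
      vs <- stat_vector(sim, spec$features)
      scale <- NULL
      if (isTRUE(spec$normalize)) {
        scale <- apply(stat_matrix(obs, spec$features), 1, sd)
      }
      l2_stats_distance(vo, vs, scale = scale)
    }
  )
}
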