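# The 18-feature-per-species candidate pool of time-series summary
# statistics used for ABC, plus the naive 4-statistic set. Conventions:
# population moments (divide by N); run ("strike") features use strict
# inequality against the mean; location features are 0-based indices
# normalised by the series length (last-location uses the one-past-the-
# index convention, so values lie in (0, 1]).

FEATURE_NAMES <- c(
  "sum", "abs_energy", "mean_abs_change", "mean_change", "median", "mean",
  "length", "standard_deviation", "skewness", "kurtosis",
  "longest_strike_below_mean", "longest_strike_above_mean",
  "last_location_of_maximum", "first_location_of_maximum",
  "last_location_of_minimum", "first_location_of_minimum",
  "maximum", "minimum"
)

#' Names of the 18 candidate time-series features
#' @return Character vector of length 18.
#' @export
feature_names <- function() FEATURE_NAMES

#' The four naive summary statistics
#' @return Character vector: mean, minimum, maximum, standard deviation.
#' @export
naive_feature_names <- function() {
  c("mean", "minimum", "maximum", "standard_deviation")
}

#' The optimized summary-statistic set
#'
#' The six features selected by approximate-sufficiency screening for this
#' system: longest strike below/above the mean, mean absolute change,
#' maximum, minimum and the spread feature (standard deviation; the
#' variance is the same pool feature on the squared scale).
#' @return Character vector of length 6.
#' @export
optimized_feature_names <- function() {
  c("longest_strike_below_mean", "longest_strike_above_mean",
    "mean_abs_change", "maximum", "minimum", "standard_deviation")
}

longest_run <- function(flag) {
  if (!any(flag)) return(0)
  r <- rle(flag)
  max(r$lengths[r$values])
}

#' Compute one time-series feature
#'
#' @param series numeric vector (a count time series); length at least 1,
#'   and at least 2 for the change-based features.
#' @param name one of [feature_names()].
#' @return A single finite numeric value. Skewness and kurtosis (excess,
#'   population moments) of a constant series are defined as 0.
#' @examples
#' compute_feature(c(1, 2, 3), "mean")       # 2
#' compute_feature(c(0, 7, 7, 0), "first_location_of_maximum")  # 0.25
#' @export
compute_feature <- function(series, name) {
  x <- as.numeric(series)
  n <- length(x)
  if (n < 1L) stop_domain("series must have length >= 1")
  if (name %in% c("mean_abs_change", "mean_change") && n < 2L) {
    stop_domain("change-based features need a series of length >= 2")
  }
  m <- mean(x)
  switch(name,
    sum = sum(x),
    abs_energy = sum(x^2),
    mean_abs_change = mean(abs(diff(x))),
    mean_change = (x[n] - x[1]) / (n - 1),
    median = median(x),
    mean = m,
    length = n,
    standard_deviation = sqrt(mean((x - m)^2)),
    skewness = {
      s2 <- mean((x - m)^2)
      if (s2 == 0) 0 else mean((x - m)^3) / s2^1.5
    },
    kurtosis = {
      s2 <- mean((x - m)^2)
      if (s2 == 0) 0 else mean((x - m)^4) / s2^2 - 3
    },
    longest_strike_below_mean = longest_run(x < m),
    longest_strike_above_mean = longest_run(x > m),
    last_location_of_maximum = (max(which(x == max(x)))) / n,
    first_location_of_maximum = (min(which(x == max(x))) - 1) / n,
    last_location_of_minimum = (max(which(x == min(x)))) / n,
    first_location_of_minimum = (min(which(x == min(x))) - 1) / n,
    maximum = max(x),
    minimum = min(x),
    stop_domain("unknown feature name: ", name)
  )
}

#' Candidate statistic pool for a set of species
#'
#' Keys are `"<species>:<feature>"`; the full two-species pool has 36
#' candidates, 18 per species.
#'
#' @param species character vector of species labels.
#' @param features feature names (default the full pool).
#' @return Character vector of pool keys.
#' @export
candidate_pool <- function(species = c("mRNA", "P"), features = feature_names()) {
  as.vector(t(outer(species, features, paste, sep = ":")))
}

#' Ensemble summary-statistic vector
#'
#' For every trajectory and species, compute each requested feature, then
#' average over trajectories. Keys are `"<species>:<feature>"`.
#'
#' @param ens a `trajectory_ensemble`.
#' @param features feature names to compute.
#' @return Named numeric vector of length `length(features) * n_species`.
#' @export
stat_vector <- function(ens, features) {
  stopifnot(inherits(ens, "trajectory_ensemble"))
  keys <- candidate_pool(ens$species, features)
  per_traj <- vapply(ens$trajectories, function(tr) {
    vapply(keys, function(k) {
      parts <- strsplit(k, ":", fixed = TRUE)[[1]]
      compute_feature(tr[, parts[1]], parts[2])
    }, numeric(1))
  }, numeric(length(keys)))
  if (is.null(dim(per_traj))) per_traj <- matrix(per_traj, nrow = length(keys))
  out <- rowMeans(per_traj)
  names(out) <- keys
  out
}

#' Per-trajectory feature values (no averaging)
#'
#' @inheritParams stat_vector
#' @return Matrix: one row per pool key, one column per trajectory.
#' @export
stat_matrix <- function(ens, features) {
  stopifnot(inherits(ens, "trajectory_ensemble"))
  keys <- candidate_pool(ens$species, features)
  out <- vapply(ens$trajectories, function(tr) {
    vapply(keys, function(k) {
      parts <- strsplit(k, ":", fixed = TRUE)[[1]]
      compute_feature(tr[, parts[1]], parts[2])
    }, numeric(1))
  }, numeric(length(keys)))
  if (is.null(dim(out))) out <- matrix(out, nrow = length(keys))
  rownames(out) <- keys
  out
}

#' The naive summary-statistic vector
#'
#' Mean, minimum, maximum and standard deviation per trajectory and
#' species, averaged over trajectories: 4 statistics x number of species
#' values (8 with both species).
#'
#' @param ens a `trajectory_ensemble`.
#' @return Named numeric vector.
#' @export
naive_stat_vector <- function(ens) stat_vector(ens, naive_feature_names())
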