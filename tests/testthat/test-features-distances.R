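test_that("feature examples evaluate to their hand-computed values", {
  expect_equal(compute_feature(c(1, 2, 3), "mean"), 2)
  expect_equal(compute_feature(c(1, 2), "abs_energy"), 5)
  # run lengths against the mean (2.5) with strict inequality
  expect_equal(compute_feature(c(1, 1, 4, 4, 4, 1), "longest_strike_above_mean"), 3)
  expect_equal(compute_feature(c(1, 1, 4, 4, 4, 1), "longest_strike_below_mean"), 2)
  # 0-based first location of the maximum, normalised by length
  expect_equal(compute_feature(c(0, 7, 7, 0), "first_location_of_maximum"), 1 / 4)
  expect_equal(compute_feature(c(0, 7, 7, 0), "last_location_of_maximum"), 3 / 4)
  expect_equal(compute_feature(c(5, 5, 5), "standard_deviation"), 0)
  expect_equal(compute_feature(c(5, 5, 5), "skewness"), 0) # degenerate: defined 0
  expect_equal(compute_feature(c(1, 5), "mean_change"), 4)
  expect_error(compute_feature(c(1), "mean_abs_change"), "length >= 2")
  expect_error(compute_feature(1:3, "no_such_feature"), "unknown")
})

test_that("the 18 features agree with an independent reference on random series", {
  set.seed(8)
  for (rep in 1:100) {
    x <- rpois(sample(5:40, 1), lambda = sample(c(2, 20, 200), 1))
    for (f in feature_names()) {
      expect_equal(compute_feature(x, f), ref_feature(x, f), tolerance = 1e-9,
                   label = paste0(f, "(", paste(x, collapse = ","), ")"))
    }
  }
})

test_that("the naive statistic vector averages 4 statistics per species over trajectories", {
  tr1 <- matrix(c(5, 5, 5, 2, 2, 2), 3, 2) # constant series per species
  tr2 <- matrix(c(3, 4, 5, 2, 4, 6), 3, 2)
  ens <- toy_ensemble(list(tr1, tr2))
  v <- naive_stat_vector(ens)
  expect_length(v, 8)
  expect_setequal(names(v), candidate_pool(c("mRNA", "P"), naive_feature_names()))
  # ensemble mean-feature is the average of per-trajectory means
  expect_equal(unname(v["mRNA:mean"]), (5 + 4) / 2)
  expect_equal(unname(v["P:mean"]), (2 + 4) / 2)
  expect_equal(unname(v["mRNA:minimum"]), (5 + 3) / 2)
  # single constant trajectory: mean = min = max, sd = 0
  e1 <- toy_ensemble(list(tr1))
  v1 <- naive_stat_vector(e1)
  expect_equal(unname(v1["mRNA:standard_deviation"]), 0)
  expect_equal(unname(v1["mRNA:maximum"]), 5)
})

test_that("the L2 statistic distance is a norm on matching key sets", {
  a <- c(`mRNA:mean` = 1, `P:mean` = 2)
  b <- c(`mRNA:mean` = 4, `P:mean` = 6) # difference (3, 4)
  expect_equal(l2_stats_distance(a, b), 5)
  expect_equal(l2_stats_distance(a, a), 0)
  expect_error(l2_stats_distance(a, c(`P:mean` = 1, `mRNA:sum` = 2)), "key set")
  set.seed(2)
  for (i in 1:20) {
    x <- stats::setNames(rnorm(4), letters[1:4])
    y <- stats::setNames(rnorm(4), letters[1:4])
    z <- stats::setNames(rnorm(4), letters[1:4])
    expect_equal(l2_stats_distance(x, y), l2_stats_distance(y, x))
    expect_equal(l2_stats_distance(x, y), sqrt(sum((x - y)^2)))
    expect_lte(l2_stats_distance(x, z),
               l2_stats_distance(x, y) + l2_stats_distance(y, z) + 1e-12)
  }
})

test_that("the Kolmogorov distance equals brute-force ECDF evaluation", {
  one_time <- function(counts) matrix(counts, 1, 1)
  obs <- toy_ensemble(list(one_time(0), one_time(1)), times = 1, species = "P")
  sim <- toy_ensemble(list(one_time(1), one_time(2)), times = 1, species = "P")
  expect_equal(kolmogorov_distance(obs, sim), 0.5)
  expect_equal(kolmogorov_distance(obs, obs), 0)
  # disjoint supports at every (time, species) -> maximal discrepancy 1
  lo <- toy_ensemble(list(one_time(0), one_time(2)), times = 1, species = "P")
  hi <- toy_ensemble(list(one_time(50), one_time(60)), times = 1, species = "P")
  expect_equal(kolmogorov_distance(lo, hi), 1)
  # random small ensembles against the brute-force oracle, both species
  set.seed(3)
  for (i in 1:10) {
    n_t <- 4
    mk <- function(lam) lapply(1:5, function(j) matrix(rpois(2 * n_t, lam), n_t, 2))
    a <- toy_ensemble(mk(8))
    b <- toy_ensemble(mk(12))
    d_pkg <- kolmogorov_distance(a, b)
    accum <- 0
    for (s in 1:2) for (t in 1:n_t) {
      accum <- accum + brute_ks(
        vapply(a$trajectories, function(m) m[t, s], numeric(1)),
        vapply(b$trajectories, function(m) m[t, s], numeric(1)))
    }
    expect_equal(d_pkg, accum / (2 * n_t), tolerance = 1e-12)
    expect_equal(d_pkg, kolmogorov_distance(b, a))
    expect_gte(d_pkg, 0)
    expect_lte(d_pkg, 1)
  }
  expect_error(kolmogorov_distance(obs, toy_ensemble(list(one_time(1)), times = 2,
                                                     species = "P")),
               "share")
})

test_that("the Kolmogorov-on-statistics variant compares per-trajectory feature ECDFs", {
  mk <- function(v) matrix(v, length(v), 1)
  # feature 'mean' per trajectory: obs {1, 2}, sim {2, 3} -> KS 0.5
  obs <- toy_ensemble(list(mk(c(1, 1)), mk(c(2, 2))), species = "P")
  sim <- toy_ensemble(list(mk(c(2, 2)), mk(c(3, 3))), species = "P")
  expect_equal(kolmogorov_on_statistics(obs, sim, features = "mean"), 0.5)
  expect_equal(kolmogorov_on_statistics(obs, obs, features = "mean"), 0)
  set.seed(9)
  a <- toy_ensemble(lapply(1:6, function(i) mk(rpois(10, 9))), species = "P")
  b <- toy_ensemble(lapply(1:6, function(i) mk(rpois(10, 11))), species = "P")
  d <- kolmogorov_on_statistics(a, b)
  expect_gte(d, 0)
  expect_lte(d, 1)
  expect_equal(d, kolmogorov_on_statistics(b, a))
  expect_error(kolmogorov_on_statistics(toy_ensemble(list(mk(1:3)), species = "P"), a),
               ">= 2 trajectories")
})

test_that("distance specs wire features and normalisation into one callable", {
  ens1 <- quick_ensemble(n_traj = 3, seed = 21)
  ens2 <- quick_ensemble(n_traj = 3, seed = 22)
  for (nm in c("naive_stats", "optimized_stats", "kolmogorov", "kolmogorov_stats")) {
    f <- distance_function(distance_spec(nm))
    expect_equal(f(ens1, ens1), 0)
    expect_gte(f(ens1, ens2), 0)
    expect_equal(f(ens1, ens2), f(ens2, ens1), tolerance = 1e-12)
  }
  dz <- distance_function(distance_spec("naive_stats", normalize = TRUE))
  expect_true(is.finite(dz(ens1, ens2)))
  expect_error(distance_spec("custom_stats"), "requires")
})

# A controllable posterior backend for selection tests. Informative
# features measure a parameter coordinate (or the full parameter point)
# up to small noise, so conditioning on them concentrates the rejection
# posterior around log10 theta = (0, 0); every other feature contributes
# pure measurement noise to the distance and leaves the posterior at the
# prior. The truth (D = 1, chi = 1) sits inside the prior box.
toy_as_backend <- function(informative, noise_sd = 0.5) {
  function(observed, features, seed) {
    withr::with_seed(seed, {
      n <- 800
      th <- prior_sample(prior_spec(), n)
      if (length(features) == 0) return(as.matrix(th))
      d2 <- rep(0, n)
      for (f in features) {
        spec <- informative[[f]]
        if (is.null(spec)) {
          if (noise_sd > 0) d2 <- d2 + rnorm(n, 0, noise_sd)^2
        } else {
          if (spec$kind %in% c("point", "D")) {
            d2 <- d2 + (log10(th$D) + rnorm(n, 0, spec$sd))^2
          }
          if (spec$kind %in% c("point", "chi")) {
            d2 <- d2 + (log10(th$chi) + rnorm(n, 0, spec$sd))^2
          }
        }
      }
      as.matrix(th)[order(d2)[1:200], ]
    })
  }
}

test_that("approximate sufficiency ranks the informative statistic first", {
  pool <- candidate_pool(c("mRNA", "P"))
  expect_length(pool, 36)
  expect_length(candidate_pool("P"), 18)
  backend <- toy_as_backend(list(`P:mean` = list(kind = "point", sd = 0.05)))
  sel <- as_select(pool, NULL, backend, n_repeats = 12, seed = 5)
  expect_true(all(sel$frequency >= 0 & sel$frequency <= 1))
  expect_equal(names(which.max(sel$frequency)), "P:mean")
  expect_gt(sel$frequency["P:mean"], 0.9)
  # reproducible for a fixed seed
  sel2 <- as_select(pool, NULL, backend, n_repeats = 12, seed = 5)
  expect_identical(sel$frequency, sel2$frequency)
  f <- withr::local_tempfile(fileext = ".csv")
  selection_to_csv(sel, f)
  expect_equal(nrow(utils::read.csv(f)), 36)
})

test_that("the optimized six-statistic subset is representable as a top-6 selection", {
  pool <- candidate_pool("P")
  targets <- candidate_pool("P", optimized_feature_names())
  # the six target features measure D or chi at three precision levels, so
  # a finer feature still shifts the posterior after a coarser one was
  # accepted; all other features are inert and never shift it
  kinds <- Map(function(k, s) list(kind = k, sd = s),
               c("D", "chi", "D", "chi", "D", "chi"),
               c(0.3, 0.3, 0.1, 0.1, 0.03, 0.03))
  informative <- stats::setNames(kinds, targets)
  sel <- as_select(pool, NULL, toy_as_backend(informative, noise_sd = 0),
                   n_repeats = 20, seed = 11, k_top = 6)
  expect_setequal(sel$chosen, targets)
  expect_true(all(sel$frequency[targets] > 0))
  expect_true(all(sel$frequency[setdiff(pool, targets)] <
                    min(sel$frequency[targets])))
})
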