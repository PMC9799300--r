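# Trajectory ensembles: replicate time series of (mRNA, P) counts at one
# parameter point for one model, plus the data-scenario operators (time
# coarsening, trajectory subsampling, species selection) and a versioned
# JSON on-disk schema.

ENSEMBLE_SCHEMA_VERSION <- 1L

#' Construct a trajectory ensemble
#'
#' @param trajectories list of integer count matrices, one per replicate,
#'   each `length(times) x length(species)`.
#' @param times sample times (min), shared by all trajectories.
#' @param species character subset of `c("mRNA", "P")`.
#' @param model model tag (`"WMM"`, `"CBM"`, `"SPATIAL"`).
#' @param D,chi the parameter point.
#' @param seeds optional per-trajectory seed manifest.
#' @return An object of class `trajectory_ensemble`.
#' @export
trajectory_ensemble <- function(trajectories, times, species, model, D, chi,
                                seeds = NULL) {
  if (length(trajectories) < 1L) stop_domain("an ensemble needs at least one trajectory")
  trajectories <- lapply(trajectories, function(tr) {
    tr <- as.matrix(tr)
    if (nrow(tr) != length(times) || ncol(tr) != length(species)) {
      stop_domain("trajectory dimensions do not match times/species")
    }
    if (any(tr < 0) || any(tr != round(tr))) {
      stop_domain("counts must be non-negative integers")
    }
    storage.mode(tr) <- "integer"
    colnames(tr) <- species
    tr
  })
  structure(
    list(model = model, D = D, chi = chi, times = as.numeric(times),
         species = as.character(species), trajectories = trajectories,
         seeds = seeds),
    class = "trajectory_ensemble"
  )
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf("%s ensemble at (D=%g, chi=%g): %d trajectories x %d samples x {%s}\n",
              x$model, x$D, x$chi, n_trajectories(x), length(x$times),
              paste(x$species, collapse = ", ")))
  invisible(x)
}

#' Number of trajectories in an ensemble
#' @param ens a `trajectory_ensemble`.
#' @export
n_trajectories <- function(ens) length(ens$trajectories)

#' Simulate a replicate ensemble at one parameter point
#'
#' Per-trajectory seeds are derived from `seed` with [derive_seed()] and
#' recorded in the ensemble's seed manifest, so regeneration from the
#' manifest is bitwise reproducible.
#'
#' @param params a `grn_params`.
#' @param model model tag (`"wmm"`, `"cbm"`, `"spatial"`).
#' @param n_traj number of replicate trajectories.
#' @param config a `sim_config` (its `seed` field is ignored here).
#' @param seed integer root seed for this ensemble.
#' @return A `trajectory_ensemble`.
#' @export
simulate_ensemble <- function(params, model, n_traj, config, seed) {
  sim <- simulator_for(model)
  seeds <- vapply(seq_len(n_traj), function(i) derive_seed(seed, "traj", i), integer(1))
  trajs <- lapply(seeds, function(s) {
    cfg <- config
    cfg$seed <- s
    sim(params, cfg)$counts
  })
  trajectory_ensemble(trajs, sample_times(config), c("mRNA", "P"),
                      toupper(model), params$D, params$chi, seeds = seeds)
}

#' Generate ground-truth ensembles over a parameter grid
#'
#' One ensemble per grid point, each with `n_traj` independent
#' trajectories; per-point seeds are derived from `seed`. Simulator
#' failures at individual points are caught and reported without aborting
#' the sweep.
#'
#' @param grid a `param_grid`.
#' @param model model tag.
#' @param n_traj trajectories per grid point.
#' @param config a `sim_config`.
#' @param seed integer root seed.
#' @return An object of class `ground_truth_grid`: the grid, one
#'   `trajectory_ensemble` per point (`NULL` where failed), the model tag
#'   and a failure log.
#' @export
generate_grid_data <- function(grid, model, n_traj, config, seed) {
  stopifnot(inherits(grid, "param_grid"))
  failures <- list()
  ensembles <- vector("list", nrow(grid$points))
  for (i in seq_len(nrow(grid$points))) {
    pt <- grid$points[i, ]
    params <- make_parameters(chi = pt$chi, D = pt$D)
    res <- tryCatch(
      simulate_ensemble(params, model, n_traj, config,
                        seed = derive_seed(seed, "point", i)),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      failures[[as.character(i)]] <- conditionMessage(res)
    } else {
      ensembles[[i]] <- res
    }
  }
  structure(
    list(grid = grid, model = toupper(model), ensembles = ensembles,
         n_traj = n_traj, config = config, seed = seed, failures = failures),
    class = "ground_truth_grid"
  )
}

#' @export
print.ground_truth_grid <- function(x, ...) {
  ok <- sum(!vapply(x$ensembles, is.null, logical(1)))
  cat(sprintf("ground_truth_grid (%s): %d/%d points, %d trajectories each\n",
              x$model, ok, nrow(x$grid$points), x$n_traj))
  invisible(x)
}

#' Reduce the time-sampling density of an ensemble
#'
#' Keeps `n` sample indices chosen as `round(seq(0, N - 1, length.out = n))`
#' (0-based), so the first and last samples are always retained; e.g.
#' reducing 100 samples to 3 keeps indices 0, 50 and 99.
#'
#' @param ens a `trajectory_ensemble`.
#' @param n target number of samples, `1 <= n <=` current samples.
#' @return A reduced `trajectory_ensemble`.
#' @export
coarsen_time <- function(ens, n) {
  stopifnot(inherits(ens, "trajectory_ensemble"))
  N <- length(ens$times)
  if (n < 1 || n > N) stop_domain("`n` must be between 1 and the current sample count")
  idx <- unique(round(seq(0, N - 1, length.out = n))) + 1L
  ens$times <- ens$times[idx]
  ens$trajectories <- lapply(ens$trajectories, function(tr) tr[idx, , drop = FALSE])
  ens
}

#' Subsample trajectories without replacement
#'
#' @param ens a `trajectory_ensemble`.
#' @param k number of trajectories to keep.
#' @param seed integer seed (draws are reproducible for a fixed seed).
#' @return A `trajectory_ensemble` with `k` trajectories.
#' @export
subsample_trajectories <- function(ens, k, seed) {
  stopifnot(inherits(ens, "trajectory_ensemble"))
  m <- n_trajectories(ens)
  if (k < 1 || k > m) stop_domain("`k` must be between 1 and the current trajectory count")
  keep <- withr::with_seed(as.integer(seed), sample.int(m, k))
  ens$trajectories <- ens$trajectories[keep]
  if (!is.null(ens$seeds)) ens$seeds <- ens$seeds[keep]
  ens
}

#' Restrict an ensemble to a species subset
#'
#' @param ens a `trajectory_ensemble`.
#' @param which one of `"both"`, `"protein_only"`, `"mrna_only"`.
#' @return A `trajectory_ensemble` with the species axis restricted.
#' @export
select_species <- function(ens, which = c("both", "protein_only", "mrna_only")) {
  stopifnot(inherits(ens, "trajectory_ensemble"))
  which <- match.arg(which)
  wanted <- switch(which, both = c("mRNA", "P"), protein_only = "P", mrna_only = "mRNA")
  if (!all(wanted %in% ens$species)) {
    stop_domain("requested species {", paste(wanted, collapse = ", "),
                "} not all present in ensemble {", paste(ens$species, collapse = ", "), "}")
  }
  keep <- match(wanted, ens$species)
  ens$species <- wanted
  ens$trajectories <- lapply(ens$trajectories, function(tr) tr[, keep, drop = FALSE])
  ens
}

#' Apply a data scenario (time coarsening, subsampling, species subset)
#'
#' @param ens a `trajectory_ensemble`.
#' @param scenario list with optional `n_time_samples`, `n_trajectories`,
#'   `species`; `NULL` entries leave that axis untouched.
#' @param seed seed for trajectory subsampling.
#' @export
apply_scenario <- function(ens, scenario, seed = 1L) {
  if (!is.null(scenario$n_time_samples) &&
      scenario$n_time_samples < length(ens$times)) {
    ens <- coarsen_time(ens, scenario$n_time_samples)
  }
  if (!is.null(scenario$n_trajectories) &&
      scenario$n_trajectories < n_trajectories(ens)) {
    ens <- subsample_trajectories(ens, scenario$n_trajectories, seed)
  }
  if (!is.null(scenario$species) && scenario$species != "both") {
    ens <- select_species(ens, scenario$species)
  }
  ens
}

#' Save / load a trajectory ensemble as JSON
#'
#' Schema (version 1):
#' `{schema_version, model, D, chi, times[], species[], seeds[],
#'   trajectories[][][]}` with counts indexed trajectory x time x species.
#' Round-trips losslessly; schema mismatches are reported with the found
#' version rather than silently mis-read.
#'
#' @param ens a `trajectory_ensemble`.
#' @param path JSON file path.
#' @export
save_ensemble <- function(ens, path) {
  stopifnot(inherits(ens, "trajectory_ensemble"))
  obj <- list(
    schema_version = ENSEMBLE_SCHEMA_VERSION,
    model = ens$model, D = ens$D, chi = ens$chi,
    times = ens$times, species = ens$species,
    seeds = ens$seeds,
    trajectories = lapply(ens$trajectories, function(tr) {
      lapply(seq_len(nrow(tr)), function(i) as.integer(tr[i, ]))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) {
                    stop_domain("cannot parse ensemble file (corrupt or truncated): ",
                                conditionMessage(e))
                  })
  ver <- obj$schema_version
  if (is.null(ver) || ver != ENSEMBLE_SCHEMA_VERSION) {
    stop_domain("ensemble schema version mismatch: found ",
                ver %||% "<missing>", ", expected ", ENSEMBLE_SCHEMA_VERSION)
  }
  species <- unlist(obj$species)
  trajs <- lapply(obj$trajectories, function(tr) {
    do.call(rbind, lapply(tr, function(row) as.integer(unlist(row))))
  })
  trajectory_ensemble(trajs, unlist(obj$times), species, obj$model,
                      obj$D, obj$chi,
                      seeds = if (is.null(obj$seeds)) NULL else unlist(obj$seeds))
}

#' Save / load a full grid dataset as a directory of JSON ensembles
#'
#' Layout: `<dir>/grid.csv` (index, D, chi), `<dir>/meta.json`, and one
#' `point_<i>.json` per non-failed grid point.
#'
#' @param gdata a `ground_truth_grid`.
#' @param dir directory path (created if needed).
#' @export
save_grid_data <- function(gdata, dir) {
  stopifnot(inherits(gdata, "ground_truth_grid"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  grid_to_csv(gdata$grid, file.path(dir, "grid.csv"))
  meta <- list(schema_version = ENSEMBLE_SCHEMA_VERSION, model = gdata$model,
               n_traj = gdata$n_traj, seed = gdata$seed,
               n_D = gdata$grid$n_D, n_chi = gdata$grid$n_chi,
               config = unclass(gdata$config), failures = gdata$failures)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (i in seq_along(gdata$ensembles)) {
    if (!is.null(gdata$ensembles[[i]])) {
      save_ensemble(gdata$ensembles[[i]], file.path(dir, sprintf("point_%04d.json", i)))
    }
  }
  invisible(dir)
}

#' @rdname save_grid_data
#' @export
load_grid_data <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  if (is.null(meta$schema_version) || meta$schema_version != ENSEMBLE_SCHEMA_VERSION) {
    stop_domain("grid dataset schema version mismatch")
  }
  grid <- make_grid(meta$n_D, meta$n_chi)
  cfg <- meta$config
  config <- sim_config(t_burn = cfg$t_burn, n_samples = cfg$n_samples,
                       dt_sample = cfg$dt_sample, dt_bd = cfg$dt_bd,
                       count_cap = cfg$count_cap)
  ensembles <- lapply(seq_len(nrow(grid$points)), function(i) {
    f <- file.path(dir, sprintf("point_%04d.json", i))
    if (file.exists(f)) load_ensemble(f) else NULL
  })
  structure(
    list(grid = grid, model = meta$model, ensembles = ensembles,
         n_traj = meta$n_traj, config = config, seed = meta$seed,
         failures = as.list(meta$failures)),
    class = "ground_truth_grid"
  )
}

#' Equality of two ensembles (times, species, counts)
#' @param a,b `trajectory_ensemble` objects.
#' @export
ensembles_equal <- function(a, b) {
  isTRUE(all.equal(a$times, b$times)) &&
    identical(a$species, b$species) &&
    length(a$trajectories) == length(b$trajectories) &&
    all(mapply(function(x, y) identical(unname(x), unname(y)),
               a$trajectories, b$trajectories))
}
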