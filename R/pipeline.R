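# Orchestration of the full workflow: generate ground-truth ensembles
# once over the grid, reuse them both as observed data and as GP training
# data, run surrogate-driven ABC-SMC for every (grid point x inference
# model) task, and reduce the posteriors to error maps. Everything is
# seeded from one root seed and cached by content hash, so interrupted
# runs resume and re-runs are bitwise identical.

#' Pipeline configuration
#'
#' @param grid_dims `c(n_D, n_chi)`.
#' @param truth_model model tag generating the synthetic observed data
#'   (the highest fidelity available for the study design).
#' @param infer_models model tags used for inference.
#' @param metric a `distance_spec`.
#' @param scenario list: `n_time_samples`, `n_trajectories`, `species`
#'   (see [apply_scenario()]); `NULL` entries keep the full data.
#' @param n_traj trajectories generated per grid point.
#' @param sim a `sim_config` for data generation.
#' @param smc an `smc_config`.
#' @param surrogate_splits number of replicate distance evaluations per
#'   grid point for GP training, obtained by splitting each training
#'   ensemble into that many disjoint halves (2 splits x 256 points =
#'   the 512-sample training design at full scale).
#' @param gp_restarts L-BFGS-B restarts for GP training.
#' @param seed root seed; every per-task seed derives from it.
#' @param out_root output directory for [run_pipeline()].
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(grid_dims = c(4, 4), truth_model = "cbm",
                            infer_models = c("wmm", "cbm"),
                            metric = distance_spec("kolmogorov"),
                            scenario = list(n_time_samples = NULL,
                                            n_trajectories = NULL,
                                            species = "both"),
                            n_traj = 8,
                            sim = sim_config(t_burn = 300, n_samples = 20),
                            smc = smc_config(),
                            surrogate_splits = 2, gp_restarts = 5,
                            seed = 1L, out_root = tempfile("grnabc_run_")) {
  stopifnot(length(grid_dims) == 2, inherits(metric, "distance_spec"),
            inherits(sim, "sim_config"), inherits(smc, "smc_config"))
  simulator_for(truth_model)                 # validates the tags
  lapply(infer_models, simulator_for)
  if (surrogate_splits < 1) stop_domain("`surrogate_splits` must be >= 1")
  if (surrogate_splits > n_traj) stop_domain("more surrogate splits than trajectories")
  structure(
    list(grid_dims = as.integer(grid_dims), truth_model = tolower(truth_model),
         infer_models = tolower(infer_models), metric = metric,
         scenario = scenario, n_traj = as.integer(n_traj), sim = sim,
         smc = smc, surrogate_splits = as.integer(surrogate_splits),
         gp_restarts = gp_restarts, seed = as.integer(seed),
         out_root = out_root),
    class = "pipeline_config"
  )
}

#' Preset configurations at three scales
#'
#' \describe{
#'   \item{smoke}{3 x 3 grid, WMM truth and inference, 4 trajectories x
#'     10 samples — finishes in a few minutes on one CPU.}
#'   \item{desk}{4 x 4 grid, CBM truth, WMM + CBM inference, 8
#'     trajectories x 20 samples — the scaled-down fidelity-comparison
#'     experiment.}
#'   \item{full}{the full-scale study design: 16 x 16 grid, spatial-model
#'     truth, all three inference models, 64 trajectories x 100 samples
#'     (one every ten minutes). Emitted for completeness; running it is a
#'     cluster-scale computation (hundreds of core-hours), not a desktop
#'     job.}
#' }
#'
#' @param scale `"smoke"`, `"desk"` or `"full"`.
#' @param seed root seed.
#' @return A validated `pipeline_config`.
#' @export
make_fixture_config <- function(scale = c("smoke", "desk", "full"), seed = 1L) {
  scale <- match.arg(scale)
  switch(scale,
    smoke = pipeline_config(
      grid_dims = c(3, 3), truth_model = "wmm", infer_models = "wmm",
      metric = distance_spec("kolmogorov"),
      n_traj = 4, sim = sim_config(t_burn = 200, n_samples = 10),
      smc = smc_config(population = 100, generations = 4),
      seed = seed
    ),
    desk = pipeline_config(
      grid_dims = c(4, 4), truth_model = "cbm",
      infer_models = c("wmm", "cbm"),
      metric = distance_spec("kolmogorov"),
      n_traj = 8, sim = sim_config(t_burn = 300, n_samples = 20),
      smc = smc_config(population = 200, generations = 8),
      seed = seed
    ),
    full = pipeline_config(
      grid_dims = c(16, 16), truth_model = "spatial",
      infer_models = c("wmm", "cbm", "spatial"),
      metric = distance_spec("kolmogorov"),
      n_traj = 64, sim = sim_config(t_burn = 500, n_samples = 100,
                                    dt_sample = 10),
      smc = smc_config(population = 200, generations = 8),
      seed = seed
    )
  )
}

#' Enumerate the inference tasks of a configuration
#'
#' One task per (observed grid point, inference model), with
#' deterministically derived per-task seeds; at the full-scale design
#' (256 points x 3 models) this is 768 inferences per setup.
#'
#' @param config a `pipeline_config`.
#' @return A data.frame: task_id, point_index, D, chi, model, seed.
#' @export
plan_setup <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  grid <- make_grid(config$grid_dims[1], config$grid_dims[2])
  tasks <- expand.grid(point_index = grid$points$index,
                       model = config$infer_models,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tasks$D <- grid$points$D[tasks$point_index]
  tasks$chi <- grid$points$chi[tasks$point_index]
  tasks$seed <- mapply(function(i, m) derive_seed(config$seed, "task", i, m),
                       tasks$point_index, tasks$model)
  tasks$task_id <- sprintf("p%03d_%s", tasks$point_index, tasks$model)
  tasks[, c("task_id", "point_index", "D", "chi", "model", "seed")]
}

# split an ensemble into k disjoint sub-ensembles (contiguous blocks)
split_ensemble <- function(ens, k) {
  m <- n_trajectories(ens)
  idx <- split(seq_len(m), cut(seq_len(m), k, labels = FALSE))
  lapply(idx, function(ii) {
    out <- ens
    out$trajectories <- ens$trajectories[ii]
    if (!is.null(out$seeds)) out$seeds <- ens$seeds[ii]
    out
  })
}

#' Train the distance surrogate for one observed data set
#'
#' Distance evaluations: for every grid point, the (scenario-reduced)
#' observed ensemble is compared to `surrogate_splits` disjoint splits of
#' the training ensemble at that point, giving replicate distance values
#' whose scatter informs the GP's white-noise level. GP inputs are
#' (log10 D, log10 chi).
#'
#' @param observed the observed `trajectory_ensemble` (already
#'   scenario-reduced).
#' @param training a `ground_truth_grid` generated with the inference
#'   model.
#' @param metric a `distance_spec`.
#' @param splits replicate splits per grid point.
#' @param restarts GP training restarts.
#' @param seed integer seed.
#' @param scenario scenario applied to each training split before the
#'   distance (the observed ensemble must already be reduced).
#' @return A `distance_surrogate`.
#' @export
train_distance_surrogate <- function(observed, training, metric,
                                     splits = 2, restarts = 5, seed = 1L,
                                     scenario = NULL) {
  dist_fn <- distance_function(metric)
  X <- NULL
  y <- NULL
  pts <- training$grid$points
  for (i in seq_len(nrow(pts))) {
    ens <- training$ensembles[[i]]
    if (is.null(ens)) next
    halves <- if (splits > 1) split_ensemble(ens, splits) else list(ens)
    for (h in halves) {
      hs <- if (is.null(scenario)) h else {
        sc <- scenario
        sc$n_trajectories <- NULL # splits already thin the trajectory axis
        apply_scenario(h, sc)
      }
      X <- rbind(X, c(log10(pts$D[i]), log10(pts$chi[i])))
      y <- c(y, dist_fn(observed, hs))
    }
  }
  train_surrogate(X, y, restarts = restarts, seed = seed)
}

#' Execute the full pipeline
#'
#' Generates the ground-truth grid data once with the truth model, reuses
#' it as observed data and (for matching models) as surrogate training
#' data, generates training data for the remaining inference models,
#' trains one GP surrogate per task, runs surrogate-driven ABC-SMC and
#' writes datasets, surrogates, posteriors, error maps and a run manifest
#' under `config$out_root`. Completed tasks (existing posterior files
#' keyed by task id and config hash) are skipped, so interrupted runs
#' resume to identical outputs. SMC itself performs zero simulator calls;
#' the manifest records the simulator-call counter before and after the
#' inference phase.
#'
#' @param config a `pipeline_config`.
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the error maps (one per inference
#'   model), the task table, per-task errors and the manifest path.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- if (quiet) function(...) invisible() else function(...) message(...)
  chash <- content_hash(unclass(config)[setdiff(names(unclass(config)), "out_root")])
  out <- config$out_root
  for (d in c("datasets", "surrogates", "posteriors", "maps")) {
    dir.create(file.path(out, d), recursive = TRUE, showWarnings = FALSE)
  }
  grid <- make_grid(config$grid_dims[1], config$grid_dims[2])
  log_path <- file.path(out, "run_log.jsonl")
  log_task <- function(rec) {
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), "\n",
        file = log_path, append = TRUE)
  }

  # --- data generation (cached on disk, keyed by config hash) ------------
  get_grid_data <- function(model) {
    dir <- file.path(out, "datasets", paste0(model, "_", substr(chash, 1, 12)))
    if (file.exists(file.path(dir, "meta.json"))) {
      say("reusing dataset: ", dir)
      return(load_grid_data(dir))
    }
    say("generating ", toupper(model), " grid data (",
        nrow(grid$points), " points x ", config$n_traj, " trajectories)")
    t0 <- Sys.time()
    gd <- generate_grid_data(grid, model, config$n_traj, config$sim,
                             seed = derive_seed(config$seed, "data", model))
    save_grid_data(gd, dir)
    log_task(list(step = "generate", model = model,
                  secs = as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    gd
  }
  truth_data <- get_grid_data(config$truth_model)
  training_data <- list()
  for (m in unique(config$infer_models)) {
    training_data[[m]] <- if (m == config$truth_model) truth_data else get_grid_data(m)
  }
  sim_calls_before_inference <- sim_call_count()

  # --- inference tasks ---------------------------------------------------
  tasks <- plan_setup(config)
  errors <- rep(NA_real_, nrow(tasks))
  posteriors <- rep(list(NULL), nrow(tasks))
  for (t_i in seq_len(nrow(tasks))) {
    tk <- tasks[t_i, ]
    pfile <- file.path(out, "posteriors",
                       paste0(tk$task_id, "_", substr(chash, 1, 12), ".csv"))
    if (file.exists(pfile)) {
      post <- posterior_from_csv(pfile)
    } else {
      obs <- truth_data$ensembles[[tk$point_index]]
      if (is.null(obs)) {
        log_task(list(step = "infer", task = tk$task_id, status = "no-data"))
        next
      }
      obs <- apply_scenario(obs, config$scenario,
                            seed = derive_seed(tk$seed, "scenario"))
      t0 <- Sys.time()
      surr <- train_distance_surrogate(
        obs, training_data[[tk$model]], config$metric,
        splits = config$surrogate_splits, restarts = config$gp_restarts,
        seed = derive_seed(tk$seed, "gp"), scenario = config$scenario)
      save_surrogate(surr, file.path(out, "surrogates",
                                     paste0(tk$task_id, "_", substr(chash, 1, 12), ".json")))
      smc <- config$smc
      smc$seed <- derive_seed(tk$seed, "smc")
      post <- tryCatch(
        run_inference(obs, tk$model, config$metric, surrogate = surr,
                      config = smc),
        error = function(e) e
      )
      if (inherits(post, "error")) {
        log_task(list(step = "infer", task = tk$task_id, status = "failed",
                      message = conditionMessage(post)))
        next
      }
      posterior_to_csv(post, pfile)
      log_task(list(
        step = "infer", task = tk$task_id, status = "ok",
        secs = as.numeric(difftime(Sys.time(), t0, units = "secs")),
        final_epsilon = post$epsilon_trace[length(post$epsilon_trace)],
        acceptance = post$acceptance_trace[length(post$acceptance_trace)]))
    }
    posteriors[[t_i]] <- post
    errors[t_i] <- expected_log_error(post, c(tk$D, tk$chi))
    say(sprintf("[%d/%d] %s: expected log-error %.3f",
                t_i, nrow(tasks), tk$task_id, errors[t_i]))
  }
  sim_calls_after_inference <- sim_call_count()

  # --- error maps --------------------------------------------------------
  maps <- list()
  for (m in unique(config$infer_models)) {
    rows <- which(tasks$model == m)
    per_point <- rep(list(NULL), nrow(grid$points))
    for (r in rows) per_point[[tasks$point_index[r]]] <- posteriors[[r]]
    map <- build_error_map(per_point, grid,
                           metadata = list(model = toupper(m),
                                           metric = config$metric$name,
                                           truth_model = toupper(config$truth_model)))
    error_map_to_csv(map, file.path(out, "maps", paste0("errors_", m, ".csv")))
    maps[[m]] <- map
  }

  manifest <- list(
    config_hash = chash, seed = config$seed,
    truth_model = config$truth_model, infer_models = config$infer_models,
    metric = config$metric$name, scenario = config$scenario,
    n_tasks = nrow(tasks), n_failed = sum(is.na(errors)),
    sim_calls_before_inference = sim_calls_before_inference,
    sim_calls_after_inference = sim_calls_after_inference,
    files = list(datasets = list.files(file.path(out, "datasets")),
                 maps = list.files(file.path(out, "maps")))
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(maps = maps, tasks = tasks, errors = errors,
                 posteriors = posteriors,
                 manifest_path = file.path(out, "manifest.json"),
                 out = out))
}
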