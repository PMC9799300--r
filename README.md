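# grnabc

Systematic evaluation of likelihood-free parameter inference for a
negative-feedback gene regulatory network, across three simulator
fidelities, with Gaussian-process surrogates of the ABC distance metric.

## The problem

A single gene at the centre of a spherical nucleus (radius r = 2.5 um)
inside a spherical cell (radius R = 6 um) represses its own expression:
mRNA is transcribed in the nucleus (rate mu), diffuses to the cytoplasm,
is translated into protein (rate kappa), and the protein diffuses back
and binds the gene (rate ka, diffusion-limited); both species degrade
(rate gamma). Two parameters are inference targets: the diffusion
constant `D` (log-uniform prior on [0.0039, 16] um^2/min) and a
reactivity multiplier `chi` (log-uniform on [0.25, 16]) that scales mu,
kappa and gamma simultaneously.

Given simulated "observed" data with known truth, the package measures
how accurately ABC-SMC recovers (D, chi) depending on

* the **simulator fidelity** used for inference — well-mixed SSA (WMM),
  a two-compartment multiscale SSA with first-passage nucleus/cytoplasm
  transfer rates (CBM), or a Brownian-dynamics particle model (SPATIAL);
* the **distance metric** — L2 on naive or optimized summary
  statistics, or the average Kolmogorov distance between count
  distributions;
* the **amount of data** — trajectories per ensemble, time samples,
  observed species.

Accuracy is reported as the expected log-error

    epsilon = E_thetahat || log10(thetahat) - log10(theta_true) ||_2

— the posterior-weighted mean order-of-magnitude error, which penalizes
both bias and posterior width — mapped over a log-spaced grid of true
parameters and summarised by extended (boxen) quantile plots.

The computational trick making grid-wide sweeps tractable on a desktop:
trajectory ensembles are generated **once** per grid point and reused
both as observed data and as training data for a Gaussian-process
surrogate of the distance metric over (log10 D, log10 chi) — rational
quadratic + white kernel, L-BFGS-B maximum marginal likelihood — so
ABC-SMC then runs against sampled surrogate distances with **zero**
additional simulator calls (a package-level call counter proves it).

## Worked example

A smoke-scale end-to-end run (3x3 known-truth grid, WMM data, 4
trajectories x 10 samples, Kolmogorov distance, surrogate-driven
ABC-SMC):

```r
library(grnabc)
cfg <- make_fixture_config("smoke", seed = 3)
cfg$out_root <- tempfile("run_")
res <- run_pipeline(cfg, quiet = TRUE)
print(res$maps$wmm)
#> error_map (WMM/kolmogorov/WMM): 9/9 points, median error 0.606
round(res$errors, 2)
#> [1] 0.53 0.50 1.03 0.47 0.61 0.62 0.55 0.61 0.63
```

Each number is the expected log-error at one grid point under
self-inference: ~0.5–0.6 means the posterior mass sits about half an
order of magnitude from the truth — the resolution attainable from 4
short trajectories. The desk-scale preset (`make_fixture_config("desk")`)
runs the fidelity comparison proper: CBM-generated ground truth inferred
with both the CBM and the (mis-specified) WMM:

```r
cfg <- make_fixture_config("desk", seed = 1)
cfg$out_root <- tempfile("run_")
res <- run_pipeline(cfg, quiet = TRUE)
round(tapply(res$errors, res$tasks$model, median), 3)
#>   cbm   wmm
#> 0.326 0.737
```

The well-specified higher-fidelity model halves the median inference
error — the package's scaled-down version of the fidelity-ordering
result. `plot(res$maps$cbm)` renders the error heatmap over (chi, D);
`plot_boxen(split(res$errors, res$tasks$model))` compares the two error
distributions.

Individual components are exposed directly: `simulate_wmm()`,
`simulate_cbm()`, `simulate_spatial()`, `compartment_rates()`,
`binding_radius()`, `coarsen_time()` / `subsample_trajectories()` /
`select_species()`, `naive_stat_vector()`, `kolmogorov_distance()`,
`as_select()` (approximate-sufficiency statistic selection),
`train_surrogate()` / `sample_distance()`, `abc_smc()`,
`expected_log_error()`, `boxen_summary()`. A thin command-line front end
lives at `inst/cli/grnabc.R` (subcommands `simulate`, `generate-data`,
`run`, `evaluate`). The methods vignette
(`vignettes/fidelity-inference-pipeline.Rmd`) documents the models,
defaults and numerical choices.

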