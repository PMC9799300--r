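# Biophysical parameters of the negative-feedback gene regulation motif:
# a single gene at the centre of a spherical nucleus (radius r) inside a
# spherical cell (radius R) transcribes mRNA; mRNA diffuses to the
# cytoplasm and is translated to protein; protein diffuses back and
# represses the gene. The two inference targets are the diffusion constant
# D and the reactivity multiplier chi, which scales transcription,
# translation and degradation simultaneously.

BASE_MU <- 3.0      # transcription rate, min^-1
BASE_KAPPA <- 1.0   # translation rate, min^-1
BASE_GAMMA <- 0.04  # degradation rate, min^-1

#' Build the biophysical parameter vector for the feedback motif
#'
#' Base values: cell radius R = 6 um, nucleus radius r = 2.5 um, binding
#' rate ka = 1e9 M^-1 min^-1, unbinding rate kd = 0.1 min^-1, transcription
#' mu = 3 min^-1, translation kappa = 1 min^-1, degradation
#' gamma = 0.04 min^-1 (at chi = 1). `chi` multiplies mu, kappa and gamma
#' simultaneously; `D` (um^2 min^-1) is the common diffusion constant of
#' mRNA and protein.
#'
#' @param chi dimensionless reactivity multiplier (> 0).
#' @param D diffusion constant in um^2 min^-1 (> 0).
#' @return An object of class `grn_params`.
#' @examples
#' p <- make_parameters(chi = 2, D = 0.6)
#' p$mu     # 6
#' p$kd     # 0.1, not scaled by chi
#' @export
make_parameters <- function(chi, D) {
  check_positive(chi, "chi")
  check_positive(D, "D")
  structure(
    list(
      R = 6.0, r = 2.5, D = D,
      ka = 1e9, kd = 0.1,
      mu = BASE_MU * chi, kappa = BASE_KAPPA * chi, gamma = BASE_GAMMA * chi,
      chi = chi
    ),
    class = "grn_params"
  )
}

#' Recover the inference coordinates (D, chi) from a parameter set
#'
#' Exact inverse of [make_parameters()]: chi is stored alongside the scaled
#' rates, so no round-trip drift occurs.
#'
#' @param params a `grn_params` object.
#' @return Named numeric vector `c(D, chi)`.
#' @export
params_theta <- function(params) {
  stopifnot(inherits(params, "grn_params"))
  c(D = params$D, chi = params$chi)
}

#' @export
print.grn_params <- function(x, ...) {
  cat("Negative-feedback GRN parameters (chi =", x$chi, ", D =", x$D, "um^2/min)\n")
  cat(sprintf("  R=%g um, r=%g um, ka=%g /M/min, kd=%g /min\n", x$R, x$r, x$ka, x$kd))
  cat(sprintf("  mu=%g /min, kappa=%g /min, gamma=%g /min\n", x$mu, x$kappa, x$gamma))
  invisible(x)
}

#' Serialise / deserialise a parameter set as JSON
#'
#' Keys carry explicit unit annotations.
#'
#' @param params a `grn_params` object.
#' @param path file path.
#' @export
params_to_json <- function(params, path) {
  stopifnot(inherits(params, "grn_params"))
  obj <- list(
    schema_version = 1L,
    R_um = params$R, r_um = params$r, D_um2_per_min = params$D,
    ka_per_M_per_min = params$ka, kd_per_min = params$kd,
    mu_per_min = params$mu, kappa_per_min = params$kappa,
    gamma_per_min = params$gamma, chi = params$chi
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname params_to_json
#' @export
params_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema_version) || obj$schema_version != 1L) {
    stop_domain("unsupported parameter schema version: ", obj$schema_version %||% "<missing>")
  }
  p <- make_parameters(chi = obj$chi, D = obj$D_um2_per_min)
  p
}

#' Log-uniform prior over (D, chi)
#'
#' Independent log-uniform distributions: chi on \[0.25, 16\] and D on
#' \[0.0039, 16\] um^2 min^-1. The density of each log-transformed
#' coordinate is constant inside the bounds and zero outside.
#'
#' @param chi_bounds,D_bounds length-2 numeric vectors (lower, upper).
#' @return An object of class `grn_prior`.
#' @export
prior_spec <- function(chi_bounds = c(0.25, 16), D_bounds = c(0.0039, 16)) {
  stopifnot(length(chi_bounds) == 2L, length(D_bounds) == 2L,
            all(chi_bounds > 0), all(D_bounds > 0),
            chi_bounds[1] < chi_bounds[2], D_bounds[1] < D_bounds[2])
  structure(list(chi_bounds = chi_bounds, D_bounds = D_bounds),
            class = "grn_prior")
}

#' Draw from the log-uniform prior
#'
#' @param prior a `grn_prior`.
#' @param n number of draws (>= 1).
#' @param seed optional integer; fixing it makes the draw reproducible.
#' @return A data.frame with columns `D` and `chi` (linear scale).
#' @export
prior_sample <- function(prior, n, seed = NULL) {
  stopifnot(inherits(prior, "grn_prior"))
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop_domain("`n` must be >= 1")
  n <- as.integer(n)
  draw <- function() {
    data.frame(
      D = exp(runif(n, log(prior$D_bounds[1]), log(prior$D_bounds[2]))),
      chi = exp(runif(n, log(prior$chi_bounds[1]), log(prior$chi_bounds[2])))
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
}

#' Is a parameter point inside the prior support?
#'
#' @param prior a `grn_prior`.
#' @param D,chi numeric vectors (recycled together).
#' @return Logical vector.
#' @export
prior_contains <- function(prior, D, chi) {
  D >= prior$D_bounds[1] & D <= prior$D_bounds[2] &
    chi >= prior$chi_bounds[1] & chi <= prior$chi_bounds[2]
}

#' Geometric ground-truth grid over (D, chi)
#'
#' Log-spaced grid inclusive of both prior bounds on each axis; the ratio
#' between consecutive values on each axis is constant. Points are ordered
#' with D varying fastest.
#'
#' @param n_D,n_chi number of grid levels per axis (>= 2).
#' @param prior a `grn_prior` supplying the bounds.
#' @return An object of class `param_grid` with fields `n_D`, `n_chi`,
#'   `D_values`, `chi_values` and `points` (data.frame: index, D, chi).
#' @examples
#' g <- make_grid(16, 16)
#' nrow(g$points)  # 256
#' @export
make_grid <- function(n_D, n_chi, prior = prior_spec()) {
  if (!is.numeric(n_D) || n_D < 2 || !is.numeric(n_chi) || n_chi < 2) {
    stop_domain("grid axis counts must be >= 2")
  }
  n_D <- as.integer(n_D); n_chi <- as.integer(n_chi)
  D_values <- exp(seq(log(prior$D_bounds[1]), log(prior$D_bounds[2]), length.out = n_D))
  chi_values <- exp(seq(log(prior$chi_bounds[1]), log(prior$chi_bounds[2]), length.out = n_chi))
  # endpoints exactly equal to the bounds (guard against seq() rounding)
  D_values[1] <- prior$D_bounds[1]; D_values[n_D] <- prior$D_bounds[2]
  chi_values[1] <- prior$chi_bounds[1]; chi_values[n_chi] <- prior$chi_bounds[2]
  pts <- expand.grid(D = D_values, chi = chi_values, KEEP.OUT.ATTRS = FALSE)
  pts <- data.frame(index = seq_len(nrow(pts)), D = pts$D, chi = pts$chi)
  structure(
    list(n_D = n_D, n_chi = n_chi, D_values = D_values,
         chi_values = chi_values, points = pts, prior = prior),
    class = "param_grid"
  )
}

#' @export
print.param_grid <- function(x, ...) {
  cat(sprintf("param_grid: %d x %d = %d points, D in [%g, %g], chi in [%g, %g]\n",
              x$n_D, x$n_chi, nrow(x$points),
              min(x$D_values), max(x$D_values),
              min(x$chi_values), max(x$chi_values)))
  invisible(x)
}

#' Write / read a grid manifest as CSV (columns: index, D, chi)
#'
#' @param grid a `param_grid`.
#' @param path CSV file path.
#' @export
grid_to_csv <- function(grid, path) {
  stopifnot(inherits(grid, "param_grid"))
  write.csv(grid$points, path, row.names = FALSE)
  invisible(path)
}

#' @rdname grid_to_csv
#' @export
grid_from_csv <- function(path) {
  pts <- read.csv(path)
  stopifnot(all(c("index", "D", "chi") %in% names(pts)))
  pts
}
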