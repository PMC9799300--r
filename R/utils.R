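# Package-level mutable state: simulator call counter and binding-radius cache.
the <- new.env(parent = emptyenv())
the$sim_calls <- 0L
the$radius_cache <- new.env(parent = emptyenv())

#' Number of stochastic simulator calls made so far
#'
#' Every call to [simulate_wmm()], [simulate_cbm()] or [simulate_spatial()]
#' increments a package-level counter. The counter exists so that
#' surrogate-mode inference can *prove* it performed no simulation: the
#' whole point of the Gaussian-process distance surrogate is that ABC-SMC
#' runs against emulated distances only.
#'
#' @return Integer count of simulator invocations since the last reset.
#' @seealso [reset_sim_call_count()]
#' @export
sim_call_count <- function() the$sim_calls

#' @rdname sim_call_count
#' @export
reset_sim_call_count <- function() {
  the$sim_calls <- 0L
  invisible(NULL)
}

bump_sim_calls <- function() {
  the$sim_calls <- the$sim_calls + 1L
  invisible(NULL)
}

#' Derive a child seed from a root seed and a path of labels
#'
#' A splittable seeding scheme: every randomised step of the pipeline takes
#' its seed from the root seed plus a descriptive path, so one root seed
#' deterministically fixes every per-trajectory, per-grid-point and per-task
#' stream, independent of execution order. Seeds stay below 2^28 (well
#' inside R's 32-bit integer range).
#'
#' @param root integer root seed.
#' @param ... labels (strings/numbers) identifying the consumer.
#' @return A single integer seed.
#' @export
derive_seed <- function(root, ...) {
  h <- rlang::hash(list(as.integer(root), ...))
  strtoi(substr(h, 1, 7), base = 16L)
}

#' Content hash of an R object
#'
#' Used to key caches and on-disk artifacts by configuration content rather
#' than by timestamps.
#'
#' @param x any R object.
#' @return A character hash.
#' @export
content_hash <- function(x) rlang::hash(x)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_domain <- function(...) stop(..., call. = FALSE)

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop_domain(sprintf("`%s` must be a single finite positive number", name))
  }
  invisible(x)
}
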