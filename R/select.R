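# Summary-statistic selection by approximate sufficiency (AS): a set of
# statistics is approximately sufficient when adding one more statistic no
# longer changes the approximated posterior. The screening order is
# random, so selection is repeated and per-feature selection frequencies
# reported; the most frequently selected statistics form the chosen set.

#' Select summary statistics by approximate sufficiency
#'
#' Per repeat, the candidate pool is shuffled and candidates are screened
#' one at a time: the posterior estimated with the running set `S` is
#' compared to the posterior with `S + {candidate}` via binned marginal
#' posterior histograms in log10-parameter space, and the candidate is
#' accepted when any bin's posterior-probability departure is significant —
#' the largest binwise two-proportion z-statistic exceeds `threshold`.
#' (A z-statistic rather than a raw density ratio keeps sparsely populated
#' bins from triggering acceptance by shot noise alone.) Accepted sets are
#' recorded across repeats and per-feature
#' selection frequencies reported; the `k_top` most frequent features form
#' the chosen subset (ties broken alphabetically for determinism).
#'
#' @param pool character vector of candidate keys (see [candidate_pool()];
#'   36 keys for two species, 18 for one).
#' @param observed the observed `trajectory_ensemble` (handed unchanged to
#'   the backend; may be `NULL` for backends that close over their data).
#' @param distance_backend `function(observed, features, seed)` returning
#'   an m x 2 matrix of posterior samples (columns D, chi, linear scale)
#'   for the given feature subset — typically cheap surrogate-driven ABC.
#'   An empty subset must return (approximately) the prior. Backend
#'   failures are caught per repeat and selection continues.
#' @param n_repeats number of shuffled screening repeats.
#' @param seed integer root seed.
#' @param prior a `grn_prior` fixing the histogram range.
#' @param n_bins marginal histogram bins (log10 space).
#' @param threshold acceptance threshold on the sup binwise two-proportion
#'   z-statistic (default 4).
#' @param k_top size of the chosen subset.
#' @return An object of class `stat_selection`: `frequency` (named, in
#'   \[0,1\]), `chosen`, `n_repeats`, `sets` (accepted set per repeat).
#' @export
as_select <- function(pool, observed, distance_backend, n_repeats = 20, seed = 1L,
                      prior = prior_spec(), n_bins = 20,
                      threshold = 4, k_top = 6) {
  if (length(pool) < 1L) stop_domain("candidate pool must be non-empty")
  breaks_D <- seq(log10(prior$D_bounds[1]), log10(prior$D_bounds[2]),
                  length.out = n_bins + 1)
  breaks_chi <- seq(log10(prior$chi_bounds[1]), log10(prior$chi_bounds[2]),
                    length.out = n_bins + 1)

  marginal_counts <- function(samples) {
    clamp <- function(x, b) pmin(pmax(x, b[1] + 1e-12), b[length(b)] - 1e-12)
    hD <- hist(clamp(log10(samples[, 1]), breaks_D), breaks = breaks_D, plot = FALSE)
    hC <- hist(clamp(log10(samples[, 2]), breaks_chi), breaks = breaks_chi, plot = FALSE)
    list(D = hD$counts, chi = hC$counts, m = nrow(samples))
  }
  z_bins <- function(c1, m1, c2, m2) {
    p1 <- c1 / m1
    p2 <- c2 / m2
    pooled <- (c1 + c2) / (m1 + m2)
    se <- sqrt(pmax(pooled * (1 - pooled), 1e-12) * (1 / m1 + 1 / m2))
    abs(p1 - p2) / se
  }
  shift_score <- function(pa, pb) {
    max(z_bins(pa$D, pa$m, pb$D, pb$m), z_bins(pa$chi, pa$m, pb$chi, pb$m))
  }

  sets <- vector("list", n_repeats)
  for (rep_i in seq_len(n_repeats)) {
    rep_seed <- derive_seed(seed, "as_repeat", rep_i)
    res <- tryCatch({
      ord <- withr::with_seed(rep_seed, sample(pool))
      S <- character(0)
      post_S <- distance_backend(observed, S, derive_seed(rep_seed, "base"))
      p_S <- marginal_counts(post_S)
      for (j in seq_along(ord)) {
        cand <- ord[j]
        post_c <- distance_backend(observed, c(S, cand), derive_seed(rep_seed, "cand", j))
        p_c <- marginal_counts(post_c)
        if (shift_score(p_c, p_S) > threshold) {
          S <- c(S, cand)
          p_S <- p_c
        }
      }
      S
    }, error = function(e) {
      warning("AS repeat ", rep_i, " failed: ", conditionMessage(e), call. = FALSE)
      NULL
    })
    sets[[rep_i]] <- res
  }
  ok <- !vapply(sets, is.null, logical(1))
  n_ok <- sum(ok)
  if (n_ok == 0L) stop_domain("all AS repeats failed")
  freq <- vapply(pool, function(f) {
    mean(vapply(sets[ok], function(s) f %in% s, logical(1)))
  }, numeric(1))
  ord <- order(-freq, names(freq))
  chosen <- names(freq)[ord][seq_len(min(k_top, length(pool)))]
  structure(
    list(frequency = freq, chosen = chosen, n_repeats = n_ok,
         sets = sets[ok], threshold = threshold, k_top = k_top),
    class = "stat_selection"
  )
}

#' @export
print.stat_selection <- function(x, ...) {
  cat("Approximate-sufficiency statistic selection (", x$n_repeats, "repeats )\n")
  top <- sort(x$frequency, decreasing = TRUE)
  print(head(top, 10))
  cat("chosen:", paste(x$chosen, collapse = ", "), "\n")
  invisible(x)
}

#' Write a selection frequency table to CSV
#'
#' @param sel a `stat_selection`.
#' @param path CSV path (columns: feature, frequency, chosen).
#' @export
selection_to_csv <- function(sel, path) {
  df <- data.frame(feature = names(sel$frequency),
                   frequency = unname(sel$frequency),
                   chosen = names(sel$frequency) %in% sel$chosen)
  df <- df[order(-df$frequency, df$feature), ]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
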