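# Accuracy of a posterior against known truth. The headline metric is the
# expected log-error
#   epsilon = E_theta_hat [ || log10 theta_hat - log10 theta_true ||_2 ],
# the posterior-weighted mean Euclidean norm of the log10 parameter
# difference: it measures agreement in orders of magnitude and penalizes
# both bias and posterior width. An RMSE variant in linear parameter
# units is provided for sensitivity checks.

#' Expected log-error of a posterior
#'
#' @param posterior an `abc_posterior`.
#' @param theta_true length-2 numeric `(D, chi)` (linear scale).
#' @return Non-negative real; 0 iff the posterior is a point mass at the
#'   truth. A posterior entirely at 10x the truth in both coordinates
#'   scores `sqrt(2)`.
#' @export
expected_log_error <- function(posterior, theta_true) {
  stopifnot(inherits(posterior, "abc_posterior"))
  w <- posterior$weights
  if (any(!is.finite(w)) || sum(w) <= 0) stop_domain("invalid posterior weights")
  dl <- sweep(log10(posterior$samples), 2, log10(as.numeric(theta_true)))
  sum(w * sqrt(rowSums(dl^2)))
}

#' Root-mean-square error of a posterior (linear parameter units)
#'
#' `sqrt(E[ || theta_hat - theta_true ||^2 ])` under the posterior weights.
#' With `log10_scale = TRUE` the same quantity is computed on log10
#' coordinates instead.
#'
#' @inheritParams expected_log_error
#' @param log10_scale compute in log10 space.
#' @export
rmse_error <- function(posterior, theta_true, log10_scale = FALSE) {
  stopifnot(inherits(posterior, "abc_posterior"))
  w <- posterior$weights
  if (any(!is.finite(w)) || sum(w) <= 0) stop_domain("invalid posterior weights")
  s <- posterior$samples
  tt <- as.numeric(theta_true)
  if (log10_scale) {
    s <- log10(s); tt <- log10(tt)
  }
  d <- sweep(s, 2, tt)
  sqrt(sum(w * rowSums(d^2)))
}

#' Build an error map over a parameter grid
#'
#' Applies an error metric to one posterior per grid point; points whose
#' inference failed are flagged (`status = "failed"`, error `NA`), never
#' silently reported as zero error.
#'
#' @param posteriors list of `abc_posterior` (or `NULL` for failed
#'   points), indexed like `grid$points`.
#' @param grid a `param_grid`.
#' @param error_metric `function(posterior, theta_true) -> real`.
#' @param metadata named list attached to the map (model, metric,
#'   scenario...).
#' @return An object of class `error_map`: data.frame (index, D, chi,
#'   error, status) plus metadata.
#' @export
build_error_map <- function(posteriors, grid, error_metric = expected_log_error,
                            metadata = list()) {
  stopifnot(inherits(grid, "param_grid"))
  n <- nrow(grid$points)
  if (length(posteriors) != n) {
    stop_domain("need exactly one posterior slot per grid point (missing points must be NULL)")
  }
  err <- rep(NA_real_, n)
  status <- rep("failed", n)
  for (i in seq_len(n)) {
    p <- posteriors[[i]]
    if (!is.null(p)) {
      err[i] <- error_metric(p, c(grid$points$D[i], grid$points$chi[i]))
      status[i] <- "ok"
    }
  }
  structure(
    list(table = data.frame(index = grid$points$index, D = grid$points$D,
                            chi = grid$points$chi, error = err,
                            status = status),
         grid = grid, metadata = metadata),
    class = "error_map"
  )
}

#' @export
print.error_map <- function(x, ...) {
  ok <- x$table$status == "ok"
  cat(sprintf("error_map (%s): %d/%d points, median error %.3f\n",
              paste(unlist(x$metadata), collapse = "/"),
              sum(ok), nrow(x$table), median(x$table$error[ok])))
  invisible(x)
}

#' Write / read an error map as CSV (columns D, chi, error, status)
#'
#' Metadata round-trips through a JSON sidecar.
#'
#' @param map an `error_map`.
#' @param path CSV path.
#' @export
error_map_to_csv <- function(map, path) {
  write.csv(map$table, path, row.names = FALSE)
  side <- sub("\\.csv$", ".json", path)
  jsonlite::write_json(
    list(metadata = map$metadata, n_D = map$grid$n_D, n_chi = map$grid$n_chi),
    side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname error_map_to_csv
#' @export
error_map_from_csv <- function(path) {
  tab <- read.csv(path)
  side <- sub("\\.csv$", ".json", path)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  structure(
    list(table = tab, grid = make_grid(meta$n_D, meta$n_chi),
         metadata = as.list(meta$metadata)),
    class = "error_map"
  )
}

#' Heatmap of an error map (log-scaled axes)
#'
#' @param x an `error_map`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
plot.error_map <- function(x, ...) {
  tab <- x$table
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$chi, y = .data$D,
                                    fill = .data$error)) +
    ggplot2::geom_tile() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_c(name = "expected\nlog-error") +
    ggplot2::labs(x = expression(chi), y = expression(D ~ (mu * m^2 / min)))
}

#' Extended (boxen-style) quantile summary
#'
#' Quartiles plus the successive tail `2^-n` quantiles below/above them
#' (`n >= 2`), descending until fewer than one observation separates
#' successive levels. Linear interpolation between order statistics
#' (type 7).
#'
#' @param errors numeric vector, length >= 8.
#' @return An object of class `boxen_summary`: data.frame (level, value),
#'   monotone in `level`.
#' @export
boxen_summary <- function(errors) {
  x <- errors[is.finite(errors)]
  n <- length(x)
  if (n < 8) stop_domain("boxen_summary needs at least 8 finite values")
  depths <- 2L
  while (n * 2^-(depths[length(depths)] + 1L) >= 1) {
    depths <- c(depths, depths[length(depths)] + 1L)
  }
  levels <- sort(unique(c(0.5, 2^-depths, 1 - 2^-depths, 0.25, 0.75)))
  structure(
    list(table = data.frame(level = levels,
                            value = as.numeric(quantile(x, levels, type = 7))),
         n = n),
    class = "boxen_summary"
  )
}

#' @export
print.boxen_summary <- function(x, ...) {
  cat("boxen summary of", x$n, "values\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Side-by-side boxen plot of several error distributions
#'
#' @param groups named list of numeric vectors (one per setup).
#' @return A ggplot object (letter-value style boxes at successive tail
#'   quantiles).
#' @export
plot_boxen <- function(groups) {
  dat <- do.call(rbind, lapply(names(groups), function(g) {
    bs <- boxen_summary(groups[[g]])$table
    k <- nrow(bs)
    lower <- bs[bs$level <= 0.5, ]
    upper <- bs[bs$level >= 0.5, ]
    m <- min(nrow(lower), nrow(upper))
    data.frame(group = g,
               ymin = rev(lower$value)[seq_len(m)],
               ymax = upper$value[seq_len(m)],
               depth = seq_len(m))
  }))
  ggplot2::ggplot(dat) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = as.numeric(factor(.data$group)) - 0.4 / .data$depth,
      xmax = as.numeric(factor(.data$group)) + 0.4 / .data$depth,
      ymin = .data$ymin, ymax = .data$ymax, fill = .data$group),
      alpha = 0.7) +
    ggplot2::scale_x_continuous(breaks = seq_along(groups),
                                labels = names(groups)) +
    ggplot2::labs(x = NULL, y = "expected log-error") +
    ggplot2::theme(legend.position = "none")
}
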