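# broom-style accessors and ggplot2 diagnostics for fitted objects.

#' Tidy a fitted expression model
#'
#' One row per (sample, region) with the estimated expression proportion.
#'
#' @param x An `mgmr_fit`.
#' @param ... Unused.
#' @return A tibble `sample_id`, `region_id`, `proportion` (and `alpha`
#'   per region for population fits).
#' @export
tidy.mgmr_fit <- function(x, ...) {
  out <- x$expression |>
    tidyr::pivot_longer(-"sample_id", names_to = "region_id",
                        values_to = "proportion")
  if (!is.null(x$alpha)) {
    out$alpha <- x$alpha[out$region_id]
  }
  out
}

#' One-row summary of a fitted expression model
#'
#' @inheritParams tidy.mgmr_fit
#' @return A tibble with sample/region counts, iteration count, convergence
#'   flag, final L1 alpha change and final penalized log-likelihood (the
#'   latter two `NA` for the uncoupled baseline).
#' @export
glance.mgmr_fit <- function(x, ...) {
  tibble::tibble(
    n_samples = length(x$sample_ids),
    n_regions = length(x$region_ids),
    iterations = x$iterations,
    converged = x$converged,
    alpha_total = if (is.null(x$alpha)) NA_real_ else sum(x$alpha),
    alpha_change = if (is.null(x$history) || nrow(x$history) == 0L)
      NA_real_ else x$history$alpha_change[nrow(x$history)],
    log_likelihood = if (is.null(x$history) || nrow(x$history) == 0L)
      NA_real_ else x$history$log_likelihood[nrow(x$history)]
  )
}

#' Convergence diagnostics plot for a population fit
#'
#' Penalized log-likelihood and L1 alpha change per iteration (the latter
#' on a log scale), from the recorded history.
#'
#' @param object An `mgmr_fit` fitted with `record_history = TRUE`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mgmr_fit <- function(object, ...) {
  if (is.null(object$history) || nrow(object$history) == 0L) {
    abort("no history recorded; refit with record_history = TRUE",
          class = "mgmr_invalid_input")
  }
  df <- object$history |>
    dplyr::transmute(
      iteration = .data$iteration,
      `log-likelihood` = .data$log_likelihood,
      `log10 |d alpha|` = log10(.data$alpha_change)
    ) |>
    tidyr::pivot_longer(-"iteration", names_to = "quantity",
                        values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$quantity), ncol = 1L,
                        scales = "free_y") +
    ggplot2::labs(x = "iteration", y = NULL,
                  title = "Population fit convergence")
}

#' Tidy an error report
#'
#' @param x An `mgmr_error_report` from [aggregate_errors()].
#' @param ... Unused.
#' @return The aggregate tibble (`measure`, `mean`, `sd`).
#' @export
tidy.mgmr_error_report <- function(x, ...) {
  x$aggregate
}

#' Error-measure comparison plot
#'
#' Mean +/- SD of each error measure, optionally for several named methods.
#'
#' @param object An `mgmr_error_report`, or a named list of them (one per
#'   method).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mgmr_error_report <- function(object, ...) {
  df <- object$aggregate
  df$method <- "estimate"
  plot_error_reports(df)
}

#' @rdname autoplot.mgmr_error_report
#' @param reports Named list of `mgmr_error_report`s.
#' @export
plot_error_comparison <- function(reports) {
  df <- dplyr::bind_rows(lapply(reports, function(r) r$aggregate),
                         .id = "method")
  plot_error_reports(df)
}

plot_error_reports <- function(df) {
  ggplot2::ggplot(df, ggplot2::aes(.data$method, .data$mean)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$measure), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "error (mean +/- SD over samples)")
}
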