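# Estimate-versus-truth error measures and their two-stage aggregation
# (mean over repetitions per sample, then mean and SD over samples).

check_measure_input <- function(p, q) {
  p <- as.numeric(p)
  q <- as.numeric(q)
  if (length(p) != length(q)) {
    abort("estimate and truth vectors must have the same length",
          class = "mgmr_schema_error")
  }
  list(p = p, q = q)
}

#' Relative error between an estimate and the truth
#'
#' Mean over regions of `|P_k - Q_k| / Q_k`. Regions with zero truth are
#' excluded from the mean (the ratio is undefined there); exclusions are
#' reported with a warning. With `signed = TRUE` the absolute value is
#' dropped for exploration, at the cost of positive and negative deviations
#' cancelling.
#'
#' @param p Estimated proportion vector.
#' @param q True proportion vector.
#' @param signed Keep the sign of each deviation (default `FALSE`).
#' @return A single number.
#' @export
#' @examples
#' relative_error(c(0.6, 0.4), c(0.5, 0.5)) # 0.2
relative_error <- function(p, q, signed = FALSE) {
  v <- check_measure_input(p, q)
  keep <- v$q > 0
  if (!all(keep)) {
    warn(sprintf("excluded %d region(s) with zero truth from relative error",
                 sum(!keep)))
  }
  dev <- (v$p[keep] - v$q[keep]) / v$q[keep]
  mean(if (signed) dev else abs(dev))
}

#' Chi-squared error between an estimate and the truth
#'
#' `sum_k (P_k - Q_k)^2 / Q_k` over regions with positive truth (zero-truth
#' regions are excluded with a warning).
#'
#' @inheritParams relative_error
#' @return A single nonnegative number.
#' @export
chi_squared_error <- function(p, q) {
  v <- check_measure_input(p, q)
  keep <- v$q > 0
  if (!all(keep)) {
    warn(sprintf("excluded %d region(s) with zero truth from chi-squared",
                 sum(!keep)))
  }
  sum((v$p[keep] - v$q[keep])^2 / v$q[keep])
}

#' Kullback-Leibler divergence from the truth to the estimate
#'
#' `sum_k P_k log(P_k / Q_k)` with the convention `0 log(0/q) = 0`.
#' Nonnegative when both vectors are normalized. If some `P_k > 0` where
#' `Q_k = 0` the divergence is infinite and reported as such with a warning.
#'
#' @inheritParams relative_error
#' @return A single nonnegative number (possibly `Inf`).
#' @export
kl_divergence <- function(p, q) {
  v <- check_measure_input(p, q)
  if (any(v$p > 0 & v$q == 0)) {
    warn("estimate has mass where truth is zero; KL divergence is infinite")
    return(Inf)
  }
  pos <- v$p > 0
  sum(v$p[pos] * log(v$p[pos] / v$q[pos]))
}

#' Per-sample error measures of an estimate matrix against a truth matrix
#'
#' @param estimate,truth `mgmr_expression` tibbles (or numeric matrices)
#'   with matching samples and regions.
#' @param repetition Optional repetition label added as a column.
#' @return A tibble `sample_id`, `relative_error`, `chi_squared`, `kl`
#'   (plus `repetition` when given).
#' @export
evaluate_errors <- function(estimate, truth, repetition = NULL) {
  pe <- if (is.data.frame(estimate)) as_expression_values(estimate) else estimate
  qt <- if (is.data.frame(truth)) as_expression_values(truth) else truth
  if (!all(dim(pe) == dim(qt))) {
    abort("estimate and truth must have the same shape",
          class = "mgmr_schema_error")
  }
  out <- tibble::tibble(
    sample_id = rownames(pe) %||% sprintf("sample%03d", seq_len(nrow(pe))),
    relative_error = vapply(seq_len(nrow(pe)), function(i) {
      relative_error(pe[i, ], qt[i, ])
    }, numeric(1)),
    chi_squared = vapply(seq_len(nrow(pe)), function(i) {
      chi_squared_error(pe[i, ], qt[i, ])
    }, numeric(1)),
    kl = vapply(seq_len(nrow(pe)), function(i) {
      kl_divergence(pe[i, ], qt[i, ])
    }, numeric(1))
  )
  if (!is.null(repetition)) {
    out <- tibble::add_column(out, repetition = repetition, .before = 1L)
  }
  out
}

#' Aggregate per-sample error measures over repetitions and samples
#'
#' Two-stage aggregation: each measure is first averaged over repetitions
#' within each sample, then the mean and standard deviation are taken over
#' samples — in that order.
#'
#' @param reports A tibble of per-sample measures with columns
#'   `repetition`, `sample_id`, `relative_error`, `chi_squared`, `kl`
#'   (rows from [evaluate_errors()], bound over repetitions).
#' @return An object of class `mgmr_error_report`: list with `per_sample`
#'   (per-sample means over repetitions) and `aggregate` (tibble `measure`,
#'   `mean`, `sd` over samples).
#' @export
aggregate_errors <- function(reports) {
  needed <- c("sample_id", "relative_error", "chi_squared", "kl")
  if (!all(needed %in% names(reports))) {
    abort("reports must carry sample_id and the three measures",
          class = "mgmr_schema_error")
  }
  if (!"repetition" %in% names(reports)) reports$repetition <- 1L
  per_sample <- reports |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(
      c("relative_error", "chi_squared", "kl")), mean), .groups = "drop")
  aggregate <- per_sample |>
    tidyr::pivot_longer(-"sample_id", names_to = "measure",
                        values_to = "value") |>
    dplyr::group_by(.data$measure) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                     .groups = "drop") |>
    dplyr::arrange(match(.data$measure,
                         c("relative_error", "chi_squared", "kl")))
  structure(list(per_sample = per_sample, aggregate = aggregate),
            class = "mgmr_error_report")
}

#' @export
print.mgmr_error_report <- function(x, ...) {
  cat("<mgmr_error_report> aggregate over",
      nrow(x$per_sample), "sample(s):\n")
  print(x$aggregate)
  invisible(x)
}

#' Count regions on which one method beats another
#'
#' A region counts as improved when method A's mean absolute deviation from
#' the truth over samples is strictly smaller than method B's.
#'
#' @param estimates_a,estimates_b,truth Expression tibbles or matrices of
#'   identical shape.
#' @return A tibble `n_improved`, `n_regions`, `proportion`.
#' @export
improved_region_count <- function(estimates_a, estimates_b, truth) {
  a <- if (is.data.frame(estimates_a)) as_expression_values(estimates_a) else estimates_a
  b <- if (is.data.frame(estimates_b)) as_expression_values(estimates_b) else estimates_b
  q <- if (is.data.frame(truth)) as_expression_values(truth) else truth
  if (!all(dim(a) == dim(q)) || !all(dim(b) == dim(q))) {
    abort("all three matrices must have the same shape",
          class = "mgmr_schema_error")
  }
  mad_a <- colMeans(abs(a - q))
  mad_b <- colMeans(abs(b - q))
  n_improved <- sum(mad_a < mad_b)
  tibble::tibble(n_improved = n_improved, n_regions = ncol(q),
                 proportion = n_improved / ncol(q))
}
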