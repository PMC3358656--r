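#' Population-coupled expression estimation (MGMR)
#'
#' Jointly estimates per-sample expression proportions and the population's
#' Dirichlet hyperparameters from per-sample read-to-region alignment
#' tables. Each iteration performs, for every sample, one E-step
#' (read-to-region responsibilities) and one M-step P update combining the
#' responsibility totals with the Dirichlet pseudo-counts, followed by a
#' single digamma fixed-point update of the hyperparameters. Iteration
#' stops when the L1 change in alpha falls below `alpha_tolerance` or after
#' `max_iterations`. Alpha starts as a vector of ones; updates are kept
#' local (one P step, one alpha step) because the joint objective is not
#' convex.
#'
#' @param tables List of per-sample [alignment_table()]s sharing one region
#'   set (with or without `q`).
#' @param regions The shared [region_set()].
#' @param init Initial expression estimates: an `mgmr_expression` tibble, a
#'   numeric matrix, or `NULL` for the per-sample naive estimate
#'   ([naive_expression()]). Zero entries are floored at `1e-20`.
#' @param epsilon Per-base error rate used to build `q` when absent.
#' @param max_iterations Iteration cap (default 100).
#' @param alpha_tolerance Stop when `sum(abs(alpha_change))` drops below
#'   this (default `1e-6`).
#' @param alpha_plus_one_shift Use the `alpha + 1` shift in the P update
#'   (default; see [p_update()]). The literal update is available for study
#'   but errors when a numerator would go negative.
#' @param alpha_inner_iterations Fixed-point applications per alpha step
#'   (default 1; values > 1 trade locality for faster prior adaptation).
#' @param record_history Record per-iteration alpha, its L1 change and the
#'   penalized log-likelihood.
#'
#' @return An object of class `mgmr_fit`: a list with `expression` (an
#'   `mgmr_expression` tibble), `alpha` (named vector), `history` (tibble
#'   `iteration`, `alpha_change`, `log_likelihood`, `alpha` list-column),
#'   `iterations`, `converged`, and the configuration used. Supports
#'   [tidy()], [glance()] and [autoplot()].
#' @export
#' @examples
#' regions <- region_set(c("gA", "gB"), c(50L, 50L), read_length = 10L)
#' tab <- alignment_table(
#'   tibble::tibble(read_id = c("r1", "r1", "r2"),
#'                  region_id = c("gA", "gB", "gA"),
#'                  mismatches = c(0L, 1L, 0L)),
#'   sample_id = "s1"
#' )
#' fit <- mgmr_fit(list(tab, tab), regions, max_iterations = 5)
#' fit$alpha
mgmr_fit <- function(tables, regions, init = NULL, epsilon = 0.01,
                     max_iterations = 100L, alpha_tolerance = 1e-6,
                     alpha_plus_one_shift = TRUE,
                     alpha_inner_iterations = 1L,
                     record_history = TRUE) {
  assert_region_set(regions)
  if (!is.list(tables) || length(tables) == 0L) {
    abort("tables must be a nonempty list of alignment tables",
          class = "mgmr_invalid_input")
  }
  if (max_iterations < 1L) {
    abort("max_iterations must be >= 1", class = "mgmr_invalid_input")
  }
  n <- length(tables)
  if (n == 1L) {
    mgmr_log("warn", "fitting a population prior to a single sample is ",
             "degenerate; estimates reduce to MAP-EM under a learned prior")
  }
  region_ids <- regions$region_id
  m_regions <- length(region_ids)
  tables <- lapply(tables, function(tb) {
    if (!("q" %in% names(tb))) build_q(tb, regions, epsilon) else tb
  })
  sample_ids <- vapply(seq_len(n), function(i) {
    attr(tables[[i]], "sample_id") %||% sprintf("sample%03d", i)
  }, character(1))

  p_mat <- init_expression(init, tables, regions, sample_ids)
  preps <- lapply(tables, prep_table, region_ids = region_ids)

  alpha <- rep(1, m_regions)
  history <- if (record_history) vector("list", max_iterations) else NULL
  converged <- FALSE
  iterations_run <- 0L

  for (iter in seq_len(max_iterations)) {
    for (i in seq_len(n)) {
      if (preps[[i]]$n_reads == 0L) next
      a <- e_step(preps[[i]], p_mat[i, ])
      sums <- responsibility_sums(preps[[i]], a)
      p_mat[i, ] <- p_update(sums, alpha, shift = alpha_plus_one_shift)
    }
    alpha_new <- alpha_update(alpha, log_mean_log_p(p_mat),
                              n_inner = alpha_inner_iterations)
    delta <- sum(abs(alpha_new - alpha))
    alpha <- alpha_new
    iterations_run <- iter
    if (record_history) {
      history[[iter]] <- tibble::tibble(
        iteration = iter,
        alpha_change = delta,
        log_likelihood = penalized_log_likelihood(p_mat, alpha, tables,
                                                  region_ids = region_ids),
        alpha = list(setNames(alpha, region_ids))
      )
      mgmr_log("debug", sprintf(
        "iteration %d: |d alpha| = %.3g, log-likelihood = %.6g",
        iter, delta, history[[iter]]$log_likelihood))
    }
    if (delta < alpha_tolerance) {
      converged <- TRUE
      break
    }
  }

  colnames(p_mat) <- region_ids
  rownames(p_mat) <- sample_ids
  structure(
    list(
      expression = expression_matrix(p_mat, renormalize = TRUE),
      alpha = setNames(alpha, region_ids),
      history = if (record_history) {
        dplyr::bind_rows(history[seq_len(iterations_run)])
      } else NULL,
      iterations = iterations_run,
      converged = converged,
      config = list(epsilon = epsilon, max_iterations = max_iterations,
                    alpha_tolerance = alpha_tolerance,
                    alpha_plus_one_shift = alpha_plus_one_shift,
                    alpha_inner_iterations = alpha_inner_iterations),
      sample_ids = sample_ids,
      region_ids = region_ids
    ),
    class = "mgmr_fit"
  )
}

# resolve the initial expression matrix: user-supplied (tibble or matrix)
# or the naive per-sample estimate; always floored strictly positive
init_expression <- function(init, tables, regions, sample_ids) {
  m_regions <- n_regions(regions)
  if (is.null(init)) {
    vals <- vapply(tables, naive_expression, numeric(m_regions),
                   regions = regions)
    p_mat <- if (m_regions == 1L) matrix(vals, ncol = 1L) else t(vals)
  } else {
    p_mat <- if (is.data.frame(init)) as_expression_values(init) else init
    if (!is.matrix(p_mat)) p_mat <- matrix(p_mat, nrow = 1L)
    if (nrow(p_mat) != length(tables) || ncol(p_mat) != m_regions) {
      abort("init must be (n samples) x (n regions)",
            class = "mgmr_schema_error")
    }
    if (!is.null(colnames(p_mat)) &&
        !identical(colnames(p_mat), regions$region_id)) {
      p_mat <- p_mat[, regions$region_id, drop = FALSE]
    }
    n_floored <- sum(p_mat < P_FLOOR)
    if (n_floored > 0L) {
      mgmr_log("info", sprintf("floored %d initial expression entries at %g",
                               n_floored, P_FLOOR))
    }
    p_mat <- floor_expression(p_mat)
    p_mat <- p_mat / rowSums(p_mat)
  }
  rownames(p_mat) <- sample_ids
  colnames(p_mat) <- regions$region_id
  p_mat
}

#' Independent per-sample EM fits, packaged like a population fit
#'
#' Runs [single_sample_em()] on every sample with a shared iteration budget.
#' This is the uncoupled baseline against which the population-coupled fit
#' is compared.
#'
#' @inheritParams mgmr_fit
#' @param iterations EM iterations per sample.
#' @return An object of class `mgmr_fit` with `alpha = NULL`.
#' @export
em_fit <- function(tables, regions, init = NULL, epsilon = 0.01,
                   iterations = 100L) {
  assert_region_set(regions)
  if (!is.list(tables) || length(tables) == 0L) {
    abort("tables must be a nonempty list of alignment tables",
          class = "mgmr_invalid_input")
  }
  tables <- lapply(tables, function(tb) {
    if (!("q" %in% names(tb))) build_q(tb, regions, epsilon) else tb
  })
  sample_ids <- vapply(seq_along(tables), function(i) {
    attr(tables[[i]], "sample_id") %||% sprintf("sample%03d", i)
  }, character(1))
  p_mat <- init_expression(init, tables, regions, sample_ids)
  for (i in seq_along(tables)) {
    p_mat[i, ] <- single_sample_em(tables[[i]], init = p_mat[i, ],
                                   iterations = iterations)
  }
  structure(
    list(
      expression = expression_matrix(p_mat, renormalize = TRUE),
      alpha = NULL,
      history = NULL,
      iterations = iterations,
      converged = NA,
      config = list(epsilon = epsilon, iterations = iterations),
      sample_ids = sample_ids,
      region_ids = regions$region_id
    ),
    class = "mgmr_fit"
  )
}

#' @export
print.mgmr_fit <- function(x, ...) {
  kind <- if (is.null(x$alpha)) "independent per-sample EM" else
    "population-coupled (MGMR)"
  cat(sprintf("<mgmr_fit> %s\n", kind))
  cat(sprintf("  samples: %d   regions: %d   iterations: %d\n",
              length(x$sample_ids), length(x$region_ids), x$iterations))
  if (!is.null(x$alpha)) {
    cat(sprintf("  converged: %s   sum(alpha): %.3f\n",
                x$converged, sum(x$alpha)))
  }
  invisible(x)
}
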