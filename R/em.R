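# EM machinery shared by the single-sample baseline and the population fit.
#
# Internally each alignment table is "prepped" once into integer index
# vectors (read index j, region index k, probability q) so that every E-step
# is a handful of vectorized operations; the exported responsibilities()
# is the tidy veneer over the same computation.

prep_table <- function(table, region_ids) {
  assert_alignment_table(table)
  if (!("q" %in% names(table))) {
    abort("alignment table has no q column; run build_q() first",
          class = "mgmr_schema_error")
  }
  read_ids <- unique(table$read_id)
  j <- match(table$read_id, read_ids)
  k <- match(table$region_id, region_ids)
  if (anyNA(k)) {
    abort("alignment table refers to regions outside the region set",
          class = "mgmr_schema_error")
  }
  list(j = j, k = k, q = table$q, read_ids = read_ids,
       n_reads = length(read_ids), M = length(region_ids))
}

# E-step for one sample: responsibilities a_jk = P_k q_jk / sum_k P_k q_jk
# over each read's stored regions. Returns the per-entry responsibilities.
e_step <- function(prep, p) {
  w <- unname(p)[prep$k] * prep$q
  denom <- rowsum(w, prep$j)[, 1L] # groups 1..n_reads, sorted ascending
  bad <- which(denom == 0 | !is.finite(denom))
  if (length(bad) > 0L) {
    abort(paste0("responsibility denominator vanished for read(s): ",
                 paste(head(prep$read_ids[bad], 5L), collapse = ", ")),
          class = "mgmr_degenerate_read")
  }
  w / unname(denom[prep$j])
}

# per-region responsibility totals sum_j a_jk, as a dense M-vector
responsibility_sums <- function(prep, a) {
  sums <- numeric(prep$M)
  rs <- rowsum(a, prep$k)
  sums[as.integer(rownames(rs))] <- rs[, 1L]
  sums
}

#' Posterior read-to-region responsibilities for one sample
#'
#' The E-step quantity: the posterior probability that a read originated
#' from each region it aligns to, given the sample's current expression
#' proportions. Per read, responsibilities sum to 1.
#'
#' @param p_row Named numeric probability vector of expression proportions
#'   (names are region ids), or an unnamed vector ordered as the table's
#'   regions appear in `region_ids`.
#' @param table An [alignment_table()] with its `q` column (see [build_q()]).
#' @param region_ids Region ordering; defaults to `names(p_row)`.
#' @return A tibble `read_id`, `region_id`, `responsibility`.
#' @export
responsibilities <- function(p_row, table, region_ids = names(p_row)) {
  if (is.null(region_ids)) {
    abort("p_row must be named by region id (or supply region_ids)",
          class = "mgmr_invalid_input")
  }
  p <- as.numeric(p_row)
  prep <- prep_table(table, region_ids)
  tibble::tibble(
    read_id = table$read_id,
    region_id = table$region_id,
    responsibility = e_step(prep, p)
  )
}

#' Maximization-step update of one sample's expression proportions
#'
#' Combines the per-region responsibility totals with the Dirichlet prior
#' pseudo-counts. With `shift = TRUE` (the default heuristic) the update is
#' `P_k = (alpha_k + S_k) / sum_k (alpha_k + S_k)`, which can never go
#' negative; with `shift = FALSE` it is the literal stationary point
#' `P_k = (alpha_k - 1 + S_k) / sum_k (alpha_k - 1 + S_k)`, valid only when
#' every numerator is nonnegative.
#'
#' @param resp_sums Numeric M-vector of per-region responsibility totals.
#' @param alpha Dirichlet hyperparameter vector (all positive).
#' @param shift Use the `alpha + 1` shift (drop the `-1`)?
#' @return A probability vector (floored away from exact zero).
#' @export
p_update <- function(resp_sums, alpha, shift = TRUE) {
  stopifnot(length(resp_sums) == length(alpha))
  if (any(alpha <= 0) || any(!is.finite(alpha))) {
    abort("alpha must be strictly positive and finite",
          class = "mgmr_invalid_input")
  }
  if (any(resp_sums < 0)) {
    abort("responsibility sums must be nonnegative",
          class = "mgmr_invalid_input")
  }
  num <- if (shift) alpha + resp_sums else alpha - 1 + resp_sums
  if (!shift && any(num < 0)) {
    abort("alpha - 1 + responsibility sum is negative; use shift = TRUE",
          class = "mgmr_negative_probability")
  }
  p <- num / sum(num)
  floor_expression(p)
}

#' Naive expression estimate for one sample
#'
#' Splits each read uniformly across the regions it maps to and normalizes.
#' This is the default initialization when no external estimate is supplied.
#'
#' @inheritParams build_q
#' @return Named probability vector over `regions$region_id`.
#' @export
naive_expression <- function(table, regions) {
  assert_alignment_table(table)
  assert_region_set(regions)
  p <- numeric(n_regions(regions))
  names(p) <- regions$region_id
  if (nrow(table) > 0L) {
    j <- match(table$read_id, unique(table$read_id))
    w <- 1 / tabulate(j)[j]
    agg <- tapply(w, table$region_id, sum)
    p[names(agg)] <- agg / sum(w)
  }
  floor_expression(p / sum(p))
}

#' Single-sample EM expression estimation
#'
#' The uncoupled baseline: standard EM on one sample's alignment table,
#' alternating responsibilities with the update `P_k = (1/rho) sum_j a_jk`
#' (`rho` reads in the sample). The likelihood of the sample's reads is
#' non-decreasing over iterations.
#'
#' @param table An [alignment_table()] with `q` (or without, if `regions`
#'   and `epsilon` are supplied so `q` can be built).
#' @param init Named probability vector; defaults to the naive estimate.
#' @param iterations Number of EM iterations.
#' @param regions Region set (required when `init` is unnamed or `q` absent).
#' @param epsilon Per-base error rate used if `q` must be built.
#' @return Named probability vector of expression proportions.
#' @export
single_sample_em <- function(table, init = NULL, iterations = 100L,
                             regions = NULL, epsilon = 0.01) {
  if (!("q" %in% names(table))) {
    if (is.null(regions)) {
      abort("supply `regions` so q can be built", class = "mgmr_schema_error")
    }
    table <- build_q(table, regions, epsilon)
  }
  region_ids <- if (!is.null(regions)) regions$region_id else names(init)
  if (is.null(region_ids)) {
    abort("region ordering unknown: name `init` or pass `regions`",
          class = "mgmr_invalid_input")
  }
  if (is.null(init)) {
    if (is.null(regions)) {
      abort("supply `init` or `regions`", class = "mgmr_invalid_input")
    }
    init <- naive_expression(table, regions)
  }
  p <- floor_expression(as.numeric(init))
  p <- p / sum(p)
  if (nrow(table) == 0L) {
    warn("sample has no mapped reads; returning the initial estimate")
    return(setNames(p, region_ids))
  }
  prep <- prep_table(table, region_ids)
  for (it in seq_len(iterations)) {
    a <- e_step(prep, p)
    p <- floor_expression(responsibility_sums(prep, a) / prep$n_reads)
  }
  setNames(p, region_ids)
}

#' Penalized log-likelihood of the population model
#'
#' The joint log-likelihood of all samples' reads and their expression
#' proportions under the shared Dirichlet prior:
#' `N log C(alpha) + sum_k (alpha_k - 1) sum_i log P_ik +
#'  sum_i sum_j log(sum_k P_ik q_ijk)`,
#' with `log C(alpha) = lgamma(sum alpha) - sum lgamma(alpha)`.
#'
#' @param P Expression matrix (tibble with `sample_id`, or numeric matrix)
#'   with one row per table in `tables`.
#' @param alpha Dirichlet hyperparameters (length = number of regions).
#' @param tables List of per-sample alignment tables with `q`.
#' @param region_ids Region ordering matching `alpha`; defaults to the
#'   expression matrix's columns.
#' @return A single number (natural-log scale).
#' @export
penalized_log_likelihood <- function(P, alpha, tables, region_ids = NULL) {
  m <- if (is.data.frame(P)) as_expression_values(P) else P
  region_ids <- region_ids %||% colnames(m)
  if (ncol(m) != length(alpha)) {
    abort("alpha length must equal the number of regions",
          class = "mgmr_schema_error")
  }
  if (nrow(m) != length(tables)) {
    abort("one alignment table per expression row is required",
          class = "mgmr_schema_error")
  }
  if (any(m <= 0)) {
    abort("P must be strictly positive (apply the 1e-20 floor)",
          class = "mgmr_domain_error")
  }
  log_c <- lgamma(sum(alpha)) - sum(lgamma(alpha))
  prior_term <- sum((alpha - 1) * colSums(log(m)))
  read_term <- 0
  for (i in seq_along(tables)) {
    prep <- prep_table(tables[[i]], region_ids)
    w <- m[i, ][prep$k] * prep$q
    read_term <- read_term + sum(log(rowsum(w, prep$j)[, 1L]))
  }
  nrow(m) * log_c + prior_term + read_term
}

# Eq-1-style log-likelihood of a single sample's reads (no prior term);
# used by the baseline's ascent property and the grid-search cross-checks.
sample_log_likelihood <- function(p, table, region_ids = names(p)) {
  prep <- prep_table(table, region_ids)
  w <- as.numeric(p)[prep$k] * prep$q
  sum(log(rowsum(w, prep$j)[, 1L]))
}
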