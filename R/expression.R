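#' Expression matrices as tibbles
#'
#' An expression matrix holds the row-stochastic N x M matrix of per-sample
#' expression proportions: one row per sample, one column per region, each
#' row summing to 1. The tibble form has a leading `sample_id` column; the
#' numeric form is a plain matrix with sample ids as rownames. Zero entries
#' are floored at `1e-20` on construction so that logarithms of the matrix
#' (needed by the Dirichlet prior) stay finite.
#'
#' @param values Numeric matrix (samples x regions) or a data frame with a
#'   `sample_id` column and one numeric column per region.
#' @param sample_ids,region_ids Identifiers; taken from dimnames when absent.
#' @param renormalize Renormalize rows that do not sum to 1 (with a warning
#'   when the deviation exceeds `1e-4`).
#' @return A tibble of class `mgmr_expression` (`sample_id` + one column per
#'   region).
#' @export
expression_matrix <- function(values, sample_ids = NULL, region_ids = NULL,
                              renormalize = FALSE) {
  if (is.data.frame(values)) {
    stopifnot("sample_id" %in% names(values))
    sample_ids <- sample_ids %||% as.character(values$sample_id)
    values <- as.matrix(values[setdiff(names(values), "sample_id")])
  }
  if (!is.matrix(values)) values <- matrix(values, nrow = 1L)
  sample_ids <- sample_ids %||% rownames(values) %||%
    sprintf("sample%03d", seq_len(nrow(values)))
  region_ids <- region_ids %||% colnames(values)
  if (is.null(region_ids)) {
    abort("region ids are required (column names or `region_ids`)",
          class = "mgmr_schema_error")
  }
  if (!is.numeric(values) || anyNA(values) || any(values < 0)) {
    abort("expression values must be nonnegative numbers",
          class = "mgmr_invalid_input")
  }
  sums <- rowSums(values)
  if (any(sums <= 0)) {
    abort("every sample row needs positive total expression",
          class = "mgmr_invalid_input")
  }
  off <- abs(sums - 1) > 1e-8
  if (any(off)) {
    if (!renormalize) {
      abort("expression rows must sum to 1 (set renormalize = TRUE to rescale)",
            class = "mgmr_invalid_input")
    }
    if (any(abs(sums - 1) > 1e-4)) {
      warn(sprintf("renormalized %d expression row(s) deviating from sum 1 by up to %.2g",
                   sum(off), max(abs(sums - 1))))
    }
    values <- values / sums
  }
  values <- floor_expression(values)
  out <- tibble::as_tibble(as.data.frame(values))
  names(out) <- region_ids
  out <- tibble::add_column(out, sample_id = as.character(sample_ids),
                            .before = 1L)
  class(out) <- c("mgmr_expression", class(out))
  out
}

# floor exact zeros (and anything below the floor) so log P is finite;
# the perturbation is ~1e-20 per entry, far inside the 1e-8 row-sum tolerance
floor_expression <- function(values) {
  values[values < P_FLOOR] <- P_FLOOR
  values
}

#' @rdname expression_matrix
#' @param x An `mgmr_expression` tibble (or compatible data frame).
#' @export
as_expression_values <- function(x) {
  stopifnot(is.data.frame(x), "sample_id" %in% names(x))
  m <- as.matrix(x[setdiff(names(x), "sample_id")])
  rownames(m) <- as.character(x$sample_id)
  m
}

assert_expression <- function(x, region_ids = NULL) {
  m <- as_expression_values(x)
  if (any(abs(rowSums(m) - 1) > 1e-8)) {
    abort("expression rows must sum to 1 within 1e-8",
          class = "mgmr_invalid_input")
  }
  if (!is.null(region_ids) && !identical(colnames(m), region_ids)) {
    abort("expression columns do not match the region set",
          class = "mgmr_schema_error")
  }
  invisible(m)
}
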