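#' Construct an alignment table
#'
#' An alignment table is the sparse read-by-region structure for one sample:
#' one row per accepted (read, region) alignment with its mismatch count.
#' Reads with no accepted alignment never enter the table; their count is
#' carried in the `n_unmapped` attribute so nothing is silently lost.
#'
#' @param mappings A data frame with columns `read_id`, `region_id` and
#'   `mismatches` (one row per accepted alignment; the best — minimum —
#'   mismatch count per pair).
#' @param sample_id Optional sample identifier.
#' @param n_unmapped Count of reads dropped for having no accepted alignment.
#' @param max_mismatches Upper bound on accepted mismatch counts (default 2).
#'
#' @return A tibble of class `mgmr_alignment_table` with columns `read_id`,
#'   `region_id`, `mismatches` (and `q` once [build_q()] has run).
#' @export
alignment_table <- function(mappings, sample_id = NULL, n_unmapped = 0L,
                            max_mismatches = 2L) {
  mappings <- tibble::as_tibble(mappings)
  needed <- c("read_id", "region_id", "mismatches")
  if (!all(needed %in% names(mappings))) {
    abort("mappings needs columns read_id, region_id, mismatches",
          class = "mgmr_schema_error")
  }
  mappings$read_id <- as.character(mappings$read_id)
  mappings$region_id <- as.character(mappings$region_id)
  mappings$mismatches <- as.integer(mappings$mismatches)
  if (nrow(mappings) > 0L) {
    if (any(is.na(mappings$mismatches)) || any(mappings$mismatches < 0L) ||
        any(mappings$mismatches > max_mismatches)) {
      abort(sprintf("mismatch counts must lie in 0..%d", max_mismatches),
            class = "mgmr_invalid_input")
    }
    if (anyDuplicated(mappings[c("read_id", "region_id")])) {
      abort("duplicate (read, region) pairs; collapse to the best alignment",
            class = "mgmr_invalid_input")
    }
  }
  attr(mappings, "sample_id") <- sample_id
  attr(mappings, "n_unmapped") <- as.integer(n_unmapped)
  attr(mappings, "max_mismatches") <- as.integer(max_mismatches)
  class(mappings) <- c("mgmr_alignment_table", class(mappings))
  mappings
}

#' @rdname alignment_table
#' @param table An alignment table.
#' @export
n_unmapped <- function(table) {
  attr(table, "n_unmapped") %||% 0L
}

n_reads <- function(table) length(unique(table$read_id))

assert_alignment_table <- function(table) {
  if (!inherits(table, "mgmr_alignment_table")) {
    abort("expected an `mgmr_alignment_table` (see alignment_table())",
          class = "mgmr_invalid_input")
  }
  invisible(table)
}

#' Probability of a read given its source region
#'
#' Under the generative model, a read arises by picking a start position
#' uniformly among the region's effective positions and copying `read_length`
#' bases, each miscalled independently with probability `epsilon`. The
#' probability of observing a read with `mismatches` errors in its best
#' alignment to the region is
#' `(1 - epsilon)^(read_length - mismatches) * epsilon^mismatches /
#' effective_length`.
#'
#' @param mismatches Integer vector of mismatch counts in the best alignment.
#' @param read_length Read length in bp.
#' @param epsilon Per-base error rate in `[0, 1)`.
#' @param effective_length Effective length(s) of the region(s).
#' @return Numeric vector of probabilities.
#' @export
#' @examples
#' read_region_probability(0, 35, 0, 100) # 1/100
read_region_probability <- function(mismatches, read_length, epsilon,
                                    effective_length) {
  if (any(mismatches < 0) || any(mismatches > read_length)) {
    abort("mismatches must lie in 0..read_length", class = "mgmr_invalid_input")
  }
  if (epsilon < 0 || epsilon >= 1) {
    abort("epsilon must lie in [0, 1)", class = "mgmr_invalid_input")
  }
  if (any(effective_length < 1)) {
    abort("effective_length must be >= 1", class = "mgmr_invalid_region")
  }
  (1 - epsilon)^(read_length - mismatches) * epsilon^mismatches /
    effective_length
}

#' Attach read-given-region probabilities to an alignment table
#'
#' Populates the `q` column: for every stored (read, region) pair the
#' probability of the read given that region, via
#' [read_region_probability()]. Pairs not stored are implicitly zero. `q`
#' depends only on the alignments, the error rate and the effective lengths —
#' not on the expression proportions or the prior — so it is computed once
#' per sample and reused across all iterations.
#'
#' @param table An [alignment_table()].
#' @param regions The [region_set()] the reads were aligned to.
#' @param epsilon Per-base error rate.
#' @return The table with a strictly positive `q` column.
#' @export
build_q <- function(table, regions, epsilon = 0.01) {
  assert_alignment_table(table)
  assert_region_set(regions)
  idx <- match(table$region_id, regions$region_id)
  if (anyNA(idx)) {
    bad <- unique(table$region_id[is.na(idx)])
    abort(paste0("alignment table refers to unknown regions: ",
                 paste(head(bad, 5L), collapse = ", ")),
          class = "mgmr_schema_error")
  }
  q <- read_region_probability(
    table$mismatches, read_length(regions), epsilon,
    regions$effective_length[idx]
  )
  out <- table
  out$q <- q
  out
}
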