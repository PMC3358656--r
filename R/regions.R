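#' Construct a region set
#'
#' A region set holds the M reference sequences (genes, transcripts, or any
#' transcribed regions) over which expression is estimated, together with the
#' read length of the experiment. The *effective length* of a region is the
#' number of start positions from which a full-length read can be drawn,
#' `length - read_length + 1`.
#'
#' @param region_id Character vector of unique region identifiers.
#' @param length Integer vector of region lengths in bp (same order).
#' @param read_length Single integer, the read length of the experiment in bp.
#' @param sequence Optional character vector of region sequences (uppercase
#'   ACGT); when present, lengths are checked against `nchar(sequence)`.
#' @param group Optional vector labelling paralog-group membership (used by
#'   the simulator; `NA` for ungrouped regions).
#'
#' @return A tibble of class `mgmr_region_set` with columns `region_id`,
#'   `length`, `effective_length` and optionally `sequence` and `group`; the
#'   read length is carried as an attribute (see [read_length()]).
#' @export
#' @examples
#' region_set(c("gA", "gB"), c(100L, 120L), read_length = 35L)
region_set <- function(region_id, length, read_length, sequence = NULL,
                       group = NULL) {
  region_id <- as.character(region_id)
  length <- as.integer(length)
  read_length <- as.integer(read_length)
  if (length(region_id) < 1L) {
    abort("a region set needs at least one region", class = "mgmr_invalid_input")
  }
  if (anyDuplicated(region_id)) {
    abort("region ids must be unique", class = "mgmr_invalid_input")
  }
  if (length(read_length) != 1L || is.na(read_length) || read_length < 1L) {
    abort("read_length must be a single positive integer",
          class = "mgmr_invalid_input")
  }
  if (any(is.na(length)) || any(length < 1L)) {
    abort("region lengths must be positive integers",
          class = "mgmr_invalid_input")
  }
  if (!is.null(sequence)) {
    sequence <- toupper(as.character(sequence))
    if (length(sequence) != length(region_id)) {
      abort("sequence must match region_id in length",
            class = "mgmr_invalid_input")
    }
    if (any(nchar(sequence) != length)) {
      abort("sequence lengths disagree with declared region lengths",
            class = "mgmr_invalid_input")
    }
    if (any(grepl("[^ACGT]", sequence))) {
      abort("region sequences must contain only A, C, G, T",
            class = "mgmr_invalid_input")
    }
  }
  effective <- length - read_length + 1L
  if (any(effective < 1L)) {
    abort(
      paste0("regions shorter than the read length have no valid start ",
             "positions: ",
             paste(region_id[effective < 1L], collapse = ", ")),
      class = "mgmr_invalid_region"
    )
  }
  out <- tibble::tibble(
    region_id = region_id,
    length = length,
    effective_length = effective
  )
  if (!is.null(sequence)) out$sequence <- sequence
  if (!is.null(group)) out$group <- group
  attr(out, "read_length") <- read_length
  class(out) <- c("mgmr_region_set", class(out))
  out
}

#' Read length of a region set
#' @param regions A [region_set()].
#' @return The read length in bp.
#' @export
read_length <- function(regions) {
  attr(regions, "read_length")
}

n_regions <- function(regions) nrow(regions)

assert_region_set <- function(regions) {
  if (!inherits(regions, "mgmr_region_set")) {
    abort("expected an `mgmr_region_set` (see region_set())",
          class = "mgmr_invalid_input")
  }
  invisible(regions)
}
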