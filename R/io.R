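# File formats: read-to-region map files, expression matrices (TSV), FASTA.
#
# Map-file dialect (one sample per file): one read per line,
#   read_id<TAB>region:mismatches[,region:mismatches]*
# '#' starts a comment line; UTF-8; LF line endings. Mappings are written
# sorted by region id, reads in input order, so output is canonical and
# byte-stable.

#' Read a read-to-region map file
#'
#' @param path Path to a map file in the canonical dialect (see Details).
#' @param max_mismatches Acceptance bound; records whose every mapping
#'   exceeds it are dropped and counted.
#' @param sample_id Sample id to stamp on the table (default: file stem).
#' @return An [alignment_table()] (without `q`).
#' @details One read per line: `read_id<TAB>region:mismatches`, further
#'   mappings comma-separated; `#` introduces comments.
#' @export
read_map_file <- function(path, max_mismatches = 2L, sample_id = NULL) {
  if (!file.exists(path)) {
    abort(paste0("no such map file: ", path), class = "mgmr_io_error")
  }
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!any(keep)) {
    warn(paste0("map file is empty: ", path))
    return(alignment_table(
      tibble::tibble(read_id = character(), region_id = character(),
                     mismatches = integer()),
      sample_id = sample_id %||% sub("\\.[^.]*$", "", basename(path)),
      max_mismatches = max_mismatches
    ))
  }
  line_no <- which(keep)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad) > 0L) {
    abort(sprintf("malformed map line %d in %s (expected read<TAB>mappings)",
                  line_no[bad[1L]], path), class = "mgmr_parse_error")
  }
  read_id <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(read_id)) {
    abort(sprintf("duplicate read id '%s' in %s",
                  read_id[duplicated(read_id)][1L], path),
          class = "mgmr_parse_error")
  }
  maps <- strsplit(vapply(parts, `[[`, character(1), 2L), ",", fixed = TRUE)
  n_map <- lengths(maps)
  flat <- unlist(maps, use.names = FALSE)
  m <- regmatches(flat, regexec("^([^:]+):([0-9]+)$", flat))
  ok <- lengths(m) == 3L
  if (!all(ok)) {
    bad_line <- line_no[rep(seq_along(maps), n_map)][!ok][1L]
    abort(sprintf("malformed mapping '%s' on line %d of %s",
                  flat[!ok][1L], bad_line, path),
          class = "mgmr_parse_error")
  }
  mappings <- tibble::tibble(
    read_id = rep(read_id, n_map),
    region_id = vapply(m, `[[`, character(1), 2L),
    mismatches = as.integer(vapply(m, `[[`, character(1), 3L))
  )
  over <- mappings$mismatches > max_mismatches
  dropped_reads <- 0L
  if (any(over)) {
    kept <- mappings[!over, ]
    dropped_reads <- length(setdiff(mappings$read_id, kept$read_id))
    if (dropped_reads > 0L) {
      mgmr_log("info", sprintf(
        "%d read(s) in %s dropped: all mappings exceed %d mismatches",
        dropped_reads, basename(path), max_mismatches))
    }
    mappings <- kept
  }
  alignment_table(mappings,
                  sample_id = sample_id %||% sub("\\.[^.]*$", "",
                                                 basename(path)),
                  n_unmapped = dropped_reads,
                  max_mismatches = max_mismatches)
}

#' Write a read-to-region map file
#'
#' Canonical, deterministic output: reads in table order, mappings sorted
#' by region id, LF endings.
#'
#' @param table An [alignment_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_map_file <- function(table, path) {
  assert_alignment_table(table)
  if (nrow(table) == 0L) {
    writeLines(character(), path, sep = "")
    return(invisible(path))
  }
  ord <- order(match(table$read_id, unique(table$read_id)), table$region_id)
  tb <- table[ord, ]
  mapping <- paste0(tb$region_id, ":", tb$mismatches)
  lines <- vapply(split(mapping, factor(tb$read_id, levels = unique(tb$read_id))),
                  paste, character(1), collapse = ",")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste0(unique(tb$read_id), "\t", lines), con, sep = "\n")
  invisible(path)
}

#' Read / write an expression matrix as TSV
#'
#' The TSV has a header `sample_id` followed by the region ids, then one
#' row per sample. The reader validates that every row sums to 1; rows off
#' by more than `1e-8` are renormalized, with a warning when the deviation
#' exceeds `1e-4`. The writer emits full double precision.
#'
#' @param path File path.
#' @return The reader returns an `mgmr_expression` tibble; the writer
#'   returns `path` invisibly.
#' @export
read_expression_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (names(df)[1L] != "sample_id") {
    abort("expression TSV must start with a sample_id column",
          class = "mgmr_parse_error")
  }
  vals <- df[-1L]
  if (!all(vapply(vals, is.numeric, logical(1)))) {
    abort("non-numeric expression values", class = "mgmr_parse_error")
  }
  m <- as.matrix(vals)
  rownames(m) <- as.character(df$sample_id)
  expression_matrix(m, renormalize = TRUE)
}

#' @rdname read_expression_matrix
#' @param matrix An `mgmr_expression` tibble (or numeric matrix with
#'   dimnames).
#' @export
write_expression_matrix <- function(matrix, path) {
  m <- if (is.data.frame(matrix)) as_expression_values(matrix) else matrix
  df <- tibble::as_tibble(as.data.frame(m))
  df <- tibble::add_column(df, sample_id = rownames(m), .before = 1L)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read reference regions from FASTA
#'
#' Region ids are the first whitespace-delimited token of each header.
#' Sequences are uppercased; records containing characters outside ACGT are
#' rejected (the simulator's substitution model is defined on ACGT only).
#' Records shorter than the read length have no valid start positions and
#' are excluded with a warning.
#'
#' @param path FASTA path.
#' @param read_length Read length in bp used to derive effective lengths.
#' @return A [region_set()] with sequences.
#' @export
read_fasta_regions <- function(path, read_length) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("the Biostrings package is required to read FASTA",
          class = "mgmr_io_error")
  }
  ss <- Biostrings::readDNAStringSet(path)
  ids <- vapply(strsplit(names(ss), "\\s+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    abort("duplicate FASTA record ids", class = "mgmr_parse_error")
  }
  seqs <- toupper(as.character(ss))
  if (any(grepl("[^ACGT]", seqs))) {
    abort("FASTA contains characters outside ACGT",
          class = "mgmr_parse_error")
  }
  too_short <- nchar(seqs) < read_length
  if (any(too_short)) {
    warn(sprintf("excluded %d region(s) shorter than the read length (%d bp)",
                 sum(too_short), read_length))
    ids <- ids[!too_short]
    seqs <- seqs[!too_short]
  }
  region_set(ids, nchar(seqs), read_length = read_length, sequence = seqs)
}

#' @rdname read_fasta_regions
#' @param regions A [region_set()] with sequences.
#' @export
write_fasta_regions <- function(regions, path) {
  assert_region_set(regions)
  if (is.null(regions$sequence)) {
    abort("region set has no sequences to write", class = "mgmr_io_error")
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste0(">", regions$region_id, "\n", regions$sequence),
             con, sep = "\n")
  invisible(path)
}

#' Write simulated reads as FASTA (origin in the header, for debugging)
#'
#' @param reads Tibble from [simulate_reads()].
#' @param path Output path.
#' @export
write_fasta_reads <- function(reads, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste0(">", reads$read_id, " origin=", reads$true_region,
                    " start=", reads$true_start, "\n", reads$sequence),
             con, sep = "\n")
  invisible(path)
}
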