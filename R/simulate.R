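# Read simulator: paralogous region sets, Dirichlet-distributed population
# expression, uniform start sites, independent per-base substitution errors,
# and exhaustive mismatch-bounded mapping back to the regions.

BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

# substitute each position independently with probability `rate`, drawing
# uniformly among the three alternative bases
mutate_sequence <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(chars)) < rate)
  if (length(hit) > 0L) {
    chars[hit] <- vapply(chars[hit], function(b) {
      sample(setdiff(BASES, b), 1L)
    }, character(1), USE.NAMES = FALSE)
  }
  paste(chars, collapse = "")
}

#' Simulate a region set containing paralog families
#'
#' Builds reference sequences in which members of a paralog group descend
#' from a common ancestor by independent substitutions at the given rate,
#' producing the sequence similarity that makes reads multimap; ungrouped
#' regions are independent uniform-random sequences. Stands in for curated
#' paralog families (e.g. HomoloGene-derived sets) so the estimator can be
#' exercised without external data.
#'
#' @param n_regions Total number of regions M.
#' @param length Region length in bp; must be at least twice the read
#'   length so full-length reads can always be sampled.
#' @param read_length Read length in bp (default 35).
#' @param paralog_groups Integer vector of group sizes (e.g. `c(4, 3, 3)`);
#'   must sum to at most `n_regions`. Remaining regions are unrelated.
#' @param divergence Per-site substitution rate applied independently to
#'   each group member relative to the ancestor. Two members then differ at
#'   a fraction `1 - ((1-d)^2 + d^2/3)` of sites in expectation.
#' @param seed Optional integer seed.
#' @return A [region_set()] with `sequence` and `group` columns.
#' @export
make_region_set <- function(n_regions, length, read_length = 35L,
                            paralog_groups = integer(), divergence = 0.02,
                            seed = NULL) {
  if (length < 2L * read_length) {
    abort("regions must be at least twice the read length",
          class = "mgmr_invalid_config")
  }
  if (sum(paralog_groups) > n_regions) {
    abort("paralog group sizes exceed n_regions", class = "mgmr_invalid_config")
  }
  if (!is.null(seed)) set.seed(seed)
  group <- rep(NA_integer_, n_regions)
  pos <- 1L
  for (gi in seq_along(paralog_groups)) {
    group[pos:(pos + paralog_groups[gi] - 1L)] <- gi
    pos <- pos + paralog_groups[gi]
  }
  sequences <- character(n_regions)
  for (gi in seq_along(paralog_groups)) {
    ancestor <- random_dna(length)
    members <- which(group == gi)
    sequences[members] <- vapply(members, function(i) {
      mutate_sequence(ancestor, divergence)
    }, character(1))
  }
  loners <- which(is.na(group))
  sequences[loners] <- vapply(loners, function(i) random_dna(length),
                              character(1))
  region_set(
    region_id = sprintf("region%02d", seq_len(n_regions)),
    length = rep(as.integer(length), n_regions),
    read_length = read_length,
    sequence = sequences,
    group = group
  )
}

#' Draw per-sample expression vectors from a population Dirichlet
#'
#' Each sample's expression proportions are an independent draw from
#' `Dirichlet(alpha)` (via normalized gamma variates).
#'
#' @param alpha Positive hyperparameter vector, named by region id (or
#'   supply `region_ids`).
#' @param n_samples Number of samples N.
#' @param region_ids Region ids; defaults to `names(alpha)`.
#' @param seed Optional integer seed.
#' @return An `mgmr_expression` tibble with N rows.
#' @export
sample_population_expression <- function(alpha, n_samples,
                                         region_ids = names(alpha),
                                         seed = NULL) {
  if (any(alpha <= 0) || any(!is.finite(alpha))) {
    abort("alpha must be strictly positive and finite",
          class = "mgmr_invalid_input")
  }
  if (n_samples < 1L) {
    abort("n_samples must be >= 1", class = "mgmr_invalid_config")
  }
  if (!is.null(seed)) set.seed(seed)
  region_ids <- region_ids %||% sprintf("region%02d", seq_along(alpha))
  g <- matrix(rgamma(n_samples * length(alpha), shape = rep(alpha,
                     each = n_samples)), nrow = n_samples)
  p <- g / rowSums(g)
  colnames(p) <- region_ids
  rownames(p) <- sprintf("sample%03d", seq_len(n_samples))
  expression_matrix(p, renormalize = TRUE)
}

#' Simulate error-bearing reads from one sample's expression profile
#'
#' For each read, a source region is drawn from the expression proportions,
#' a start position uniformly among the region's effective positions, and
#' `read_length` bases are copied; each base is then independently
#' substituted with probability `epsilon` (uniformly among the three
#' alternatives). The read count is `round(coverage * sum(lengths) /
#' read_length)` unless `n_reads` is given.
#'
#' @param regions A [region_set()] with sequences.
#' @param p_row Expression proportion vector for the sample (named by
#'   region id or ordered as `regions`).
#' @param coverage Mean read bases per region base (ignored if `n_reads`
#'   is given).
#' @param n_reads Explicit read count (overrides `coverage`).
#' @param epsilon Per-base substitution error rate.
#' @param length_weighting Weight region choice by `p * effective_length`
#'   instead of `p` alone, for the interpretation of expression as base
#'   proportions rather than molecule proportions.
#' @param seed Optional integer seed.
#' @return A tibble `read_id`, `sequence`, `true_region`, `true_start`
#'   (0-based start within the region).
#' @export
simulate_reads <- function(regions, p_row, coverage = 20, n_reads = NULL,
                           epsilon = 0.01, length_weighting = FALSE,
                           seed = NULL) {
  assert_region_set(regions)
  if (is.null(regions$sequence)) {
    abort("region set has no sequences to sample reads from",
          class = "mgmr_invalid_input")
  }
  if (!is.null(seed)) set.seed(seed)
  len <- read_length(regions)
  p <- as.numeric(p_row)
  if (!is.null(names(p_row))) p <- p[match(regions$region_id, names(p_row))]
  w <- if (length_weighting) p * regions$effective_length else p
  w <- w / sum(w)
  rho <- n_reads %||% round(coverage * sum(regions$length) / len)
  origin <- sample.int(n_regions(regions), rho, replace = TRUE, prob = w)
  start <- vapply(origin, function(k) {
    sample.int(regions$effective_length[k], 1L) - 1L
  }, integer(1))
  seqs <- substr(regions$sequence[origin], start + 1L, start + len)
  if (epsilon > 0) {
    seqs <- vapply(seqs, mutate_sequence, character(1), rate = epsilon,
                   USE.NAMES = FALSE)
  }
  tibble::tibble(
    read_id = sprintf("read%06d", seq_len(rho)),
    sequence = seqs,
    true_region = regions$region_id[origin],
    true_start = as.integer(start)
  )
}

#' Map reads to regions by exhaustive mismatch-bounded scanning
#'
#' Every read is compared against every start position of every region; the
#' minimum Hamming mismatch count per (read, region) pair is recorded when
#' it does not exceed `max_mismatches` (the best-match-position convention).
#' Reads with no accepted alignment are dropped and counted (see
#' [n_unmapped()]). The scan is exact under the substitution-only error
#' model, so no external aligner is involved.
#'
#' @param reads Tibble with `read_id` and `sequence` (as produced by
#'   [simulate_reads()]), or a character vector of sequences.
#' @param regions A [region_set()] with sequences.
#' @param max_mismatches Acceptance bound on mismatches (default 2).
#' @param sample_id Optional sample id to stamp on the table.
#' @return An [alignment_table()] (without `q`).
#' @export
map_reads <- function(reads, regions, max_mismatches = 2L, sample_id = NULL) {
  assert_region_set(regions)
  if (is.character(reads)) {
    reads <- tibble::tibble(read_id = sprintf("read%06d", seq_along(reads)),
                            sequence = reads)
  }
  if (is.null(regions$sequence)) {
    abort("region set has no sequences to map against",
          class = "mgmr_invalid_input")
  }
  hits <- hamming_scan_cpp(reads$sequence, regions$sequence,
                           as.integer(max_mismatches))
  mapped_reads <- unique(hits$read)
  n_drop <- nrow(reads) - length(mapped_reads)
  if (n_drop > 0L) {
    mgmr_log("info", sprintf("%d read(s) had no alignment within %d mismatches",
                             n_drop, max_mismatches))
  }
  alignment_table(
    tibble::tibble(
      read_id = reads$read_id[hits$read],
      region_id = regions$region_id[hits$region],
      mismatches = hits$mismatches
    ),
    sample_id = sample_id,
    n_unmapped = n_drop,
    max_mismatches = max_mismatches
  )
}

#' Preset study designs for the simulator
#'
#' `"gene-level"` mirrors a short-read gene-level design (35 bp reads,
#' coverage 20, 20 samples, 30 repetitions); `"transcript-level"` a
#' longer-read transcript-level design (100 bp reads, coverage 20, 74
#' samples, 30 repetitions).
#'
#' @param name Preset name.
#' @return A named list of simulation settings.
#' @export
sim_preset <- function(name = c("gene-level", "transcript-level")) {
  name <- match.arg(name)
  switch(name,
    "gene-level" = list(read_length = 35L, coverage = 20, n_samples = 20L,
                        n_repetitions = 30L, epsilon = 0.01,
                        max_mismatches = 2L),
    "transcript-level" = list(read_length = 100L, coverage = 20,
                              n_samples = 74L, n_repetitions = 30L,
                              epsilon = 0.01, max_mismatches = 2L)
  )
}

#' Simulate a full population experiment
#'
#' Draws (or accepts) a ground-truth expression matrix, then for every
#' repetition and sample simulates reads and maps them back to the regions,
#' yielding everything the estimators and the error measures need. The
#' truth is drawn once and shared across repetitions; reads are re-simulated
#' per repetition. Fully deterministic given `seed`.
#'
#' @param regions A [region_set()] with sequences (e.g. from
#'   [make_region_set()]).
#' @param n_samples Number of samples N (ignored when `truth` is supplied).
#' @param true_alpha Population Dirichlet hyperparameters used to draw the
#'   truth (ignored when `truth` is supplied).
#' @param truth Optional explicit truth `mgmr_expression` tibble.
#' @param coverage,epsilon,max_mismatches,length_weighting Passed to
#'   [simulate_reads()] / [map_reads()].
#' @param n_repetitions Independent read-simulation repetitions.
#' @param seed Integer seed (required: the experiment must be reproducible).
#' @return An object of class `mgmr_simulation`: list with `regions`,
#'   `truth`, `tables` (list over repetitions of lists over samples of
#'   alignment tables), `origins` (per repetition/sample read-origin
#'   tibbles) and `config`.
#' @export
simulate_experiment <- function(regions, n_samples = 20L,
                                true_alpha = NULL, truth = NULL,
                                coverage = 20, epsilon = 0.01,
                                max_mismatches = 2L,
                                length_weighting = FALSE,
                                n_repetitions = 1L, seed) {
  assert_region_set(regions)
  if (missing(seed) || is.null(seed)) {
    abort("a seed is required for a reproducible experiment",
          class = "mgmr_invalid_config")
  }
  set.seed(seed)
  if (is.null(truth)) {
    if (is.null(true_alpha)) {
      abort("supply true_alpha or an explicit truth matrix",
            class = "mgmr_invalid_config")
    }
    truth <- sample_population_expression(true_alpha, n_samples,
                                          region_ids = regions$region_id)
  } else {
    assert_expression(truth, regions$region_id)
    n_samples <- nrow(truth)
  }
  truth_vals <- as_expression_values(truth)
  tables <- vector("list", n_repetitions)
  origins <- vector("list", n_repetitions)
  for (rep_i in seq_len(n_repetitions)) {
    tables[[rep_i]] <- vector("list", n_samples)
    origins[[rep_i]] <- vector("list", n_samples)
    for (i in seq_len(n_samples)) {
      reads <- simulate_reads(regions, truth_vals[i, ], coverage = coverage,
                              epsilon = epsilon,
                              length_weighting = length_weighting)
      tables[[rep_i]][[i]] <- map_reads(reads, regions,
                                        max_mismatches = max_mismatches,
                                        sample_id = truth$sample_id[i])
      origins[[rep_i]][[i]] <- reads[c("read_id", "true_region", "true_start")]
    }
  }
  structure(
    list(regions = regions, truth = truth, tables = tables,
         origins = origins,
         config = list(n_samples = n_samples, coverage = coverage,
                       epsilon = epsilon, max_mismatches = max_mismatches,
                       length_weighting = length_weighting,
                       n_repetitions = n_repetitions, seed = seed)),
    class = "mgmr_simulation"
  )
}

#' @export
print.mgmr_simulation <- function(x, ...) {
  cat(sprintf(
    "<mgmr_simulation> %d sample(s) x %d repetition(s), %d region(s)\n",
    x$config$n_samples, x$config$n_repetitions, n_regions(x$regions)))
  invisible(x)
}
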