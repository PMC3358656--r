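# Independent oracles and small fixture builders. Everything here is
# deliberately naive (loops, substr comparisons, grid search) so it cannot
# share a defect with the vectorized / compiled implementation paths.

toy_regions <- function(ids, lengths, read_length, sequences = NULL) {
  region_set(ids, lengths, read_length = read_length, sequence = sequences)
}

toy_table <- function(read_id, region_id, mismatches, ...) {
  alignment_table(tibble::tibble(read_id = read_id, region_id = region_id,
                                 mismatches = as.integer(mismatches)), ...)
}

# brute-force read mapper: position-by-position substring comparison
brute_force_map <- function(read_seqs, region_seqs, max_mismatches = 2L) {
  out <- list()
  for (j in seq_along(read_seqs)) {
    rd <- strsplit(read_seqs[[j]], "")[[1]]
    for (k in seq_along(region_seqs)) {
      g <- strsplit(region_seqs[[k]], "")[[1]]
      n_pos <- length(g) - length(rd) + 1L
      if (n_pos < 1L) next
      best <- Inf
      for (s in seq_len(n_pos)) {
        mm <- sum(rd != g[s:(s + length(rd) - 1L)])
        if (mm < best) best <- mm
      }
      if (best <= max_mismatches) {
        out[[length(out) + 1L]] <- data.frame(read = j, region = k,
                                              mismatches = best)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(read = integer(), region = integer(),
                      mismatches = integer()))
  }
  do.call(rbind, out)
}

# dense grid search over P1 for a two-region single-sample likelihood
grid_search_em2 <- function(table, region_ids, resolution = 1e-4) {
  stopifnot(length(region_ids) == 2L)
  reads <- split(seq_len(nrow(table)), table$read_id)
  loglik <- function(p1) {
    p <- c(p1, 1 - p1)
    names(p) <- region_ids
    total <- 0
    for (rows in reads) {
      total <- total +
        log(sum(p[table$region_id[rows]] * table$q[rows]))
    }
    total
  }
  grid <- seq(resolution, 1 - resolution, by = resolution)
  vals <- vapply(grid, loglik, numeric(1))
  grid[which.max(vals)]
}

# independent digamma inversion by root bracketing (no Newton, no shared code)
uniroot_digamma_inverse <- function(y) {
  stats::uniroot(function(x) digamma(x) - y, lower = 1e-12, upper = 1e6,
                 tol = 1e-14)$root
}

# random small alignment instance for property tests: returns a list of
# per-sample tables with q attached, plus the region set
random_instance <- function(seed, n_samples = NULL, n_regions = NULL,
                            n_reads = NULL) {
  set.seed(seed)
  m <- n_regions %||% sample(2:4, 1)
  n <- n_samples %||% sample(2:4, 1)
  region_ids <- paste0("g", seq_len(m))
  regions <- region_set(region_ids, sample(50:120, m, replace = TRUE),
                        read_length = 20L)
  tables <- lapply(seq_len(n), function(i) {
    rho <- n_reads %||% sample(3:8, 1)
    rows <- do.call(rbind, lapply(seq_len(rho), function(j) {
      hits <- sample(m, sample(seq_len(min(m, 3)), 1))
      data.frame(read_id = paste0("r", j), region_id = region_ids[hits],
                 mismatches = sample(0:2, length(hits), replace = TRUE))
    }))
    build_q(alignment_table(rows, sample_id = paste0("s", i)), regions,
            epsilon = 0.01)
  })
  list(regions = regions, tables = tables, region_ids = region_ids,
       n_samples = n, n_regions = m)
}

# uniform random probability matrix with rows summing to 1
random_p_matrix <- function(n, m, region_ids = paste0("g", seq_len(m))) {
  x <- matrix(stats::rexp(n * m), nrow = n)
  x <- x / rowSums(x)
  colnames(x) <- region_ids
  rownames(x) <- paste0("s", seq_len(n))
  x
}
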