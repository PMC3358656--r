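# The synthetic population generator: paralog families, Dirichlet expression,
# error-bearing reads, and exhaustive mismatch-bounded mapping.

test_that("paralog groups control sequence identity", {
  # divergence 0: group members are identical
  rs0 <- make_region_set(2, 120, read_length = 20L, paralog_groups = 2,
                         divergence = 0, seed = 11)
  expect_identical(rs0$sequence[1], rs0$sequence[2])
  # expected pairwise identity under the substitution model:
  # (1-d)^2 + d^2/3 per site
  d <- 0.02
  rs <- make_region_set(3, 300, read_length = 35L, paralog_groups = 3,
                        divergence = d, seed = 12)
  ident <- function(a, b) {
    mean(strsplit(a, "")[[1]] == strsplit(b, "")[[1]])
  }
  expected <- (1 - d)^2 + d^2 / 3
  sigma <- sqrt(expected * (1 - expected) / 300)
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    expect_lt(abs(ident(rs$sequence[pair[1]], rs$sequence[pair[2]]) -
                    expected), 5 * sigma)
  }
  # full divergence looks like unrelated sequence (~25% identity)
  rs1 <- make_region_set(2, 300, read_length = 20L, paralog_groups = 2,
                         divergence = 1, seed = 13)
  expect_lt(ident(rs1$sequence[1], rs1$sequence[2]), 0.45)
  # region length must allow full-length reads from both halves
  expect_error(make_region_set(2, 30, read_length = 20L),
               class = "mgmr_invalid_config")
})

test_that("population expression draws have Dirichlet structure", {
  # concentration limit: huge symmetric alpha pins rows near uniform
  big <- sample_population_expression(rep(1e6, 4), 5, seed = 21)
  expect_true(all(abs(as_expression_values(big) - 0.25) < 1e-2))
  # Beta(1,1) marginal at M = 2, alpha = (1,1)
  flat <- sample_population_expression(c(1, 1), 2000, seed = 22)
  ks <- stats::ks.test(as_expression_values(flat)[, 1], "punif")
  expect_gt(ks$p.value, 0.01)
  # empirical mean ~ alpha / sum(alpha)
  alpha <- c(5, 1, 2)
  draws <- sample_population_expression(alpha, 2000, seed = 23)
  m <- colMeans(as_expression_values(draws))
  target <- alpha / sum(alpha)
  se <- sqrt(target * (1 - target) / (sum(alpha) + 1) / 2000)
  expect_true(all(abs(m - target) < 3 * se))
  # rows sum to one
  expect_true(all(abs(rowSums(as_expression_values(draws)) - 1) < 1e-8))
})

test_that("simulated reads follow the generative model", {
  regions <- make_region_set(3, 200, read_length = 25L, seed = 31)
  # with no errors every read is an exact substring of its origin
  reads0 <- simulate_reads(regions, c(0.3, 0.3, 0.4), n_reads = 200,
                           epsilon = 0, seed = 32)
  for (i in seq_len(50)) {
    origin_seq <- regions$sequence[regions$region_id == reads0$true_region[i]]
    expect_identical(
      substr(origin_seq, reads0$true_start[i] + 1, reads0$true_start[i] + 25),
      reads0$sequence[i])
  }
  expect_true(all(reads0$true_start >= 0))
  expect_true(all(reads0$true_start < regions$effective_length[
    match(reads0$true_region, regions$region_id)]))
  # a degenerate profile puts every read on the expressed region
  reads1 <- simulate_reads(regions, c(1, 0, 0), n_reads = 100, seed = 33)
  expect_true(all(reads1$true_region == "region01"))
  # mean mismatch count vs the origin window matches Binomial(l, epsilon)
  reads2 <- simulate_reads(regions, c(0.3, 0.3, 0.4), n_reads = 3000,
                           epsilon = 0.01, seed = 34)
  mm <- vapply(seq_len(nrow(reads2)), function(i) {
    origin_seq <- regions$sequence[regions$region_id == reads2$true_region[i]]
    window <- substr(origin_seq, reads2$true_start[i] + 1,
                     reads2$true_start[i] + 25)
    sum(strsplit(window, "")[[1]] != strsplit(reads2$sequence[i], "")[[1]])
  }, numeric(1))
  expected <- 25 * 0.01
  se <- sqrt(25 * 0.01 * 0.99 / 3000)
  expect_lt(abs(mean(mm) - expected), 4 * se)
  # coverage sets the read count: round(coverage * total bp / read length)
  reads3 <- simulate_reads(regions, c(0.3, 0.3, 0.4), coverage = 5, seed = 35)
  expect_equal(nrow(reads3), round(5 * 600 / 25))
})

test_that("read origins follow the expression weights", {
  regions <- make_region_set(4, 150, read_length = 20L, seed = 41)
  p <- c(0.4, 0.3, 0.2, 0.1)
  reads <- simulate_reads(regions, p, n_reads = 5000, epsilon = 0, seed = 42)
  counts <- table(factor(reads$true_region, levels = regions$region_id))
  gof <- stats::chisq.test(as.numeric(counts), p = p)
  expect_gt(gof$p.value, 0.001)
})

test_that("map_reads agrees with the brute-force oracle", {
  for (seed in 1:4) {
    regions <- make_region_set(4, 60, read_length = 20L,
                               paralog_groups = c(2, 2), divergence = 0.05,
                               seed = seed)
    reads <- simulate_reads(regions, rep(0.25, 4), n_reads = 15,
                            epsilon = 0.05, seed = seed + 100)
    got <- map_reads(reads, regions)
    want <- brute_force_map(reads$sequence, regions$sequence, 2L)
    got_df <- data.frame(
      read = match(got$read_id, reads$read_id),
      region = match(got$region_id, regions$region_id),
      mismatches = got$mismatches
    )
    got_df <- got_df[order(got_df$read, got_df$region), ]
    want <- want[order(want$read, want$region), ]
    rownames(got_df) <- rownames(want) <- NULL
    expect_equal(got_df, want)
    expect_equal(n_unmapped(got),
                 nrow(reads) - length(unique(want$read)))
  }
})

test_that("identical regions make mapping the group-membership relation", {
  regions <- make_region_set(2, 100, read_length = 20L, paralog_groups = 2,
                             divergence = 0, seed = 51)
  reads <- simulate_reads(regions, c(0.5, 0.5), n_reads = 40, epsilon = 0,
                          seed = 52)
  tab <- map_reads(reads, regions)
  per_read <- table(tab$read_id)
  expect_true(all(per_read == 2)) # every read maps to both copies
  mm <- tapply(tab$mismatches, tab$read_id, function(x) length(unique(x)))
  expect_true(all(mm == 1)) # with identical mismatch counts
})

test_that("a full experiment is deterministic given its seed", {
  regions <- make_region_set(4, 120, read_length = 20L,
                             paralog_groups = c(2, 2), divergence = 0.03,
                             seed = 61)
  sim1 <- simulate_experiment(regions, n_samples = 3, true_alpha = rep(2, 4),
                              coverage = 3, n_repetitions = 2, seed = 62)
  sim2 <- simulate_experiment(regions, n_samples = 3, true_alpha = rep(2, 4),
                              coverage = 3, n_repetitions = 2, seed = 62)
  expect_equal(sim1$truth, sim2$truth)
  expect_identical(
    lapply(sim1$tables, function(r) lapply(r, as.data.frame)),
    lapply(sim2$tables, function(r) lapply(r, as.data.frame)))
  # single sample, single region: truth is the unit vector
  one <- make_region_set(1, 100, read_length = 20L, seed = 63)
  sim3 <- simulate_experiment(one, n_samples = 1, true_alpha = 5,
                              coverage = 2, seed = 64)
  expect_equal(as_expression_values(sim3$truth)[1, 1], 1)
  # a seed is mandatory
  expect_error(simulate_experiment(one, n_samples = 1, true_alpha = 5),
               class = "mgmr_invalid_config")
})
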