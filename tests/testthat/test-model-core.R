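# The generative-model quantities: read-given-region probabilities, the
# sparse q table, responsibilities, and the M-step updates.

test_that("read-given-region probability matches the closed form", {
  # error-free read, no mismatches: 1 / effective length
  expect_equal(read_region_probability(0, 35, 0, 100), 0.01)
  # direct evaluation of the closed form at epsilon > 0
  expect_equal(read_region_probability(1, 35, 0.01, 100),
               0.99^34 * 0.01 / 100, tolerance = 1e-14)
  expect_equal(read_region_probability(0, 35, 0.01, 1), 0.99^35,
               tolerance = 1e-14)
  # strictly positive whenever epsilon > 0
  expect_gt(read_region_probability(2, 35, 0.01, 500), 0)
})

test_that("invalid probability inputs are rejected", {
  expect_error(read_region_probability(36, 35, 0.01, 100),
               class = "mgmr_invalid_input")
  expect_error(read_region_probability(0, 35, 1, 100),
               class = "mgmr_invalid_input")
  expect_error(read_region_probability(0, 35, 0.01, 0),
               class = "mgmr_invalid_region")
})

test_that("build_q populates q for every stored pair", {
  regions <- toy_regions(c("gA", "gB"), c(59L, 59L), read_length = 10L)
  # effective length 50; one read, one region, no mismatches, epsilon 0
  tab <- toy_table("r1", "gA", 0)
  expect_equal(build_q(tab, regions, epsilon = 0)$q, 0.02)
  # symmetry: equal effective lengths and mismatches give equal q
  tab2 <- toy_table(c("r1", "r1"), c("gA", "gB"), c(1, 1))
  q2 <- build_q(tab2, regions, epsilon = 0.01)$q
  expect_equal(q2[1], q2[2])
  # element-wise oracle on a mixed table
  tab3 <- toy_table(c("r1", "r1", "r2", "r3"), c("gA", "gB", "gB", "gA"),
                    c(0, 2, 1, 0))
  got <- build_q(tab3, regions, epsilon = 0.02)$q
  want <- c(0.98^10 / 50,
            0.98^8 * 0.02^2 / 50,
            0.98^9 * 0.02 / 50,
            0.98^10 / 50)
  expect_equal(got, want, tolerance = 1e-14)
  # unknown region id is a schema error
  expect_error(build_q(toy_table("r1", "gZ", 0), regions),
               class = "mgmr_schema_error")
})

test_that("responsibilities are posterior read-origin probabilities", {
  regions <- toy_regions(c("gA", "gB"), c(59L, 59L), read_length = 10L)
  # uniquely mapped read gets responsibility 1
  tab <- build_q(toy_table("r1", "gA", 0), regions, 0.01)
  r <- responsibilities(c(gA = 0.3, gB = 0.7), tab)
  expect_equal(r$responsibility, 1)
  # equal P and equal q split evenly
  tab2 <- build_q(toy_table(c("r1", "r1"), c("gA", "gB"), c(0, 0)),
                  regions, 0.01)
  r2 <- responsibilities(c(gA = 0.5, gB = 0.5), tab2)
  expect_equal(r2$responsibility, c(0.5, 0.5))
  # hand evaluation: equal q, P = (0.8, 0.2) -> a = (0.8, 0.2)
  r3 <- responsibilities(c(gA = 0.8, gB = 0.2), tab2)
  expect_equal(r3$responsibility, c(0.8, 0.2), tolerance = 1e-12)
})

test_that("responsibilities sum to one per read on random instances", {
  for (seed in 1:10) {
    inst <- random_instance(seed)
    for (tab in inst$tables) {
      p <- random_p_matrix(1, inst$n_regions, inst$region_ids)[1, ]
      r <- responsibilities(p, tab)
      sums <- tapply(r$responsibility, r$read_id, sum)
      expect_true(all(abs(sums - 1) < 1e-12))
    }
  }
})

test_that("p_update combines counts with prior pseudo-counts", {
  # shifted formula, hand evaluation
  expect_equal(p_update(c(3, 1), c(1, 1), shift = TRUE), c(4, 2) / 6)
  # all-zero sums with unit alpha: uniform
  expect_equal(p_update(c(0, 0, 0), c(1, 1, 1), shift = TRUE), rep(1 / 3, 3))
  # literal stationary point, symmetric case
  expect_equal(p_update(c(0, 0), c(2, 2), shift = FALSE), c(0.5, 0.5))
  # negative numerator without the shift is an explicit error
  expect_error(p_update(c(0, 5), c(0.5, 1), shift = FALSE),
               class = "mgmr_negative_probability")
  # output is always a probability vector
  out <- p_update(c(2.3, 0.1, 4.4), c(0.7, 1.9, 3.1))
  expect_equal(sum(out), 1, tolerance = 1e-12)
})

test_that("log_mean_log_p averages logs across samples", {
  m <- matrix(0.25, nrow = 3, ncol = 4,
              dimnames = list(paste0("s", 1:3), paste0("g", 1:4)))
  expect_equal(log_mean_log_p(m), setNames(rep(log(0.25), 4), paste0("g", 1:4)),
               ignore_attr = TRUE)
  one <- matrix(c(0.9, 0.1), nrow = 1)
  expect_equal(log_mean_log_p(one), log(c(0.9, 0.1)))
  two <- rbind(c(0.9, 0.1), c(0.5, 0.5))
  expect_equal(log_mean_log_p(two),
               c(mean(log(c(0.9, 0.5))), mean(log(c(0.1, 0.5)))))
  expect_error(log_mean_log_p(rbind(c(0, 1))), class = "mgmr_domain_error")
})

test_that("penalized log-likelihood matches independent term-by-term sums", {
  regions <- toy_regions(c("gA", "gB"), c(59L, 59L), read_length = 10L)
  t1 <- build_q(toy_table(c("r1", "r1", "r2"), c("gA", "gB", "gA"),
                          c(0, 1, 0)), regions, 0.01)
  t2 <- build_q(toy_table(c("r1", "r2", "r2"), c("gB", "gA", "gB"),
                          c(0, 2, 0)), regions, 0.01)
  P <- rbind(c(0.7, 0.3), c(0.4, 0.6))
  colnames(P) <- c("gA", "gB")
  alpha <- c(1.5, 2.5)

  # independent evaluation, spelled out term by term
  q <- function(mm) 0.99^(10 - mm) * 0.01^mm / 50
  read_term <- log(0.7 * q(0) + 0.3 * q(1)) + log(0.7 * q(0)) + # sample 1
    log(0.6 * q(0)) + log(0.4 * q(2) + 0.6 * q(0))              # sample 2
  prior_term <- (alpha[1] - 1) * (log(0.7) + log(0.4)) +
    (alpha[2] - 1) * (log(0.3) + log(0.6))
  log_c <- lgamma(sum(alpha)) - lgamma(alpha[1]) - lgamma(alpha[2])
  want <- 2 * log_c + prior_term + read_term

  expect_equal(penalized_log_likelihood(P, alpha, list(t1, t2)), want,
               tolerance = 1e-12)
})

test_that("unit alpha collapses the prior term of the likelihood", {
  regions <- toy_regions(c("gA", "gB", "gC"), c(59L, 59L, 59L),
                         read_length = 10L)
  tab <- build_q(toy_table(c("r1", "r2"), c("gA", "gC"), c(0, 0)),
                 regions, 0.01)
  P <- matrix(c(0.5, 0.2, 0.3), nrow = 1,
              dimnames = list("s1", c("gA", "gB", "gC")))
  got <- penalized_log_likelihood(P, c(1, 1, 1), list(tab))
  # N log Gamma(M) + read term; log C(1,1,1) = log Gamma(3)
  want <- lgamma(3) + log(0.5 * tab$q[1]) + log(0.3 * tab$q[2])
  expect_equal(got, want, tolerance = 1e-12)
})
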