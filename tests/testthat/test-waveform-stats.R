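test_that("pointwise Welch matches t.test to 1e-10, with pairwise deletion", {
  cfg <- stats_config(tail = "A_less")
  # spec-style fixture at a single timepoint
  A <- matrix(c(0.1, 0.2, 0.3), ncol = 1)
  B <- matrix(c(0.4, 0.5, 0.6), ncol = 1)
  pw <- pointwise_welch(A, B, cfg)
  oracle <- t.test(A[, 1], B[, 1], alternative = "less")
  expect_equal(pw$t, unname(oracle$statistic), tolerance = 1e-10)
  expect_equal(pw$df, unname(oracle$parameter), tolerance = 1e-10)
  expect_equal(pw$p, oracle$p.value, tolerance = 1e-10)
  expect_equal(pw$df, 4, tolerance = 1e-10)

  # random matrices with missingness, all three tails
  set.seed(11)
  A <- matrix(rnorm(8 * 20), 8)
  B <- matrix(rnorm(6 * 20, sd = 2), 6)
  A[sample(length(A), 25)] <- NA
  B[sample(length(B), 20)] <- NA
  for (tail in c("A_less", "A_greater", "two_sided")) {
    alt <- switch(tail, A_less = "less", A_greater = "greater",
                  two_sided = "two.sided")
    pw <- pointwise_welch(A, B, stats_config(tail = tail))
    for (j in seq_len(20)) {
      a <- A[!is.na(A[, j]), j]; b <- B[!is.na(B[, j]), j]
      if (length(a) < 2 || length(b) < 2) {
        expect_false(pw$testable[j])
        expect_true(is.na(pw$p[j]))
      } else {
        o <- t.test(a, b, alternative = alt)
        expect_equal(pw$t[j], unname(o$statistic), tolerance = 1e-10)
        expect_equal(pw$df[j], unname(o$parameter), tolerance = 1e-10)
        expect_equal(pw$p[j], o$p.value, tolerance = 1e-10)
      }
    }
  }
})

test_that("identical groups give t = 0 and one-tailed p = 0.5", {
  M <- matrix(rnorm(50, sd = 0.3), 5)
  pw <- pointwise_welch(M, M, stats_config(tail = "A_less"))
  expect_equal(pw$t, rep(0, 10))
  expect_equal(pw$p, rep(0.5, 10))
})

test_that("cohens_d is the (n-1)-pooled standardized mean difference", {
  expect_equal(cohens_d(c(0, 0, 2, 2), c(1, 1, 3, 3)), -0.866, tolerance = 1e-3)
  expect_equal(cohens_d(c(0, 0, 2, 2), c(1, 1, 3, 3)),
               -cohens_d(c(1, 1, 3, 3), c(0, 0, 2, 2)))
  expect_equal(cohens_d(c(1, 2, 3), c(2, 3, 1)), 0)
  expect_warning(d <- cohens_d(c(1, 1), c(1, 1)))
  expect_true(is.na(d))
  expect_error(cohens_d(1, c(1, 2)), class = "pw_input_error")
})

test_that("estimate_phi recovers the residual lag-1 autocorrelation", {
  wn <- list(ar1_matrix(12, 600, 0, 1), ar1_matrix(12, 600, 0, 2))
  expect_lt(abs(estimate_phi(wn[[1]], wn[[2]])), 0.05)
  ar <- list(ar1_matrix(12, 600, 0.9, 3), ar1_matrix(12, 600, 0.9, 4))
  expect_lt(abs(estimate_phi(ar[[1]], ar[[2]]) - 0.9), 0.05)
  # negative estimates clip to zero; constants are degenerate
  expect_gte(estimate_phi(ar1_matrix(3, 30, 0, 5), ar1_matrix(3, 30, 0, 6)), 0)
  const <- matrix(1, 4, 10)
  expect_error(estimate_phi(const, const), class = "pw_degenerate_error")
})

test_that("exact_max_run_tail agrees with closed forms and brute enumeration", {
  for (T in c(5, 40)) for (a in c(0.1, 0.5)) {
    expect_equal(exact_max_run_tail(T, 1, a), 1 - (1 - a)^T, tolerance = 1e-12)
    expect_equal(exact_max_run_tail(T, T, a), a^T, tolerance = 1e-12)
  }
  expect_equal(exact_max_run_tail(3, 2, 0.5), 0.375)
  expect_equal(exact_max_run_tail(3, 4, 0.5), 0)

  # full enumeration oracle, T = 10
  T <- 10; alpha <- 0.3
  grid <- as.matrix(expand.grid(rep(list(0:1), T)))
  maxrun <- apply(grid, 1, function(row) {
    r <- rle(row)
    m <- r$lengths[r$values == 1]
    if (length(m)) max(m) else 0
  })
  prob <- alpha^rowSums(grid) * (1 - alpha)^(T - rowSums(grid))
  for (k in 1:10)
    expect_equal(exact_max_run_tail(T, k, alpha), sum(prob[maxrun >= k]),
                 tolerance = 1e-12)
})

test_that("null_max_run honors alpha limits, seeds and the tail direction", {
  cfg1 <- stats_config(alpha_point = 0.999, n_sim = 50)
  cfg1$alpha_point <- 1  # forced significance
  expect_true(all(null_max_run(30, 5, 5, 0.5, cfg1) == 30))
  cfg0 <- stats_config(alpha_point = 1e-12, n_sim = 200)
  expect_true(all(null_max_run(30, 5, 5, 0.5, cfg0) == 0))

  cfg <- stats_config(n_sim = 500, seed = 7)
  expect_identical(as.integer(null_max_run(50, 6, 6, 0.5, cfg)),
                   as.integer(null_max_run(50, 6, 6, 0.5, cfg)))
  # the two one-tailed nulls are exchangeable in distribution
  m1 <- mean(null_max_run(50, 6, 6, 0.5, stats_config(n_sim = 2000, seed = 1)))
  m2 <- mean(null_max_run(50, 6, 6, 0.5,
                          stats_config(n_sim = 2000, tail = "A_greater",
                                       seed = 2)))
  expect_lt(abs(m1 - m2), 0.3)
})

test_that("run_threshold picks the smallest k with tail at or below alpha_fw", {
  cfg <- stats_config(alpha_fw = 0.05)
  expect_equal(run_threshold(rep(0L, 1000), cfg)$k_samples, 1)
  unif <- rep(1:20, each = 50)  # P(max >= 20) = 0.05 exactly
  thr <- run_threshold(unif, cfg)
  expect_equal(thr$k_samples, 20)
  expect_equal(thr$null_tail, 0.05)
  expect_error(run_threshold(rep(1L, 10), cfg), class = "pw_resolution_error")
})

test_that("k is non-decreasing in alpha_point under common random numbers", {
  ks <- vapply(c(0.02, 0.1, 0.3), function(a) {
    cfg <- stats_config(alpha_point = a, n_sim = 2000, seed = 31)
    run_threshold(null_max_run(200, 12, 12, 0.5, cfg, seed = 99), cfg)$k_samples
  }, numeric(1))
  expect_false(is.unsorted(ks))
})

test_that("find_windows respects run length, breaks on untestable points", {
  mk_tests <- function(p, testable = rep(TRUE, length(p))) {
    T <- length(p)
    data.frame(time_s = (seq_len(T) - 1) / 10, mean_A = 0, mean_B = 0,
               t = ifelse(p < 0.5, -2 - seq_len(T) / 100, 0), df = 10,
               p = p, n_A = 6L, n_B = 6L, testable = testable)
  }
  thr <- structure(list(k_samples = 3L, k_seconds = 0.3, phi_hat = 0,
                        null_tail = 0.01, n_sim = 1000),
                   class = "run_threshold")
  set.seed(5)
  A <- matrix(rnorm(60, -1), 6)
  B <- matrix(rnorm(60, 0), 6)
  cfg <- stats_config(tail = "A_less")

  expect_equal(nrow(find_windows(mk_tests(rep(0.5, 10)), thr, A, B, cfg)), 0)

  p <- rep(0.5, 10); p[4:5] <- 0.01      # run of 2 < k = 3
  expect_equal(nrow(find_windows(mk_tests(p), thr, A, B, cfg)), 0)
  p[6] <- 0.01                           # run of exactly 3
  w <- find_windows(mk_tests(p), thr, A, B, cfg)
  expect_equal(nrow(w), 1)
  expect_equal(w$start_s, 0.3)
  expect_equal(w$end_s, 0.5)
  expect_equal(w$length_samples, 3L)
  expect_gt(w$t, 0)  # oriented: positive = evidence for the A_less tail
  expect_gt(w$cohens_d, 0)

  # an untestable timepoint splits a would-be window
  p <- rep(0.01, 10)
  testable <- rep(TRUE, 10); testable[5] <- FALSE
  p[5] <- NA
  w <- find_windows(mk_tests(p, testable), thr, A, B, cfg)
  expect_equal(nrow(w), 2)
  expect_equal(w$length_samples, c(4L, 5L))
})

test_that("compare_groups is deterministic and silent on identical groups", {
  set.seed(19)
  M <- matrix(rnorm(12 * 80, sd = 0.2), 12)
  M <- M + rep(sin(seq_len(80) / 10), each = 12) * 0.1  # shared structure
  cfg <- stats_config(n_sim = 400, seed = 23)
  r1 <- compare_groups(M, M, cfg)
  r2 <- compare_groups(M, M, cfg)
  expect_identical(r1, r2)
  expect_equal(nrow(r1$windows), 0)
  expect_equal(r1$pointwise$t, rep(0, 80))

  # a strong A-lower offset in a known region is found there
  A <- M - 0.5 * rep(as.numeric(seq_len(80) >= 30 & seq_len(80) <= 60),
                     each = 12)
  r3 <- compare_groups(A, M, cfg)
  expect_gt(nrow(r3$windows), 0)
  expect_true(all(r3$windows$start_s >= 2.5 & r3$windows$end_s <= 6.2))
})
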