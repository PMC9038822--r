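test_that("pointwise t statistics match hand computation and handle degeneracy", {
  # hand oracle at a single center: mean/sd/sqrt(n)
  vals <- c(0.2, 0.3, 0.4, 0.5)
  hand_t <- mean(vals) / (sd(vals) / sqrt(4))
  mat <- cbind(vals, 0, c(1, 1, -1, -1))
  t <- t_series(mat)
  expect_equal(t[1], hand_t)
  expect_equal(t[2], 0) # all-zero center
  expect_equal(t[3], 0) # symmetric cancellation: mean 0
  # zero variance with nonzero mean: undefined, subthreshold, warned
  expect_warning(t4 <- t_series(cbind(vals, 1)), "zero variance")
  expect_equal(t4[2], 0)
})

test_that("cluster-forming threshold is the two-tailed t critical value", {
  expect_equal(round(critical_t(49), 2), 2.01)
  expect_equal(round(critical_t(1e7), 2), 1.96)
  # independent high-precision quantile check at n = 4
  expect_equal(critical_t(4, 0.05), qt(0.975, 3), tolerance = 1e-12)
  expect_error(critical_t(2), "n_participants >= 3")
})

test_that("clusters are maximal same-sign suprathreshold runs with summed mass", {
  cl <- find_clusters(c(0, 3, 3, 0, -3), 2.01)
  expect_equal(nrow(cl), 2)
  expect_equal(cl$mass, c(6, -3))
  expect_equal(cl$start, c(2, 5))
  expect_equal(cl$end, c(3, 5))
  expect_equal(cl$sign, c("positive", "negative"))

  expect_equal(nrow(find_clusters(c(1.5, -2, 0.3), 2.01)), 0)

  alternating <- find_clusters(c(3, -3, 3), 2)
  expect_equal(nrow(alternating), 3)
  expect_equal(alternating$mass, c(3, -3, 3))
})

test_that("Monte-Carlo p agrees with exhaustive enumeration at n = 4", {
  withr::with_seed(10, {
    mat <- matrix(rnorm(4 * 6, mean = 0.9, sd = 1), nrow = 4)
  })
  thr <- critical_t(4)
  suppressMessages(ex <- permutation_test(mat, method = "exhaustive",
                                          threshold = thr))
  mc <- permutation_test(mat, n_perm = 10000, seed = 3, method = "montecarlo",
                         threshold = thr)
  expect_gt(nrow(ex), 0)
  for (i in seq_len(nrow(ex))) {
    p_ex <- ex$p_value[i]
    se <- sqrt(p_ex * (1 - p_ex) / 10000)
    expect_lt(abs(mc$p_value[i] - p_ex), max(3 * se, 2e-4))
  }
})

test_that("an all-zero matrix yields no clusters", {
  res <- suppressMessages(permutation_test(matrix(0, 5, 8), n_perm = 100))
  expect_equal(nrow(res), 0)
})

test_that("p-values are valid probabilities and seed-reproducible", {
  withr::with_seed(4, mat <- matrix(rnorm(60, 0.5), nrow = 6))
  a <- suppressMessages(permutation_test(mat, n_perm = 500, seed = 9))
  b <- suppressMessages(permutation_test(mat, n_perm = 500, seed = 9))
  expect_equal(a, b)
  if (nrow(a) > 0) {
    expect_true(all(a$p_value > 0 & a$p_value <= 1))
    expect_equal(a$significant, a$p_value < 0.05)
  }
})

test_that("p-values are invariant to participant relabeling and time reversal", {
  withr::with_seed(11, mat <- matrix(rnorm(5 * 10, 0.8), nrow = 5))
  base <- suppressMessages(permutation_test(mat, method = "exhaustive"))
  relabeled <- suppressMessages(
    permutation_test(mat[c(3, 1, 5, 2, 4), ], method = "exhaustive"))
  expect_equal(base$p_value, relabeled$p_value)
  reversed <- suppressMessages(
    permutation_test(mat[, 10:1], method = "exhaustive"))
  expect_equal(sort(base$p_value), sort(reversed$p_value))
  expect_equal(sort(abs(base$mass)), sort(abs(reversed$mass)))
})

test_that("stronger injected effects are detected at least as often", {
  detect <- function(shift) {
    hits <- 0
    for (r in 1:20) {
      withr::with_seed(100 + r, {
        mat <- matrix(rnorm(8 * 15), nrow = 8)
        mat[, 6:10] <- mat[, 6:10] + shift
      })
      res <- suppressMessages(permutation_test(mat, method = "exhaustive"))
      hits <- hits + any(res$significant)
    }
    hits / 20
  }
  rates <- vapply(c(0, 0.8, 2), detect, numeric(1))
  expect_true(all(diff(rates) >= -0.1)) # nondecreasing up to simulation noise
  expect_equal(rates[3], 1)
})

test_that("trend test finds an increasing group effect and respects the null", {
  withr::with_seed(21, {
    ramp <- matrix(rep(seq(0, 1, length.out = 12), each = 10), nrow = 10) +
      matrix(rnorm(120, 0, 0.4), nrow = 10)
    flat <- matrix(rnorm(120), nrow = 10)
  })
  up <- permutation_trend_test(ramp, n_perm = 1000, seed = 2)
  expect_gt(up$statistic, 0.5)
  expect_lt(up$p_value, 0.01)
  null <- permutation_trend_test(flat, n_perm = 1000, seed = 2)
  expect_gt(null$p_value, 0.01)
})
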