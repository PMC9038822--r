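test_that("homogeneous accurate sample keeps every participant", {
  tr <- dplyr::bind_rows(lapply(1:5, function(p) {
    toy_trials(rep(c(400, 420, 440, 460), 5), participant = p)
  }))
  res <- screen_participants(tr)
  expect_setequal(res$included, 1:5)
  expect_equal(nrow(res$excluded), 0)
})

test_that("a participant 10 sample-SDs slow is excluded, matching hand z-scores", {
  base_means <- c(400, 402, 404, 406, 408, 410, 412, 414, 416)
  tr <- dplyr::bind_rows(lapply(1:10, function(p) {
    rt <- if (p <= 9) rep(base_means[p], 20) else rep(0, 20) # placeholder
    toy_trials(rt, participant = p)
  }))
  # place participant 10 exactly 10 sample SDs above the mean of all 10 means:
  # with m10 unknown, solve via fixed point is awkward; instead use an RT so
  # extreme that its z (computed below) clearly exceeds 10
  tr$rt_ms[tr$participant == 10] <- 2000
  res <- screen_participants(tr, rt_sd_cut = 2.5)
  # independent hand computation of the z-scores from the 10 participant means
  means <- tapply(tr$rt_ms, tr$participant, mean)
  z <- (means - mean(means)) / sd(means)
  expect_true(all(abs(z[1:9]) < 2.5) && abs(z[10]) > 2.5)
  expect_equal(res$excluded$participant, 10)
  expect_equal(res$excluded$reason, "slow_mean_rt")
  expect_equal(res$excluded$z, unname(z[10]))
})

test_that("accuracy below the 95% cutoff excludes a participant", {
  tr <- dplyr::bind_rows(lapply(1:3, function(p) {
    toy_trials(rep(450, 100), participant = p,
               correct = if (p == 2) rep(c(TRUE, FALSE), c(94, 6)) else TRUE)
  }))
  res <- screen_participants(tr, acc_min = 0.95)
  expect_equal(res$excluded$participant, 2)
  expect_equal(res$excluded$reason, "low_accuracy")
  expect_setequal(res$included, c(1, 3))
})

test_that("an extreme RT is removed by the 3SD log-RT rule, matching hand z", {
  rts <- c(rep(c(395, 400, 405, 410), 5), 20000)
  tr <- toy_trials(rts)
  # independent hand computation on the single-pass statistics
  z <- abs(log(rts) - mean(log(rts))) / sd(log(rts))
  expect_true(z[21] > 3 && all(z[-21] < 3))
  res <- filter_trials(tr, logrt_sd_cut = 3)
  expect_equal(res$trials$rt_ms, rts[-21])
  expect_equal(res$report$n_logrt_outliers_removed, 1)
  expect_equal(res$report$fraction_discarded, 1 / 21)
})

test_that("zero-variance RTs remove nothing and incorrect trials go first", {
  res <- filter_trials(toy_trials(rep(500, 10)))
  expect_equal(nrow(res$trials), 10)
  expect_equal(res$report$n_logrt_outliers_removed, 0)

  tr <- toy_trials(c(rep(500, 9), 505), correct = c(rep(TRUE, 9), FALSE))
  res2 <- filter_trials(tr)
  expect_equal(nrow(res2$trials), 9)
  expect_equal(res2$report$n_incorrect_removed, 1)
  expect_equal(res2$report$n_logrt_outliers_removed, 0)
  expect_equal(res2$report$n_trials_in,
               res2$report$n_retained + res2$report$n_incorrect_removed +
                 res2$report$n_logrt_outliers_removed)
})

test_that("participants with fewer than two correct trials are retained and flagged", {
  tr <- dplyr::bind_rows(
    toy_trials(c(400, 30000), participant = 1, correct = c(TRUE, FALSE)),
    toy_trials(rep(400, 10), participant = 2)
  )
  res <- filter_trials(tr)
  expect_equal(sum(res$trials$participant == 1), 1)
  expect_true(res$report$sd_undefined[res$report$participant == 1])
  expect_false(res$report$sd_undefined[res$report$participant == 2])
})

test_that("filtering decisions are invariant to row order", {
  withr::with_seed(2, {
    tr <- dplyr::bind_rows(lapply(1:3, function(p) {
      toy_trials(exp(rnorm(50, log(450), 0.2)), participant = p,
                 correct = runif(50) > 0.05)
    }))
    a <- filter_trials(tr)
    shuffled <- tr[sample(nrow(tr)), ]
    b <- filter_trials(shuffled)
    key <- function(x) dplyr::arrange(x$trials, participant, trial_index)$rt_ms
    expect_equal(key(a), key(b))
    expect_equal(a$report, b$report)
  })
})

test_that("inverse RT is 1000/rt_ms and round-trips exactly", {
  tr <- add_inverse_rt(toy_trials(c(500, 1000, 250)))
  expect_equal(tr$inv_rt, c(2, 1, 4))
  expect_equal(1000 / tr$inv_rt, tr$rt_ms)
  expect_true("rt_ms" %in% names(tr))
})
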