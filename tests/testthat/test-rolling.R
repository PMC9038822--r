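test_that("design rows follow the fixed coding", {
  expect_equal(unname(build_design_row(300, "E")[1, ]),
               c(1, -0.45, -0.5, 0.225))
  expect_equal(unname(build_design_row(1200, "A")[1, ]),
               c(1, 0.45, 0.5, 0.225))
  expect_equal(unname(build_design_row(750, "A")[1, ]), c(1, 0, 0.5, 0))
  expect_error(build_design_row(600, "X"), "unknown s1_type")
})

test_that("constant response gives Intercept = y and zero for other coefficients", {
  tr <- linear_series(70)
  tr$inv_rt <- 2.5
  tc <- rolling_ols(tr, window = 20)
  expect_equal(nrow(tc), 4 * (70 - 20 + 1))
  expect_equal(tc$beta[tc$coefficient == "Intercept"], rep(2.5, 51))
  expect_equal(max(abs(tc$beta[tc$coefficient != "Intercept"])), 0,
               tolerance = 1e-12)
})

test_that("noise-free linear data are recovered exactly in every window", {
  beta_true <- c(2, -0.8, 0.1, -0.4)
  tr <- linear_series(90, beta = beta_true, noise = 0)
  tc <- rolling_ols(tr, window = 30)
  for (j in seq_along(beta_true)) {
    vals <- tc$beta[tc$coefficient == levels(tc$coefficient)[j]]
    expect_equal(vals, rep(beta_true[j], length(vals)), tolerance = 1e-10)
  }
})

test_that("rolling OLS matches an explicit normal-equations oracle to 1e-10", {
  tr <- linear_series(100, noise = 0.3, seed = 8)
  w <- 60
  tc <- rolling_ols(tr, window = w)
  X_all <- build_design_row(tr$fp_ms, tr$s1_type)
  wide <- tidyr::pivot_wider(tc, names_from = coefficient, values_from = beta,
                             id_cols = center_trial)
  for (i in c(1, 17, 41)) {
    rows <- i:(i + w - 1)
    X <- X_all[rows, ]
    oracle <- solve(t(X) %*% X) %*% t(X) %*% tr$inv_rt[rows]
    got <- unlist(wide[i, c("Intercept", "FP", "S1type", "FPxS1type")])
    expect_equal(unname(got), as.vector(oracle), tolerance = 1e-10)
  }
  # centers are the trial at position ceiling(w/2) of each window
  expect_equal(wide$center_trial, seq_len(100 - w + 1) + 29)
})

test_that("window equal to the series length reproduces the global OLS fit", {
  tr <- linear_series(64, noise = 0.4, seed = 5)
  tc <- rolling_ols(tr, window = 64)
  X <- build_design_row(tr$fp_ms, tr$s1_type)
  global <- qr.coef(qr(X), tr$inv_rt)
  expect_equal(tc$beta, unname(global), tolerance = 1e-10)
})

test_that("permuting trials within a window leaves its estimate unchanged", {
  tr <- linear_series(40, noise = 0.5, seed = 3)
  tc <- rolling_ols(tr, window = 40)
  withr::with_seed(1, {
    perm <- sample(40)
    tr2 <- tr[perm, ]
    tr2$trial_index <- seq_len(40) # order changed, same window content
  })
  tc2 <- rolling_ols(tr2, window = 40)
  expect_equal(tc$beta, tc2$beta, tolerance = 1e-12)
})

test_that("all window sizes used in sensitivity analyses are supported", {
  tr <- linear_series(150, noise = 0.3, seed = 4)
  for (w in c(40, 60, 120)) {
    tc <- rolling_ols(tr, window = w)
    expect_equal(nrow(tc), 4 * (150 - w + 1))
    expect_true(all(tc$window == w))
  }
})

test_that("rank-deficient windows are flagged and dropped", {
  tr <- linear_series(60, noise = 0.2, seed = 6)
  tr$s1_type <- "E" # one S1 type only: S1 columns collinear with intercept
  tc <- rolling_ols(tr, window = 20)
  expect_equal(nrow(tc), 0)
  expect_equal(attr(tc, "n_flagged"), 41)
})

test_that("series shorter than the window warns and yields an empty course", {
  tr <- linear_series(10)
  expect_warning(tc <- rolling_ols(tr, window = 60), "shorter than window")
  expect_equal(nrow(tc), 0)
})

test_that("delta baselining subtracts the first center and is idempotent", {
  tr <- linear_series(30, noise = 0.3, seed = 2)
  tc <- to_delta(rolling_ols(tr, window = 10))
  first <- tc |>
    dplyr::group_by(coefficient) |>
    dplyr::slice_min(center_trial, n = 1)
  expect_true(all(first$delta_beta == 0))
  by_coef <- split(tc, tc$coefficient)
  for (b in by_coef) {
    expect_equal(b$delta_beta, b$beta - b$beta[1])
  }
  expect_equal(to_delta(to_delta(tc))$delta_beta, tc$delta_beta)
})

test_that("to_delta on a hand series gives (0, 1, 2)", {
  tc <- tibble::tibble(
    participant = 1, center_trial = 1:3,
    coefficient = factor("FP", levels = prepdyn:::coef_names),
    beta = c(3, 4, 5), delta_beta = NA_real_, window = 3
  )
  expect_equal(to_delta(tc)$delta_beta, c(0, 1, 2))
})
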