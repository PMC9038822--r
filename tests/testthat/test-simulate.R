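test_that("null generator carries no S1-type or interaction dependence", {
  params <- quiet_params(beta_s1 = 0, beta_int_max = 0, seed = 3)
  d <- generate_design(design_spec(), 4, seed = 1)
  tr <- simulate_rts(d, params)
  X <- build_design_row(tr$fp_ms, tr$s1_type)
  fit <- lm.fit(X, 1000 / tr$rt_ms)
  se <- sqrt(diag(chol2inv(chol(crossprod(X)))) *
               sum(fit$residuals^2) / (nrow(X) - 4))
  expect_lt(abs(fit$coefficients["S1type"]), 3 * se[3])
  expect_lt(abs(fit$coefficients["FPxS1type"]), 3 * se[4])
})

test_that("noise-free limit reproduces the deterministic mean exactly", {
  params <- quiet_params(noise_sd = 0, seed = 9, schedule = "constant",
                         beta_s1 = 0.05)
  d <- generate_design(tiny_spec(), 1, seed = 4)
  tr <- simulate_rts(d, params)
  mu <- with(tr, params$beta0 + params$beta_fp * (fp_ms - 750) / 1000 +
               params$beta_s1 * ifelse(s1_type == "A", 0.5, -0.5) +
               params$beta_int_max * (fp_ms - 750) / 1000 *
                 ifelse(s1_type == "A", 0.5, -0.5))
  expect_equal(1000 / tr$rt_ms, mu, tolerance = 1e-12)
  expect_true(all(tr$correct))
})

test_that("group OLS recovers the injected interaction within the analytic OLS SE", {
  # independent oracle: closed-form sampling SD of the per-participant OLS
  # interaction coefficient, sigma^2 * [(X'X)^-1]_{44}, averaged over
  # participants; the group-mean estimate must fall within 3 such SEs of the
  # schedule's true mean interaction level over the last Acquisition block.
  n_sub <- 12
  params <- generative_params(error_rate = 0, outlier_rate = 0, seed = 21)
  d <- generate_design(design_spec(), n_sub, seed = 20)
  tr <- simulate_rts(d, params)
  last <- tr[tr$block == 6, ]
  est <- var44 <- numeric(n_sub)
  for (p in seq_len(n_sub)) {
    tp <- last[last$participant == p, ]
    X <- build_design_row(tp$fp_ms, tp$s1_type)
    est[p] <- qr.coef(qr(X), 1000 / tp$rt_ms)["FPxS1type"]
    var44[p] <- params$noise_sd^2 * chol2inv(chol(crossprod(X)))[4, 4]
  }
  true_level <- mean(params$beta_int_max *
                       (1 - 2^(-(601:720) / params$learning_rate)))
  se_group <- sqrt(mean(var44) / n_sub)
  expect_lt(abs(mean(est) - true_level), 3 * se_group)
})

test_that("interaction schedule ramps, dips at Transfer onset and recovers", {
  params <- generative_params()
  phase <- c(rep("Acquisition", 720), rep("Transfer", 240))
  sched <- prepdyn:::interaction_schedule(params, phase)
  expect_true(all(diff(sched[1:720]) > 0))           # saturating ramp
  expect_lt(sched[720] , params$beta_int_max)
  expect_gt(sched[720], 0.8 * params$beta_int_max)   # near asymptote by Block 6
  expect_equal(sched[721], sched[720] * (1 - params$dip_depth)) # the dip
  expect_equal(sched[721 + params$dip_span_trials], sched[720]) # full recovery
  # constant schedule for stationary-effect simulations
  params$schedule <- "constant"
  expect_equal(unique(prepdyn:::interaction_schedule(params, phase)),
               params$beta_int_max)
})

test_that("simulated RTs are reproducible, positive and above 100 ms", {
  d <- generate_design(tiny_spec(4, 0), 2, seed = 5)
  p <- generative_params(seed = 8)
  t1 <- simulate_rts(d, p)
  t2 <- simulate_rts(d, p)
  expect_identical(t1, t2)
  expect_true(all(t1$rt_ms > 100))
  expect_equal(t1$correct, t1$response == t1$s2_side)
})

test_that("invalid parameters are rejected before simulation", {
  expect_error(generative_params(error_rate = 0.2), "error_rate")
  expect_error(generative_params(outlier_rate = -0.1), "outlier_rate")
  expect_error(generative_params(noise_sd = -1), "noise_sd")
  d <- generate_design(tiny_spec(), 1, seed = 1)
  bad <- quiet_params(beta0 = 0.01) # FP slope pushes the mean below 0
  expect_error(simulate_rts(d, bad), "non-positive mean")
  shuffled <- d[rev(seq_len(nrow(d))), ]
  expect_error(simulate_rts(shuffled, quiet_params()), "ordered")
})

test_that("scale_effects touches only the two contingency coefficients", {
  p <- generative_params(beta_s1 = 0.08)
  s <- scale_effects(p, 0.5)
  expect_equal(s$beta_s1, 0.04)
  expect_equal(s$beta_int_max, p$beta_int_max * 0.5)
  expect_equal(s[setdiff(names(s), c("beta_s1", "beta_int_max"))],
               p[setdiff(names(p), c("beta_s1", "beta_int_max"))])
  expect_identical(scale_effects(p, 1), p)
  expect_error(scale_effects(p, 0), "in \\(0, 1\\]")
})
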