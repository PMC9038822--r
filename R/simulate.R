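#' Parameters of the generative inverse-RT model
#'
#' The generator works on the inverse-RT scale (units 1/s), mirroring the
#' analysis model: the expected inverse RT on trial t is
#' \deqn{\mu(t) = \beta_0(t) + \beta_{FP}\,fp + \beta_{S1}\,s1 +
#'   \beta_{int}(t)\,fp\,s1}
#' with `fp` the FP in seconds centred at the design midpoint (750 ms) and
#' `s1` coded -0.5 (E) / +0.5 (A). The interaction coefficient follows a
#' saturating ramp over Acquisition trials (reflecting gradual learning of the
#' category-FP contingency), is suppressed by `dip_depth` at the first
#' Transfer trial (the transient effect of countermanding instructions) and
#' recovers linearly over `dip_span_trials`. The intercept carries a
#' within-block linear fatigue drift that resets at block breaks. Participants
#' get correlated random intercepts and FP slopes; residual noise is Gaussian
#' on the inverse-RT scale.
#'
#' @param beta0 Baseline inverse RT (1/s). Default 2.2 (about 455 ms).
#' @param beta_fp Inverse-RT change per second of FP; positive values give the
#'   downward-sloping RT-FP curve typical of temporal preparation.
#' @param beta_s1 Main S1-type effect (A minus E contrast on inverse RT);
#'   negative values make responses slightly faster after exponential-type S1s.
#' @param beta_int_max Asymptote of the S1-type-by-FP interaction ramp.
#' @param learning_rate Acquisition trials to half-asymptote of the ramp.
#' @param dip_depth Fractional suppression of the interaction at Transfer
#'   onset (1 = full return to baseline).
#' @param dip_span_trials Transfer trials over which the dip recovers.
#' @param fatigue_amp Within-block intercept drop from first to last trial
#'   of a block (1/s); resets at each block break.
#' @param noise_sd Residual SD on inverse RT (1/s). Zero gives the
#'   deterministic noise-free limit.
#' @param subject_sd_intercept,subject_sd_fp,subject_corr Random-effect
#'   standard deviations and their correlation.
#' @param error_rate Probability of an incorrect response on a trial.
#' @param outlier_rate,outlier_scale Probability that a trial's RT is inflated
#'   by `outlier_scale` (attentional lapses and the like).
#' @param schedule `"ramp"` for the learned, dipping interaction trajectory;
#'   `"constant"` holds the interaction at `beta_int_max` throughout (used by
#'   power simulations of a stationary Transfer-phase effect).
#' @param seed Integer RNG seed used by [simulate_rts()].
#'
#' @return An object of class `generative_params`.
#' @export
generative_params <- function(beta0 = 2.2,
                              beta_fp = 0.2,
                              beta_s1 = -0.02,
                              beta_int_max = 0.2,
                              learning_rate = 240,
                              dip_depth = 1,
                              dip_span_trials = 60,
                              fatigue_amp = 0.1,
                              noise_sd = 0.25,
                              subject_sd_intercept = 0.2,
                              subject_sd_fp = 0.1,
                              subject_corr = -0.3,
                              error_rate = 0.03,
                              outlier_rate = 0.005,
                              outlier_scale = 3,
                              schedule = c("ramp", "constant"),
                              seed = 1L) {
  schedule <- match.arg(schedule)
  p <- structure(
    list(beta0 = beta0, beta_fp = beta_fp, beta_s1 = beta_s1,
         beta_int_max = beta_int_max, learning_rate = learning_rate,
         dip_depth = dip_depth, dip_span_trials = dip_span_trials,
         fatigue_amp = fatigue_amp, noise_sd = noise_sd,
         subject_sd_intercept = subject_sd_intercept,
         subject_sd_fp = subject_sd_fp, subject_corr = subject_corr,
         error_rate = error_rate, outlier_rate = outlier_rate,
         outlier_scale = outlier_scale, schedule = schedule,
         seed = as.integer(seed)),
    class = "generative_params"
  )
  validate_generative_params(p)
  p
}

validate_generative_params <- function(p) {
  stopifnot(inherits(p, "generative_params"))
  if (p$noise_sd < 0) stop("parameter error: noise_sd must be >= 0", call. = FALSE)
  if (p$error_rate < 0 || p$error_rate >= 0.1) {
    stop("parameter error: error_rate must be in [0, 0.1)", call. = FALSE)
  }
  if (p$outlier_rate < 0 || p$outlier_rate >= 0.1) {
    stop("parameter error: outlier_rate must be in [0, 0.1)", call. = FALSE)
  }
  if (p$outlier_scale < 1) {
    stop("parameter error: outlier_scale must be >= 1", call. = FALSE)
  }
  if (p$learning_rate <= 0 || p$dip_span_trials < 1) {
    stop("parameter error: learning_rate > 0 and dip_span_trials >= 1 required",
         call. = FALSE)
  }
  if (p$dip_depth < 0 || p$dip_depth > 1) {
    stop("parameter error: dip_depth must be in [0, 1]", call. = FALSE)
  }
  if (abs(p$subject_corr) > 1 || p$subject_sd_intercept < 0 || p$subject_sd_fp < 0) {
    stop("parameter error: invalid random-effect scales", call. = FALSE)
  }
  invisible(p)
}

#' Scale down the category-contingency effects
#'
#' Multiplies the S1-type main effect and the S1-type-by-FP interaction
#' asymptote by `scale`, leaving every other parameter untouched. This is the
#' effect-size manipulation used by the power simulations.
#'
#' @param params A [generative_params()] object.
#' @param scale Effect-size scale in (0, 1].
#' @return A `generative_params` object with scaled `beta_s1`/`beta_int_max`.
#' @export
scale_effects <- function(params, scale) {
  stopifnot(inherits(params, "generative_params"))
  if (!is.numeric(scale) || length(scale) != 1 || scale <= 0 || scale > 1) {
    stop("scale must be a single number in (0, 1]", call. = FALSE)
  }
  params$beta_s1 <- params$beta_s1 * scale
  params$beta_int_max <- params$beta_int_max * scale
  params
}

# FP centring used throughout: seconds, centred at the 750 ms design midpoint.
fp_coded <- function(fp_ms) (fp_ms - 750) / 1000

s1_coded <- function(s1_type) {
  if (!all(s1_type %in% c("E", "A"))) {
    stop("input error: unknown s1_type label (expected 'E' or 'A')", call. = FALSE)
  }
  ifelse(s1_type == "A", 0.5, -0.5)
}

# Interaction coefficient schedule for one participant's ordered trials.
interaction_schedule <- function(params, phase) {
  if (params$schedule == "constant") {
    return(rep(params$beta_int_max, length(phase)))
  }
  is_acq <- phase == "Acquisition"
  n_acq <- sum(is_acq)
  ramp <- function(k) params$beta_int_max * (1 - 2^(-k / params$learning_rate))
  out <- numeric(length(phase))
  out[is_acq] <- ramp(seq_len(n_acq))
  if (any(!is_acq)) {
    base <- ramp(n_acq) # level reached by the end of Acquisition
    j <- seq_len(sum(!is_acq))
    suppression <- params$dip_depth * pmax(0, 1 - (j - 1) / params$dip_span_trials)
    out[!is_acq] <- base * (1 - suppression)
  }
  out
}

#' Simulate responses and RTs for a designed trial sequence
#'
#' Completes trial skeletons from [generate_design()] with responses and RTs
#' drawn from the time-varying generative inverse-RT model described in
#' [generative_params()]. Draws whose implied RT would be non-positive or
#' below 100 ms are resampled; a fraction `outlier_rate` of trials has its RT
#' inflated by `outlier_scale`; responses are flipped with probability
#' `error_rate`. Fully reproducible given `params$seed`.
#'
#' @param design Trial skeletons, ordered by participant then `trial_index`.
#' @param params A [generative_params()] object.
#' @return The design tibble with added columns `response`, `rt_ms`, `correct`.
#' @export
#' @examples
#' d <- generate_design(design_spec(), n_participants = 2, seed = 1)
#' trials <- simulate_rts(d, generative_params(seed = 2))
simulate_rts <- function(design, params) {
  validate_generative_params(params)
  stopifnot(all(c("participant", "trial_index", "phase", "s1_type", "fp_ms",
                  "s2_side", "block") %in% names(design)))
  ord <- order(design$participant, design$trial_index)
  if (!identical(ord, seq_len(nrow(design)))) {
    stop("design must be ordered by participant then trial_index", call. = FALSE)
  }

  fp_c <- fp_coded(design$fp_ms)
  s1_c <- s1_coded(design$s1_type)
  split_idx <- split(seq_len(nrow(design)), design$participant)

  # deterministic trial-level mean (no random effects): must be positive
  beta_int <- numeric(nrow(design))
  drift <- numeric(nrow(design))
  for (idx in split_idx) {
    beta_int[idx] <- interaction_schedule(params, design$phase[idx])
    for (b in unique(design$block[idx])) {
      bi <- idx[design$block[idx] == b]
      nb <- length(bi)
      drift[bi] <- if (nb > 1) {
        params$fatigue_amp * (seq_len(nb) - 1) / (nb - 1)
      } else 0
    }
  }
  mu0 <- params$beta0 - drift + params$beta_fp * fp_c + params$beta_s1 * s1_c +
    beta_int * fp_c * s1_c
  if (any(mu0 <= 0)) {
    stop("parameter error: parameters imply a non-positive mean inverse RT",
         call. = FALSE)
  }

  withr::with_seed(params$seed, {
    # correlated subject random effects via 2x2 Cholesky
    ids <- names(split_idx)
    z <- matrix(stats::rnorm(2 * length(ids)), ncol = 2)
    b0 <- params$subject_sd_intercept * z[, 1]
    bfp <- params$subject_sd_fp *
      (params$subject_corr * z[, 1] + sqrt(1 - params$subject_corr^2) * z[, 2])
    names(b0) <- names(bfp) <- ids

    pid <- as.character(design$participant)
    mu <- mu0 + unname(b0[pid]) + unname(bfp[pid]) * fp_c
    # extreme random-effect draws could push a subject's mean non-positive;
    # clamp to a slow-but-finite 0.2/s (5 s) rather than fail mid-simulation
    mu <- pmax(mu, 0.2)

    y <- mu + stats::rnorm(length(mu), 0, params$noise_sd)
    bad <- y <= 0 | y >= 1000 / 100 # implied rt <= 100 ms
    tries <- 0
    while (any(bad)) {
      y[bad] <- mu[bad] + stats::rnorm(sum(bad), 0, params$noise_sd)
      bad <- y <= 0 | y >= 1000 / 100
      tries <- tries + 1
      if (tries > 1000) {
        stop("parameter error: cannot draw positive RTs above 100 ms", call. = FALSE)
      }
    }
    rt_ms <- 1000 / y
    is_outlier <- stats::runif(length(y)) < params$outlier_rate
    rt_ms[is_outlier] <- rt_ms[is_outlier] * params$outlier_scale

    correct <- stats::runif(length(y)) >= params$error_rate
    response <- ifelse(correct, design$s2_side,
                       ifelse(design$s2_side == "left", "right", "left"))

    design$response <- response
    design$rt_ms <- rt_ms
    design$correct <- correct
    design
  })
}

#' Generate and simulate a full synthetic experiment
#'
#' Convenience wrapper: builds the balanced design for `n_participants` and
#' simulates responses from the generative model. The design uses `seed` and
#' the response simulation `seed + 1`, so a single integer reproduces the
#' whole dataset.
#'
#' @param n_participants Number of participants (study default 49).
#' @param spec A [design_spec()].
#' @param params A [generative_params()]; its `seed` field is overridden.
#' @param seed Master integer seed.
#' @return A completed trial tibble (see [simulate_rts()]).
#' @export
simulate_experiment <- function(n_participants = 49,
                                spec = design_spec(),
                                params = generative_params(),
                                seed = 1L) {
  seed <- as.integer(seed)
  design <- generate_design(spec, n_participants, seed = seed)
  params$seed <- seed + 1L
  simulate_rts(design, params)
}
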