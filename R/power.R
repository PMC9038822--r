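#' Simulation-based power for the S1-type contingency effects
#'
#' Reimplements the scaled-effect power heuristic: for each combination of
#' sample size and effect-size scale, many Transfer-phase datasets are
#' simulated from the generative model with the S1-type main effect and the
#' S1-type-by-FP interaction scaled down, the FP-only and FP-by-S1-type mixed
#' models are both fit by maximum likelihood, and power is the fraction of
#' simulations in which the 2-df likelihood-ratio test for the S1-type terms
#' is significant at `alpha`. Non-converged fits are excluded from the
#' denominator and counted separately. Per-cell and per-simulation seeds are
#' derived deterministically from the master seed.
#'
#' @param n_grid Sample sizes to simulate (study grid 35-45).
#' @param scale_grid Effect-size scales in (0, 1] (study grid 0.15-0.25).
#' @param n_sims Simulated datasets per cell (study default 250).
#' @param alpha LRT significance level.
#' @param params Reference [generative_params()]; the interaction schedule is
#'   forced to `"constant"`, matching a stationary Transfer-phase effect.
#' @param spec Transfer-phase [design_spec()]; default 2 uniform-FP blocks
#'   and no Acquisition blocks.
#' @param seed Master integer seed.
#' @param rule How significance is scored: `"phase"` (one LRT on all
#'   Transfer trials), `"per_block_any"` or `"per_block_all"` (LRT per block,
#'   significant if any/all blocks are).
#' @return A tibble with one row per cell: `n`, `scale`, `n_sims`,
#'   `n_converged`, `n_significant`, `power`, `se` (binomial).
#' @export
estimate_power <- function(n_grid, scale_grid, n_sims = 250, alpha = 0.05,
                           params = generative_params(),
                           spec = design_spec(n_acquisition_blocks = 0,
                                              n_transfer_blocks = 2),
                           seed = 1L,
                           rule = c("phase", "per_block_any", "per_block_all")) {
  rule <- match.arg(rule)
  stopifnot(length(n_grid) >= 1, length(scale_grid) >= 1, n_sims >= 1,
            all(scale_grid > 0), all(scale_grid <= 1))
  params$schedule <- "constant"
  params$dip_depth <- 0
  grid <- expand.grid(n = n_grid, scale = scale_grid)
  out <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    n <- grid$n[g]
    sc <- grid$scale[g]
    cell_params <- scale_effects(params, sc)
    sig <- conv <- logical(n_sims)
    for (s in seq_len(n_sims)) {
      sim_seed <- (as.integer(seed) + 7919L * g + s) %% .Machine$integer.max
      trials <- simulate_experiment(n, spec, cell_params, seed = sim_seed)
      trials <- add_inverse_rt(filter_trials(trials)$trials)
      data <- prepare_lmm_data(trials)
      res <- power_one_lrt(data, alpha, rule)
      sig[s] <- res$significant
      conv[s] <- res$converged
    }
    n_conv <- sum(conv)
    p_hat <- if (n_conv > 0) mean(sig[conv]) else NA_real_
    out[[g]] <- tibble::tibble(
      n = n, scale = sc, n_sims = n_sims, n_converged = n_conv,
      n_significant = sum(sig[conv]), power = p_hat,
      se = if (n_conv > 0) sqrt(p_hat * (1 - p_hat) / n_conv) else NA_real_
    )
  }
  dplyr::bind_rows(out)
}

power_one_lrt <- function(data, alpha, rule) {
  run_lrt <- function(d) {
    full <- fit_lmm(d, c("FP", "S1type", "FPxS1type"))
    null <- fit_lmm(d, "FP")
    list(p = lrt(full, null)$p_value,
         converged = full$converged && null$converged)
  }
  if (rule == "phase") {
    r <- run_lrt(data)
    return(list(significant = r$converged && r$p < alpha, converged = r$converged))
  }
  per_block <- lapply(split(data, data$block), run_lrt)
  converged <- all(vapply(per_block, `[[`, logical(1), "converged"))
  ps <- vapply(per_block, `[[`, numeric(1), "p")
  hit <- if (rule == "per_block_any") any(ps < alpha) else all(ps < alpha)
  list(significant = converged && hit, converged = converged)
}
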