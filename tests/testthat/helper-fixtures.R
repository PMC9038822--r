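# Small fixtures shared across tests; everything is generated in code.

# Degenerate design: one trial per FP x type cell per block.
tiny_spec <- function(n_acq = 1, n_trans = 1) {
  design_spec(
    n_acquisition_blocks = n_acq, n_transfer_blocks = n_trans,
    exp_counts_per_block = c(1, 1, 1, 1), uniform_count_per_fp = 1
  )
}

# Quiet generative parameters: no errors, no outliers, no drift; overridable.
quiet_params <- function(...) {
  defaults <- list(fatigue_amp = 0, error_rate = 0, outlier_rate = 0,
                   subject_sd_intercept = 0, subject_sd_fp = 0)
  do.call(generative_params, utils::modifyList(defaults, list(...)))
}

# Hand-built trial table from explicit RTs (all same design cell by default).
toy_trials <- function(rt_ms, participant = 1, correct = TRUE,
                       fp_ms = 600, s1_type = "E") {
  n <- length(rt_ms)
  tibble::tibble(
    participant = participant, block = 1L, trial_index = seq_len(n),
    phase = "Acquisition", s1_category = "face",
    s1_type = rep_len(s1_type, n), fp_ms = rep_len(fp_ms, n),
    s2_side = "left",
    response = ifelse(rep_len(correct, n), "left", "right"),
    rt_ms = rt_ms, correct = rep_len(correct, n)
  )
}

# A filtered, analysis-ready table for rolling tests: balanced FP x type
# sequence with a known linear structure plus optional noise.
linear_series <- function(n = 80, beta = c(2, -0.8, 0.1, -0.4), noise = 0,
                          seed = 1) {
  withr::with_seed(seed, {
    fp <- sample(rep(c(300, 600, 900, 1200), length.out = n))
    s1 <- sample(rep(c("E", "A"), length.out = n))
    X <- build_design_row(fp, s1)
    y <- as.vector(X %*% beta) + rnorm(n, 0, noise)
    tibble::tibble(
      participant = 1L, block = 1L, trial_index = seq_len(n),
      phase = "Acquisition", s1_category = "face", s1_type = s1,
      fp_ms = fp, s2_side = "left", response = "left",
      rt_ms = 1000 / pmax(y, 0.1), correct = TRUE, inv_rt = y
    )
  })
}
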