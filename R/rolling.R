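#' Design row(s) for the four-coefficient trial model
#'
#' Builds the predictor matrix (Intercept, FP, S1 type, FP x S1 type) used by
#' both the rolling regression and the generative model. FP is coded in
#' seconds centred at the 750 ms design midpoint — a fixed constant, not
#' re-centred per window, so coefficient time courses are comparable across
#' windows. S1 type is coded -0.5 (E) / +0.5 (A).
#'
#' @param fp_ms FP durations in ms.
#' @param s1_type S1 type labels ("E"/"A").
#' @return A numeric matrix with columns `Intercept`, `FP`, `S1type`,
#'   `FPxS1type`.
#' @export
#' @examples
#' build_design_row(300, "E") # (1, -0.45, -0.5, 0.225)
build_design_row <- function(fp_ms, s1_type) {
  fp <- fp_coded(fp_ms)
  s1 <- s1_coded(s1_type)
  cbind(Intercept = 1, FP = fp, S1type = s1, FPxS1type = fp * s1)
}

coef_names <- c("Intercept", "FP", "S1type", "FPxS1type")

# OLS over sliding windows of one participant's series. Returns a list with
# the coefficient matrix (n_centers x 4), center trial indices, and a flag
# vector for rank-deficient windows.
rolling_ols_one <- function(y, X, trial_index, window, center_pos) {
  n <- length(y)
  n_win <- n - window + 1
  beta <- matrix(NA_real_, n_win, 4, dimnames = list(NULL, coef_names))
  flagged <- logical(n_win)
  for (i in seq_len(n_win)) {
    rows <- i:(i + window - 1)
    qrX <- qr(X[rows, , drop = FALSE])
    if (qrX$rank < 4) {
      flagged[i] <- TRUE
    } else {
      beta[i, ] <- qr.coef(qrX, y[rows])
    }
  }
  list(beta = beta, center_trial = trial_index[seq_len(n_win) + center_pos - 1],
       flagged = flagged)
}

#' Rolling-window coefficient time courses
#'
#' Slides a `window`-trial ordinary-least-squares fit of inverse RT on
#' (Intercept, FP, S1 type, FP x S1 type) over each participant's retained
#' trials in experiment order. Windows cross block and phase boundaries. Each
#' window's estimate is assigned to the trial at the window's center (position
#' `ceiling(window/2)` by default, i.e. position 30 of a 60-trial window), so
#' no values exist for the first and last trials of the experiment.
#' Rank-deficient windows (e.g. a window containing only one S1 type) are
#' flagged and dropped rather than estimated.
#'
#' @param trials Analysis-ready trials (needs `participant`, `trial_index`,
#'   `fp_ms`, `s1_type`, `inv_rt`), ordered within participant.
#' @param window Window length in trials (study default 60; sensitivity
#'   analyses use 40 and 120).
#' @param center_pos Position within the window taken as its center; default
#'   `ceiling(window / 2)` (left-of-middle for even windows).
#' @return A tibble with columns `participant`, `center_trial`, `coefficient`,
#'   `beta`, `delta_beta` (NA until [to_delta()]), `window`. The number of
#'   dropped rank-deficient windows is attached as attribute `n_flagged`.
#' @export
rolling_ols <- function(trials, window = 60, center_pos = ceiling(window / 2)) {
  stopifnot(window >= 4, center_pos >= 1, center_pos <= window)
  if (!"inv_rt" %in% names(trials)) trials <- add_inverse_rt(trials)
  trials <- dplyr::arrange(trials, .data$participant, .data$trial_index)
  out <- list()
  n_flagged <- 0L
  for (p in unique(trials$participant)) {
    tp <- trials[trials$participant == p, ]
    if (nrow(tp) < window) {
      warning(sprintf("participant %s: series shorter than window; empty time course", p))
      next
    }
    X <- build_design_row(tp$fp_ms, tp$s1_type)
    fit <- rolling_ols_one(tp$inv_rt, X, tp$trial_index, window, center_pos)
    ok <- !fit$flagged
    n_flagged <- n_flagged + sum(fit$flagged)
    if (!any(ok)) next
    out[[length(out) + 1]] <- tibble::tibble(
      participant = p,
      center_trial = rep(fit$center_trial[ok], times = 4),
      coefficient = rep(coef_names, each = sum(ok)),
      beta = as.vector(fit$beta[ok, ]),
      delta_beta = NA_real_,
      window = window
    )
  }
  res <- if (length(out)) dplyr::bind_rows(out) else tibble::tibble(
    participant = integer(), center_trial = integer(), coefficient = character(),
    beta = numeric(), delta_beta = numeric(), window = integer()
  )
  res$coefficient <- factor(res$coefficient, levels = coef_names)
  attr(res, "n_flagged") <- n_flagged
  res
}

#' Baseline coefficient time courses to the start of the experiment
#'
#' Subtracts, per participant and coefficient, the first window's estimate
#' from the whole series, yielding the change-since-start measure (delta
#' beta). The first element of every series is exactly zero and the operation
#' is idempotent.
#'
#' @param timecourse Output of [rolling_ols()].
#' @return The tibble with `delta_beta` populated.
#' @export
to_delta <- function(timecourse) {
  if (nrow(timecourse) == 0) return(timecourse)
  timecourse |>
    dplyr::group_by(.data$participant, .data$coefficient) |>
    dplyr::arrange(.data$center_trial, .by_group = TRUE) |>
    dplyr::mutate(delta_beta = .data$beta - .data$beta[1]) |>
    dplyr::ungroup()
}

#' Align participants' delta-beta series into a group matrix
#'
#' Stacks one coefficient's delta-beta series into a participants-by-centers
#' matrix for group-level inference. If participants' center grids differ
#' (e.g. because trial filtering removed different numbers of trials), series
#' are aligned on their ordinal center sequence and truncated to the shortest
#' series, with a message; no values are imputed.
#'
#' @param timecourse Output of [to_delta()].
#' @param coefficient One of `"Intercept"`, `"FP"`, `"S1type"`, `"FPxS1type"`.
#' @return A list with `mat` (participants x centers matrix of delta_beta),
#'   `centers` (per-column median center trial index), `coefficient` and `n`.
#' @export
group_timecourse <- function(timecourse, coefficient = "FPxS1type") {
  coefficient <- match.arg(coefficient, coef_names)
  tc <- timecourse |>
    dplyr::filter(.data$coefficient == !!coefficient) |>
    dplyr::arrange(.data$participant, .data$center_trial)
  if (nrow(tc) == 0) stop("input error: no series for that coefficient", call. = FALSE)
  series <- split(tc, tc$participant)
  lens <- vapply(series, nrow, integer(1))
  m <- min(lens)
  if (length(unique(lens)) > 1) {
    message(sprintf(
      "unequal center grids across participants; truncating to %d ordinal centers", m))
  }
  mat <- do.call(rbind, lapply(series, function(s) s$delta_beta[seq_len(m)]))
  centers <- apply(
    do.call(rbind, lapply(series, function(s) s$center_trial[seq_len(m)])),
    2, stats::median)
  list(mat = unname(mat), centers = centers, coefficient = coefficient,
       n = nrow(mat), participants = names(series))
}
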