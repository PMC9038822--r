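#' Screen participants on mean RT and accuracy
#'
#' Excludes participants whose mean correct-trial RT lies more than
#' `rt_sd_cut` sample standard deviations from the sample mean of participant
#' means, and participants whose overall accuracy falls below `acc_min`.
#' Mirrors the study's sample-level exclusion rules (2.5 SD on mean correct RT,
#' 95% accuracy cutoff). Screening operates on the full sample statistics
#' computed once, before any trial-level filtering.
#'
#' @param trials Completed trial tibble (needs `participant`, `rt_ms`,
#'   `correct`).
#' @param rt_sd_cut Exclusion threshold in sample SDs of participant mean RTs.
#' @param acc_min Minimum accuracy (fraction of all trials correct).
#' @return A list with `included` (participant ids), `excluded` (tibble of
#'   `participant`, `reason` in `slow_mean_rt`/`low_accuracy`, `mean_rt`,
#'   `accuracy`, `z`), and `participant_stats` (per-participant summary).
#' @export
screen_participants <- function(trials, rt_sd_cut = 2.5, acc_min = 0.95) {
  if (nrow(trials) == 0) stop("input error: empty trial table", call. = FALSE)
  stats_tbl <- trials |>
    dplyr::group_by(.data$participant) |>
    dplyr::summarise(
      mean_rt = mean(.data$rt_ms[.data$correct]),
      accuracy = mean(.data$correct),
      .groups = "drop"
    )
  if (nrow(stats_tbl) < 3) {
    stop("input error: need at least 3 participants for sample statistics",
         call. = FALSE)
  }
  m <- mean(stats_tbl$mean_rt)
  s <- stats::sd(stats_tbl$mean_rt)
  stats_tbl$z <- if (s > 0) (stats_tbl$mean_rt - m) / s else 0
  stats_tbl$reason <- dplyr::case_when(
    abs(stats_tbl$z) > rt_sd_cut ~ "slow_mean_rt",
    stats_tbl$accuracy < acc_min ~ "low_accuracy",
    TRUE ~ NA_character_
  )
  list(
    included = stats_tbl$participant[is.na(stats_tbl$reason)],
    excluded = dplyr::filter(stats_tbl, !is.na(.data$reason))[
      , c("participant", "reason", "mean_rt", "accuracy", "z")],
    participant_stats = stats_tbl[, c("participant", "mean_rt", "accuracy", "z")]
  )
}

#' Remove incorrect trials and per-participant log-RT outliers
#'
#' Applies the two trial-level exclusion rules in order: (1) incorrect
#' responses are discarded; (2) among each participant's remaining trials,
#' those whose log RT deviates from that participant's mean log RT by more
#' than `logrt_sd_cut` standard deviations are discarded. Statistics are
#' computed once, in a single pass — the rule is not re-applied to its own
#' output. Participants with fewer than two correct trials (undefined SD)
#' keep all their correct trials and are flagged.
#'
#' @param trials Completed trial tibble with positive `rt_ms`.
#' @param logrt_sd_cut Outlier threshold in within-participant SDs of log RT.
#' @return A list with `trials` (retained rows) and `report`, a per-participant
#'   tibble: `n_trials_in`, `n_incorrect_removed`, `n_logrt_outliers_removed`,
#'   `n_retained`, `fraction_discarded` (log-RT outliers among correct trials,
#'   the study's "trials discarded" statistic), `sd_undefined`.
#' @export
filter_trials <- function(trials, logrt_sd_cut = 3) {
  if (nrow(trials) == 0) stop("input error: empty trial table", call. = FALSE)
  stopifnot(all(trials$rt_ms > 0))
  keep <- trials |>
    dplyr::group_by(.data$participant) |>
    dplyr::mutate(.logrt = log(.data$rt_ms),
                  .mu = mean(.data$.logrt[.data$correct]),
                  .sd = stats::sd(.data$.logrt[.data$correct]),
                  .outlier = .data$correct & !is.na(.data$.sd) & .data$.sd > 0 &
                    abs(.data$.logrt - .data$.mu) > logrt_sd_cut * .data$.sd) |>
    dplyr::ungroup()
  report <- keep |>
    dplyr::group_by(.data$participant) |>
    dplyr::summarise(
      n_trials_in = dplyr::n(),
      n_incorrect_removed = sum(!.data$correct),
      n_logrt_outliers_removed = sum(.data$.outlier),
      n_retained = sum(.data$correct & !.data$.outlier),
      fraction_discarded = sum(.data$.outlier) / max(1, sum(.data$correct)),
      sd_undefined = sum(.data$correct) < 2,
      .groups = "drop"
    )
  retained <- keep |>
    dplyr::filter(.data$correct, !.data$.outlier) |>
    dplyr::select(-dplyr::all_of(c(".logrt", ".mu", ".sd", ".outlier")))
  list(trials = retained, report = report)
}

#' Add the inverse-RT analysis response
#'
#' Appends `inv_rt = 1000 / rt_ms`, the reciprocal reaction time in 1/s used
#' as the dependent variable throughout; the raw RT column is preserved.
#'
#' @param trials Trial tibble with positive `rt_ms`.
#' @return `trials` with an `inv_rt` column.
#' @export
#' @examples
#' add_inverse_rt(tibble::tibble(rt_ms = c(500, 1000)))$inv_rt # 2, 1
add_inverse_rt <- function(trials) {
  stopifnot(all(trials$rt_ms > 0))
  trials$inv_rt <- 1000 / trials$rt_ms
  trials
}

#' Run the full preprocessing chain
#'
#' Participant screening, then trial filtering, then the inverse-RT response.
#'
#' @inheritParams screen_participants
#' @inheritParams filter_trials
#' @return A list with `trials` (analysis-ready), `screen` (from
#'   [screen_participants()]) and `report` (from [filter_trials()]).
#' @export
preprocess <- function(trials, rt_sd_cut = 2.5, acc_min = 0.95, logrt_sd_cut = 3) {
  screen <- screen_participants(trials, rt_sd_cut = rt_sd_cut, acc_min = acc_min)
  kept <- dplyr::filter(trials, .data$participant %in% screen$included)
  filt <- filter_trials(kept, logrt_sd_cut = logrt_sd_cut)
  list(trials = add_inverse_rt(filt$trials), screen = screen,
       report = filt$report)
}
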