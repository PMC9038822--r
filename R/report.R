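#' Participant and group mean RT per FP, S1 type and phase
#'
#' Computes each participant's mean RT per condition cell first, then the
#' unweighted group mean of participant means (every participant counts
#' equally regardless of trial counts).
#'
#' @param trials Retained trials.
#' @return A list with `participant_means` (participant x condition tibble)
#'   and `group` (per-condition `mean_rt`, `n`).
#' @export
rt_fp_table <- function(trials) {
  pm <- trials |>
    dplyr::group_by(.data$participant, .data$phase, .data$s1_type, .data$fp_ms) |>
    dplyr::summarise(mean_rt = mean(.data$rt_ms), .groups = "drop")
  grp <- pm |>
    dplyr::group_by(.data$phase, .data$s1_type, .data$fp_ms) |>
    dplyr::summarise(mean_rt = mean(.data$mean_rt), n = dplyr::n(),
                     .groups = "drop")
  list(participant_means = pm, group = grp)
}

#' Cousineau-Morey within-subject confidence intervals
#'
#' Subject-centres the participant x condition means (`y' = y - participant
#' mean + grand mean`), then computes per-condition CI half-widths
#' `t(n-1, 1-alpha/2) * sd(y') / sqrt(n) * sqrt(M / (M-1))`, where M is the
#' number of conditions (the Morey bias correction). The normalization
#' preserves the grand mean and removes between-subject offset variance, so
#' the intervals reflect within-subject effects only.
#'
#' @param cell_means Tibble of participant x condition means with a
#'   `participant` column, a `mean_rt` value column and one row per
#'   participant x condition; every participant must have every condition.
#' @param value Name of the value column.
#' @param alpha CI level is `1 - alpha`.
#' @return The per-condition tibble with `mean`, `ci_half_width`, `n`, `M`.
#' @export
cousineau_morey_ci <- function(cell_means, value = "mean_rt", alpha = 0.05) {
  cond_cols <- setdiff(names(cell_means), c("participant", value))
  if (length(cond_cols) == 0) stop("input error: no condition columns", call. = FALSE)
  y <- cell_means[[value]]
  cond <- interaction(cell_means[cond_cols], drop = TRUE)
  n <- length(unique(cell_means$participant))
  M <- nlevels(cond)
  if (M < 2) stop("input error: need >= 2 conditions", call. = FALSE)
  counts <- table(cell_means$participant, cond)
  if (any(counts != 1)) {
    stop("input error: each participant must contribute exactly one mean per condition",
         call. = FALSE)
  }
  pmean <- stats::ave(y, cell_means$participant)
  y_norm <- y - pmean + mean(y)
  correction <- sqrt(M / (M - 1))
  out <- tibble::tibble(cell_means[cond_cols], .y = y_norm, .raw = y) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(cond_cols))) |>
    dplyr::summarise(
      mean = mean(.data$.raw),
      ci_half_width = stats::qt(1 - alpha / 2, n - 1) *
        stats::sd(.data$.y) / sqrt(n) * correction,
      .groups = "drop"
    )
  out$n <- n
  out$M <- M
  out
}

#' RT-FP curves by S1 type and phase with within-subject CIs
#'
#' @param trials Retained trials.
#' @param alpha Error bars show `1 - alpha` Cousineau-Morey intervals.
#' @return A ggplot object.
#' @export
plot_rt_fp <- function(trials, alpha = 0.05) {
  tab <- rt_fp_table(trials)
  ci <- cousineau_morey_ci(tab$participant_means, alpha = alpha)
  ggplot2::ggplot(ci, ggplot2::aes(x = .data$fp_ms, y = .data$mean,
                                   colour = .data$s1_type,
                                   group = .data$s1_type)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$ci_half_width,
                                          ymax = .data$mean + .data$ci_half_width)) +
    ggplot2::facet_wrap(~phase) +
    ggplot2::labs(x = "Foreperiod (ms)", y = "Mean RT (ms)",
                  colour = "S1 type") +
    ggplot2::theme_minimal()
}

#' Coefficient time courses with cluster annotations
#'
#' Plots the group-mean delta-beta series per coefficient with within-subject
#' 95% CI ribbons, vertical dashed lines at block breaks, and horizontal
#' segments marking significant clusters. Centers are plotted at the middle
#' of the sliding window, so the first and last trials of the experiment have
#' no values.
#'
#' @param timecourse Output of [to_delta()].
#' @param clusters Optional named list of [permutation_test()] results, one
#'   per coefficient, used to draw significant-cluster segments.
#' @param block_breaks Trial indices of block boundaries (default every 120
#'   trials up to the maximum center).
#' @param alpha Ribbon level is `1 - alpha`.
#' @return A ggplot object.
#' @export
plot_timecourse <- function(timecourse, clusters = NULL, block_breaks = NULL,
                            alpha = 0.05) {
  summ <- timecourse |>
    dplyr::group_by(.data$coefficient, .data$center_trial) |>
    dplyr::summarise(mean = mean(.data$delta_beta),
                     n = dplyr::n(), .groups = "drop")
  # within-subject (subject-centred) SE per coefficient
  norm <- timecourse |>
    dplyr::group_by(.data$participant, .data$coefficient) |>
    dplyr::mutate(.y = .data$delta_beta - mean(.data$delta_beta)) |>
    dplyr::group_by(.data$coefficient) |>
    dplyr::mutate(.y = .data$.y + mean(.data$delta_beta)) |>
    dplyr::group_by(.data$coefficient, .data$center_trial) |>
    dplyr::summarise(se = stats::sd(.data$.y) / sqrt(dplyr::n()), .groups = "drop")
  summ <- dplyr::left_join(summ, norm, by = c("coefficient", "center_trial"))
  crit <- stats::qt(1 - alpha / 2, max(summ$n) - 1)
  if (is.null(block_breaks)) {
    block_breaks <- seq(120, max(summ$center_trial), by = 120)
  }
  p <- ggplot2::ggplot(summ, ggplot2::aes(x = .data$center_trial, y = .data$mean)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = block_breaks, linetype = "dashed",
                        linewidth = 0.2) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - crit * .data$se,
                                      ymax = .data$mean + crit * .data$se),
                         alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~coefficient, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Trial (window center)",
                  y = expression(Delta * beta)) +
    ggplot2::theme_minimal()
  if (!is.null(clusters)) {
    segs <- dplyr::bind_rows(lapply(names(clusters), function(cf) {
      cl <- clusters[[cf]]
      if (nrow(cl) == 0) return(NULL)
      sig <- cl[cl$significant, , drop = FALSE]
      if (nrow(sig) == 0) return(NULL)
      tibble::tibble(coefficient = factor(cf, levels = levels(summ$coefficient)),
                     x = sig$start_center, xend = sig$end_center)
    }))
    if (nrow(segs) > 0) {
      p <- p + ggplot2::geom_segment(
        data = segs,
        ggplot2::aes(x = .data$x, xend = .data$xend, y = -Inf, yend = -Inf),
        inherit.aes = FALSE, linewidth = 2, colour = "orange")
    }
  }
  p
}
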