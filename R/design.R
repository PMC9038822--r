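#' Experimental design specification
#'
#' Describes the two-phase variable-foreperiod design: an Acquisition phase in
#' which one warning-stimulus (S1) category is paired with an exponential
#' foreperiod (FP) distribution and the other with its anti-exponential
#' mirror, followed by a Transfer phase in which both categories are paired
#' with a uniform FP distribution. Defaults reproduce the study design:
#' 6 Acquisition + 2 Transfer blocks of 120 trials, FPs of 300/600/900/1200 ms,
#' per-block FP counts 32/16/8/4 for the exponential type (reversed for the
#' anti-exponential type) and 15 per FP per type in Transfer.
#'
#' @param n_acquisition_blocks Number of Acquisition blocks.
#' @param n_transfer_blocks Number of Transfer blocks.
#' @param fp_levels_ms Ordered FP durations in milliseconds.
#' @param exp_counts_per_block Per-block trial counts at each FP level for the
#'   exponential S1 type; the anti-exponential type uses the reversed counts.
#' @param uniform_count_per_fp Per-block trials per FP per S1 type in Transfer.
#' @param categories Two S1 category labels; their assignment to the E/A types
#'   is counterbalanced across participants.
#' @param iti_range_ms Inter-trial interval range (uniformly sampled, carried
#'   as metadata only).
#'
#' @return An object of class `design_spec`.
#' @export
#' @examples
#' spec <- design_spec()
#' spec$exp_counts_per_block
design_spec <- function(n_acquisition_blocks = 6,
                        n_transfer_blocks = 2,
                        fp_levels_ms = c(300, 600, 900, 1200),
                        exp_counts_per_block = c(32, 16, 8, 4),
                        uniform_count_per_fp = 15,
                        categories = c("face", "scene"),
                        iti_range_ms = c(750, 1500)) {
  spec <- structure(
    list(
      n_acquisition_blocks = as.integer(n_acquisition_blocks),
      n_transfer_blocks = as.integer(n_transfer_blocks),
      fp_levels_ms = as.numeric(fp_levels_ms),
      exp_counts_per_block = as.integer(exp_counts_per_block),
      uniform_count_per_fp = as.integer(uniform_count_per_fp),
      categories = as.character(categories),
      iti_range_ms = as.numeric(iti_range_ms)
    ),
    class = "design_spec"
  )
  validate_design_spec(spec)
  spec
}

#' Validate a design specification
#'
#' Checks the internal balance constraints the generator relies on: count
#' vectors aligned with the FP levels, even per-type block totals (so S2 side
#' can be balanced left/right within each S1 type within each block), and
#' well-formed phase/ITI settings. Errors name the violated constraint.
#'
#' @param spec A `design_spec`.
#' @return `spec`, invisibly, if valid.
#' @export
validate_design_spec <- function(spec) {
  stopifnot(inherits(spec, "design_spec"))
  n_fp <- length(spec$fp_levels_ms)
  if (n_fp < 1 || anyDuplicated(spec$fp_levels_ms) > 0) {
    stop("design error: fp_levels_ms must be a non-empty set of distinct durations",
         call. = FALSE)
  }
  if (length(spec$exp_counts_per_block) != n_fp) {
    stop("design error: exp_counts_per_block must give one count per FP level",
         call. = FALSE)
  }
  if (any(spec$exp_counts_per_block < 0) || sum(spec$exp_counts_per_block) < 1) {
    stop("design error: exp_counts_per_block must be non-negative with a positive total",
         call. = FALSE)
  }
  if (spec$n_acquisition_blocks > 0 && sum(spec$exp_counts_per_block) %% 2 != 0) {
    stop(paste("design error: per-type Acquisition block total must be even",
               "so S2 side can be balanced within S1 type"), call. = FALSE)
  }
  if (spec$uniform_count_per_fp < 0 ||
      (spec$n_transfer_blocks > 0 && spec$uniform_count_per_fp < 1)) {
    stop("design error: uniform_count_per_fp must be positive when Transfer blocks exist",
         call. = FALSE)
  }
  if (spec$n_transfer_blocks > 0 && (n_fp * spec$uniform_count_per_fp) %% 2 != 0) {
    stop(paste("design error: per-type Transfer block total must be even",
               "so S2 side can be balanced within S1 type"), call. = FALSE)
  }
  if (spec$n_acquisition_blocks + spec$n_transfer_blocks < 1) {
    stop("design error: at least one block required", call. = FALSE)
  }
  if (length(spec$categories) != 2 || anyDuplicated(spec$categories) > 0) {
    stop("design error: exactly two distinct S1 categories required", call. = FALSE)
  }
  if (length(spec$iti_range_ms) != 2 || diff(spec$iti_range_ms) < 0 ||
      any(spec$iti_range_ms < 0)) {
    stop("design error: iti_range_ms must be a non-decreasing non-negative interval",
         call. = FALSE)
  }
  invisible(spec)
}

# Balanced (fp, side) multiset for one S1 type in one block; sides are
# assigned by random permutation so left/right counts are exactly equal
# within the type, then rows are later shuffled jointly with the other type.
type_block_rows <- function(spec, phase, s1_type) {
  counts <- switch(
    phase,
    Acquisition = if (s1_type == "E") spec$exp_counts_per_block else
      rev(spec$exp_counts_per_block),
    Transfer = rep(spec$uniform_count_per_fp, length(spec$fp_levels_ms))
  )
  fps <- rep(spec$fp_levels_ms, counts)
  n <- length(fps)
  sides <- sample(rep(c("left", "right"), n / 2))
  tibble::tibble(s1_type = s1_type, fp_ms = fps, s2_side = sides)
}

#' Generate balanced trial sequences for the two-phase design
#'
#' Builds, for each participant, the exact per-block multiset of
#' (FP, S1 type, S2 side) trials required by the design, shuffles trial order
#' jointly within each block, and assigns each trial a unique S1 image
#' identifier (each image is seen only once). The mapping from S1 category to
#' E/A type alternates across participants (odd participants: first category
#' is the exponential type).
#'
#' @param spec A [design_spec()].
#' @param n_participants Number of participants.
#' @param seed Integer RNG seed; the same seed yields a bit-identical table.
#'
#' @return A tibble with one row per trial and columns `participant`, `block`,
#'   `trial_index`, `phase`, `s1_category`, `s1_type`, `s1_image_id`, `fp_ms`,
#'   `iti_ms`, `s2_side`. Response columns are added by [simulate_rts()].
#' @export
#' @examples
#' d <- generate_design(design_spec(), n_participants = 1, seed = 1)
#' table(d$block)
generate_design <- function(spec = design_spec(), n_participants, seed) {
  validate_design_spec(spec)
  stopifnot(n_participants >= 1)
  phases <- c(rep("Acquisition", spec$n_acquisition_blocks),
              rep("Transfer", spec$n_transfer_blocks))
  withr::with_seed(as.integer(seed), {
    per_participant <- lapply(seq_len(n_participants), function(p) {
      # counterbalancing: odd participants map categories[1] -> E
      type_of <- if (p %% 2 == 1) {
        c(E = spec$categories[1], A = spec$categories[2])
      } else {
        c(E = spec$categories[2], A = spec$categories[1])
      }
      blocks <- lapply(seq_along(phases), function(b) {
        rows <- dplyr::bind_rows(
          type_block_rows(spec, phases[b], "E"),
          type_block_rows(spec, phases[b], "A")
        )
        rows <- rows[sample(nrow(rows)), ]
        rows$block <- b
        rows$phase <- phases[b]
        rows
      })
      out <- dplyr::bind_rows(blocks)
      out$participant <- p
      out$trial_index <- seq_len(nrow(out))
      out$s1_category <- unname(type_of[out$s1_type])
      out$s1_image_id <- out$trial_index
      out$iti_ms <- stats::runif(nrow(out), spec$iti_range_ms[1],
                                 spec$iti_range_ms[2])
      out
    })
    dplyr::bind_rows(per_participant)[, c(
      "participant", "block", "trial_index", "phase", "s1_category",
      "s1_type", "s1_image_id", "fp_ms", "iti_ms", "s2_side"
    )]
  })
}
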