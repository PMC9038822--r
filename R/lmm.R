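#' Prepare trials for mixed-model fitting
#'
#' Adds the coded predictors used by the model family: `fp_s` (FP in seconds,
#' centred at the grand mean of the data at hand, entering as a continuous
#' linear predictor), `s1_c` (-0.5 for E, +0.5 for A), `phase_c` (-0.5 for
#' Acquisition, +0.5 for Transfer) and, if absent, the inverse-RT response.
#'
#' @param trials Analysis-ready trial tibble.
#' @return The tibble with coded predictor columns.
#' @export
prepare_lmm_data <- function(trials) {
  if (!"inv_rt" %in% names(trials)) trials <- add_inverse_rt(trials)
  trials$fp_s <- (trials$fp_ms - mean(trials$fp_ms)) / 1000
  trials$s1_c <- s1_coded(trials$s1_type)
  trials$phase_c <- ifelse(trials$phase == "Transfer", 0.5, -0.5)
  trials$participant <- factor(trials$participant)
  trials
}

lmm_term_map <- c(
  "FP" = "fp_s", "S1type" = "s1_c", "Phase" = "phase_c",
  "FPxS1type" = "fp_s:s1_c", "FPxPhase" = "fp_s:phase_c",
  "S1typexPhase" = "s1_c:phase_c", "FPxS1typexPhase" = "fp_s:s1_c:phase_c"
)

lmm_required_mains <- list(
  "FPxS1type" = c("FP", "S1type"), "FPxPhase" = c("FP", "Phase"),
  "S1typexPhase" = c("S1type", "Phase"),
  "FPxS1typexPhase" = c("FP", "S1type", "Phase", "FPxS1type", "FPxPhase",
                        "S1typexPhase")
)

#' Fit one linear mixed model on inverse RT
#'
#' Fits inverse RT on the requested fixed terms with the study's fixed random
#' structure: a per-participant random intercept plus a correlated random FP
#' slope. Estimation is by maximum likelihood (not REML), because the fits
#' are compared across fixed-effect structures via BIC and likelihood ratios.
#' Interaction terms require their lower-order terms. Non-convergence and
#' singular fits are flagged, never silently dropped.
#'
#' @param data Output of [prepare_lmm_data()].
#' @param fixed_terms Character subset of `"FP"`, `"S1type"`, `"Phase"`,
#'   `"FPxS1type"`, `"FPxPhase"`, `"S1typexPhase"`, `"FPxS1typexPhase"`
#'   (the intercept is always included).
#' @param n_restarts Extra optimizer runs from jittered starts if the first
#'   fit fails to converge.
#' @return An object of class `lmm_fit`: `model` (the `lmerMod`), `formula`,
#'   `logLik`, `n_params` (fixed effects + 3 random-effect (co)variances +
#'   residual variance), `n_obs`, `bic`, `converged`, `singular`.
#' @export
fit_lmm <- function(data, fixed_terms = c("FP", "S1type", "FPxS1type"),
                    n_restarts = 3) {
  stopifnot(all(fixed_terms %in% names(lmm_term_map)))
  if (length(unique(data$participant)) < 2 || length(unique(data$s1_c)) < 2) {
    stop("input error: need >= 2 participants and both S1 types", call. = FALSE)
  }
  for (term in intersect(fixed_terms, names(lmm_required_mains))) {
    missing <- setdiff(lmm_required_mains[[term]], fixed_terms)
    if (length(missing)) {
      stop(sprintf("model spec error: %s requires lower-order term(s) %s",
                   term, paste(missing, collapse = ", ")), call. = FALSE)
    }
  }
  rhs <- paste(c("1", unname(lmm_term_map[fixed_terms])), collapse = " + ")
  form <- stats::as.formula(paste0("inv_rt ~ ", rhs, " + (1 + fp_s | participant)"))
  fit <- suppressWarnings(suppressMessages(lme4::lmer(form, data = data, REML = FALSE)))
  conv_ok <- function(m) {
    msgs <- unlist(m@optinfo$conv$lme4$messages)
    m@optinfo$conv$opt == 0 && !any(grepl("failed to converge", msgs))
  }
  attempt <- 0
  while (!conv_ok(fit) && attempt < n_restarts) {
    attempt <- attempt + 1
    start <- lme4::getME(fit, "theta") * stats::runif(3, 0.8, 1.2)
    fit <- suppressWarnings(suppressMessages(try(
      lme4::lmer(form, data = data, REML = FALSE, start = start),
      silent = TRUE)))
    if (inherits(fit, "try-error")) {
      fit <- suppressWarnings(suppressMessages(lme4::lmer(form, data = data, REML = FALSE)))
      break
    }
  }
  ll <- stats::logLik(fit)
  structure(
    list(model = fit, formula = form, fixed_terms = fixed_terms,
         logLik = as.numeric(ll), n_params = attr(ll, "df"),
         n_obs = stats::nobs(fit), bic = stats::BIC(fit),
         converged = conv_ok(fit), singular = lme4::isSingular(fit)),
    class = "lmm_fit"
  )
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat("Linear mixed model (ML) on inverse RT\n")
  cat("  fixed terms:", paste(x$fixed_terms, collapse = ", "), "\n")
  cat(sprintf("  logLik %.2f | BIC %.2f | params %d | n %d\n",
              x$logLik, x$bic, x$n_params, x$n_obs))
  if (!x$converged) cat("  WARNING: fit did not converge\n")
  if (x$singular) cat("  note: singular random-effects fit\n")
  invisible(x)
}

#' Convert a BIC difference to an estimated Bayes factor
#'
#' Applies the BIC approximation `BF = exp(delta_bic / 2)`. By convention a
#' positive `delta_bic` (the richer model has the lower BIC) is evidence for
#' including the term and reported as BF > 1; a negative `delta_bic` is
#' evidence against inclusion and reported as the inverse Bayes factor
#' 1/BF > 1. Values above 1000 print as "> 1000" while the exact value is
#' retained.
#'
#' @param delta_bic Finite BIC difference, signed so positive favours the
#'   richer model.
#' @return An object of class `bf_evidence`: `delta_bic`, `bf` (raw
#'   `exp(delta_bic/2)`), `evidence` (`exp(|delta_bic|/2)`, the reported BF or
#'   1/BF), `direction` (`"for_inclusion"`/`"against_inclusion"`).
#' @export
#' @examples
#' bic_to_bf(-3.02)$evidence # ~4.53, reported as 1/BF
bic_to_bf <- function(delta_bic) {
  stopifnot(is.finite(delta_bic))
  structure(
    list(delta_bic = delta_bic,
         bf = exp(delta_bic / 2),
         evidence = exp(abs(delta_bic) / 2),
         direction = if (delta_bic >= 0) "for_inclusion" else "against_inclusion"),
    class = "bf_evidence"
  )
}

#' @export
format.bf_evidence <- function(x, ...) {
  label <- if (x$direction == "for_inclusion") "BF" else "1/BF"
  value <- if (x$evidence > 1000) "> 1000" else sprintf("= %.2f", x$evidence)
  sprintf("dBIC = %.2f; %s %s", x$delta_bic, label, value)
}

#' @export
print.bf_evidence <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Compare a richer against a reduced mixed model by BIC
#'
#' @param fit_rich,fit_reduced `lmm_fit` objects for nested models fit to the
#'   same data; `fit_rich` contains the term(s) under test.
#' @param name_rich,name_reduced Labels for the report.
#' @return A one-row tibble: names, BICs, `delta_bic` (reduced minus richer,
#'   so positive = evidence for the richer model), `bf`, `direction`,
#'   `evidence_label`, convergence flags.
#' @export
compare_models <- function(fit_rich, fit_reduced,
                           name_rich = paste(fit_rich$fixed_terms, collapse = "+"),
                           name_reduced = paste(fit_reduced$fixed_terms, collapse = "+")) {
  stopifnot(inherits(fit_rich, "lmm_fit"), inherits(fit_reduced, "lmm_fit"))
  if (fit_rich$n_obs != fit_reduced$n_obs) {
    stop("input error: models were fit to different numbers of observations",
         call. = FALSE)
  }
  delta <- fit_reduced$bic - fit_rich$bic
  ev <- bic_to_bf(delta)
  tibble::tibble(
    name_a = name_rich, name_b = name_reduced,
    bic_a = fit_rich$bic, bic_b = fit_reduced$bic,
    delta_bic = delta, bf = ev$evidence, direction = ev$direction,
    evidence_label = format(ev),
    converged = fit_rich$converged && fit_reduced$converged,
    singular = fit_rich$singular || fit_reduced$singular
  )
}

#' Likelihood-ratio test between nested mixed-model fits
#'
#' @inheritParams compare_models
#' @return A list with `statistic` (2 x log-likelihood difference), `df`
#'   (number of dropped fixed-effect terms) and `p_value`.
#' @export
lrt <- function(fit_rich, fit_reduced) {
  stopifnot(inherits(fit_rich, "lmm_fit"), inherits(fit_reduced, "lmm_fit"))
  stat <- 2 * (fit_rich$logLik - fit_reduced$logLik)
  df <- fit_rich$n_params - fit_reduced$n_params
  list(statistic = stat, df = df,
       p_value = stats::pchisq(max(stat, 0), df = df, lower.tail = FALSE))
}
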