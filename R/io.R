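trial_columns <- c("participant", "block", "trial_index", "phase",
                   "s1_category", "s1_type", "fp_ms", "s2_side",
                   "response", "rt_ms", "correct")

#' Write a trial table to CSV with a provenance sidecar
#'
#' Writes the canonical trial columns (UTF-8, '.' decimal separator) and, if
#' `seed` is given, an adjacent `<path>.json` sidecar recording the seed and
#' basic provenance.
#'
#' @param trials Completed trial tibble.
#' @param path Output CSV path.
#' @param seed Optional integer seed to record.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path, seed = NULL) {
  cols <- intersect(trial_columns, names(trials))
  readr::write_csv(trials[cols], path)
  if (!is.null(seed)) {
    jsonlite::write_json(
      list(seed = seed,
           n_participants = length(unique(trials$participant)),
           n_trials = nrow(trials),
           created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
      paste0(path, ".json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' Read a trial table written by [write_trials()]
#'
#' @param path CSV path.
#' @return A trial tibble with typed columns.
#' @export
read_trials <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    participant = readr::col_integer(), block = readr::col_integer(),
    trial_index = readr::col_integer(), phase = readr::col_character(),
    s1_category = readr::col_character(), s1_type = readr::col_character(),
    fp_ms = readr::col_double(), s2_side = readr::col_character(),
    response = readr::col_character(), rt_ms = readr::col_double(),
    correct = readr::col_logical()
  ))
}

#' Read a design spec and generative parameters from a YAML config
#'
#' The YAML file may hold a `design:` block (fields of [design_spec()]) and a
#' `params:` block (fields of [generative_params()]); missing fields take the
#' defaults.
#'
#' @param path YAML file path.
#' @return A list with `spec` and `params`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  spec <- do.call(design_spec, cfg$design %||% list())
  params <- do.call(generative_params, cfg$params %||% list())
  list(spec = spec, params = params)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
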