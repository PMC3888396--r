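# Plain-text interchange: planning datasets as CSV, simulated datasets as
# long/wide CSV, scenario grids as YAML.

#' Write a planning dataset to CSV
#'
#' Columns `group`, `pattern_bits` (responses to items 1..J, left to
#' right), `expected_frequency`.
#'
#' @param planning A tibble from [build_planning_dataset()].
#' @param path Output file.
#'
#' @return Invisibly, `path`.
#' @export
write_planning_csv <- function(planning, path) {
  planning |>
    dplyr::transmute(group = .data$group, pattern_bits = .data$bits,
                     expected_frequency = .data$expected_frequency) |>
    readr::write_csv(path)
  invisible(path)
}

#' Write a simulated dataset to CSV
#'
#' @param data A tibble from [simulate_dataset()].
#' @param path Output file.
#' @param format `"long"` (subject, group, item, response) or `"wide"`
#'   (one row per subject).
#'
#' @return Invisibly, `path`.
#' @export
write_sim_csv <- function(data, path, format = c("long", "wide")) {
  format <- match.arg(format)
  out <- if (format == "long") sim_to_long(data) else data
  readr::write_csv(out, path)
  invisible(path)
}

#' Read a scenario specification from YAML
#'
#' Expected keys: `ng`, `j`, `gamma`, `shape` (each scalar or list, crossed
#' into a grid as in [scenario_grid()]) and optional `reps` and `seed`.
#'
#' @param path Path to a YAML file.
#'
#' @return A list with elements `grid` (tibble), `reps`, `seed`.
#' @export
read_scenario_yaml <- function(path) {
  spec <- yaml::read_yaml(path)
  for (key in c("ng", "j", "gamma", "shape")) {
    if (is.null(spec[[key]])) abort(sprintf("scenario YAML is missing `%s`", key))
  }
  list(
    grid = scenario_grid(ng = unlist(spec$ng), j = unlist(spec$j),
                         gamma = unlist(spec$gamma),
                         shape = unlist(spec$shape)),
    reps = spec$reps %||% 1000,
    seed = spec$seed %||% 1
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
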