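# Package configuration: every tunable constant of the pipeline in one
# declarative structure, overridable from a plain key = value text file.

#' Default pipeline configuration
#'
#' Returns the full set of tunable constants as a nested list:
#'
#' * `spike`: spike-detector settings — `mad_mult` (deviation threshold in
#'   MADs of the indentation residuals), `min_run` (minimum run length in
#'   points), `median_window` (running-median window), `abs_floor`
#'   (absolute deviation floor as a fraction of the maximum force, so that
#'   numerically flat residual series report no spikes).
#' * `filter`: log-filter scale applied to unbounded features,
#'   `x -> log(1 + scale * x)`.
#' * `binary`: usability filter bounds — `min_points` (minimum combined
#'   approach + indentation size) and `max_spikes`.
#' * `penalty`: procedural-rating constants of [ground_truth_rating]
#'   (`a_spike`, `a_tilt`, `a_offset`, `a_noise` and the reference
#'   magnitudes `tilt0` \[N/m\], `noise0`).
#' * `generator`: synthetic-population settings — artifact inclusion
#'   probability, log-uniform severity range (penalty units), noise floor,
#'   and the modulus range \[Pa\].
#' * `rater`: regressor defaults — `num_trees`, `threshold`.
#'
#' @param path optional path to a `key = value` override file (see
#'   [read_fd_config]).
#' @return A nested configuration list.
#' @export
fd_config <- function(path = NULL) {
  cfg <- list(
    spike = list(mad_mult = 5, min_run = 3L, median_window = 25L,
                 abs_floor = 1e-4),
    filter = list(scale = 100),
    binary = list(min_points = 600L, max_spikes = 5L),
    penalty = list(a_spike = 16, a_tilt = 5, a_offset = 25, a_noise = 5,
                   tilt0 = 1e-4, noise0 = 0.1),
    generator = list(p_include = 0.65, severity_min = 0.05,
                     severity_max = 8, noise_floor = 0.005,
                     E_min = 200, E_max = 5000),
    rater = list(num_trees = 100L, threshold = 4.5)
  )
  if (!is.null(path)) cfg <- utils::modifyList(cfg, read_fd_config(path))
  cfg
}

#' Read a configuration override file
#'
#' Plain declarative text: `[section]` headers followed by `key = value`
#' lines; values are parsed as numbers when possible. Lines starting with
#' `#` and blank lines are ignored.
#'
#' @param path file path.
#' @return A nested list mirroring the [fd_config] structure.
#' @export
read_fd_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  section <- NULL
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      if (is.null(out[[section]])) out[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      if (is.null(section)) stop("config values must appear under a [section]")
      eq <- regexpr("=", ln, fixed = TRUE)
      key <- trimws(substr(ln, 1, eq - 1))
      val <- trimws(substr(ln, eq + 1, nchar(ln)))
      num <- suppressWarnings(as.numeric(val))
      out[[section]][[key]] <- if (is.na(num)) val else num
    } else stop(sprintf("cannot parse config line: '%s'", ln))
  }
  out
}
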