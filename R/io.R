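# Trial tables travel as plain CSV. Required columns: participant_id,
# target_angle (deg, [0, 360)), target_radius (cm), reach_angle (deg).
# Optional: hand, experiment, block, feedback, endpoint_x, endpoint_y.
# Unknown columns are preserved on a round trip.

REQUIRED_TRIAL_COLS <- c("participant_id", "target_angle", "target_radius",
                         "reach_angle")

validate_trials <- function(trials, context = "trial table") {
  missing <- setdiff(REQUIRED_TRIAL_COLS, names(trials))
  if (length(missing)) {
    stop(sprintf("%s is missing required column(s): %s", context,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  bad <- which(!is.finite(trials$reach_angle) |
                 !is.finite(trials$target_angle) |
                 trials$target_angle < 0 | trials$target_angle >= 360 |
                 !is.finite(trials$target_radius) | trials$target_radius <= 0)
  if (length(bad)) {
    stop(sprintf(
      "%s has %d malformed row(s) (non-finite angles, target_angle outside [0, 360), or non-positive radius); first offending rows: %s",
      context, length(bad),
      paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  invisible(trials)
}

#' Read a trial table from CSV
#'
#' @param path Path to a CSV file with the documented column schema; unknown
#'   columns are preserved.
#' @return A validated trial table `data.frame`.
#' @export
read_trials <- function(path) {
  trials <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("feedback" %in% names(trials)) {
    trials$feedback <- as.logical(trials$feedback)
  }
  validate_trials(trials, context = sprintf("'%s'", path))
}

#' Write a trial table to CSV
#'
#' @param trials A trial table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  validate_trials(trials)
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' Write a bias function to CSV
#'
#' Columns `angle_deg`, `angular_bias_deg` and, when present,
#' `radial_bias_cm`.
#'
#' @param bias A `bias_fn`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bias <- function(bias, path) {
  stopifnot(inherits(bias, "bias_fn"))
  utils::write.csv(as.data.frame(bias), path, row.names = FALSE)
  invisible(path)
}
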