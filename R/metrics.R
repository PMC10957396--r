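#' Per-trial proportional linear and angular errors
#'
#' The proportional linear error is the length of the performed inbound
#' path (cone 3 to the response) divided by the length of the correct
#' inbound path (cone 3 to cone 1); it is absent for out-of-bound trials,
#' whose distance is uninformative. The proportional angular error is the
#' produced egocentric turn divided by the correct inbound turn, both
#' wrapped to `[0, 2*pi)` under the anticlockwise convention; out-of-bound
#' trials contribute it via their boundary-hit direction. A value of 1 is
#' perfect; ratios above 1 are over-shooting / over-turning.
#'
#' @param std standardised trials from [standardize_trials()].
#' @return `std` with columns `prop_linear_error` and
#'   `prop_angular_error` appended.
#' @export
trial_errors <- function(std) {
  if (any(std$correct_angle <= 0, na.rm = TRUE)) {
    stop("correct inbound angle must be positive for a valid triangle")
  }
  std$prop_linear_error <- ifelse(std$oob, NA_real_, std$l3 / std$correct_dist)
  std$prop_angular_error <- std$theta3 / std$correct_angle
  std
}

#' Participant and group summaries of the behavioural errors
#'
#' Aggregation follows the trial -> participant-condition mean ->
#' participant mean (across conditions, unweighted) -> group mean/SD
#' ladder. Out-of-bound trials are excluded from the linear-error means
#' (never imputed; the denominator is the count of defined values) and the
#' per-participant out-of-bound ratio is reported alongside.
#'
#' @param errors output of [trial_errors()].
#' @param max_trials_per_condition optionally restrict each
#'   participant-condition cell to its first n trials (used to put the
#'   young group, who completed more trials, on the same footing).
#' @return List of tibbles: `cells` (participant x condition means),
#'   `participants` (condition-averaged), `groups` (group mean/SD).
#' @export
summarize_errors <- function(errors, max_trials_per_condition = NULL) {
  df <- errors
  if (!is.null(max_trials_per_condition)) {
    df <- df |>
      dplyr::group_by(participant_id, condition) |>
      dplyr::arrange(trial_index, .by_group = TRUE) |>
      dplyr::slice_head(n = max_trials_per_condition) |>
      dplyr::ungroup()
  }
  cells <- df |>
    dplyr::group_by(participant_id, group, condition) |>
    dplyr::summarise(
      mean_ple = mean(prop_linear_error, na.rm = TRUE),
      mean_pae = mean(prop_angular_error, na.rm = TRUE),
      oob_ratio = mean(oob),
      n_trials = dplyr::n(),
      .groups = "drop"
    )
  participants <- cells |>
    dplyr::group_by(participant_id, group) |>
    dplyr::summarise(
      mean_ple = mean(mean_ple, na.rm = TRUE),
      mean_pae = mean(mean_pae, na.rm = TRUE),
      oob_ratio = mean(oob_ratio),
      .groups = "drop"
    )
  groups <- participants |>
    dplyr::group_by(group) |>
    dplyr::summarise(
      ple_mean = mean(mean_ple, na.rm = TRUE),
      ple_sd = stats::sd(mean_ple),
      pae_mean = mean(mean_pae, na.rm = TRUE),
      pae_sd = stats::sd(mean_pae),
      oob_ratio = mean(oob_ratio),
      n = dplyr::n(),
      .groups = "drop"
    )
  list(cells = cells, participants = participants, groups = groups)
}
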