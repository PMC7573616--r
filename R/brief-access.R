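#' Keep only valid (intraburst) interlick intervals
#'
#' Retains ILIs strictly inside the open interval
#' (`lower`, `upper`) — by default greater than 50 ms and less than 200 ms —
#' the window that isolates the stereotyped within-burst lick rhythm from
#' pauses and double-contact artefacts. Both boundaries are excluded.
#'
#' @param ilis Numeric vector of interlick intervals in seconds.
#' @param lower,upper Open-interval bounds in seconds.
#' @return The retained ILIs, order preserved. Errors if none survive (an
#'   unusable training session).
#' @export
filter_valid_ilis <- function(ilis, lower = 0.050, upper = 0.200) {
  if (!length(ilis) || !is.numeric(ilis))
    abort("`ilis` must be a non-empty numeric vector",
          class = "lickometry_validation_error")
  if (any(ilis <= 0))
    abort("interlick intervals must be positive",
          class = "lickometry_validation_error")
  out <- ilis[ilis > lower & ilis < upper]
  if (!length(out))
    abort(sprintf("no interlick intervals inside (%g, %g) s: unusable training data",
                  lower, upper),
          class = "lickometry_validation_error")
  out
}

#' Maximum potential lick rate
#'
#' The number of licks a subject could emit in a trial if it licked at its
#' baseline intraburst rhythm for the whole trial: trial duration divided by
#' the mean valid training ILI. Not rounded.
#'
#' @param trial_duration_s Trial duration in seconds.
#' @param mean_valid_ili_s Mean valid ILI in seconds; vectorized.
#' @return Licks per trial (real).
#' @export
max_potential_lick_rate <- function(trial_duration_s, mean_valid_ili_s) {
  if (any(!is.finite(trial_duration_s)) || any(trial_duration_s <= 0))
    abort("`trial_duration_s` must be strictly positive",
          class = "lickometry_validation_error")
  if (any(!is.finite(mean_valid_ili_s)) || any(mean_valid_ili_s <= 0))
    abort("`mean_valid_ili_s` must be strictly positive",
          class = "lickometry_validation_error")
  trial_duration_s / mean_valid_ili_s
}

#' Standardized lick ratio
#'
#' Trial lick count (or mean count) divided by the subject's maximum
#' potential lick rate. Normalizes licking for individual differences in the
#' baseline lick rhythm, independent of motivational state. Values above 1
#' (licking faster than during training) are allowed and reported with a
#' note, not clipped.
#'
#' @param mean_licks Mean licks per trial (>= 0); vectorized.
#' @param max_potential Maximum potential lick rate (> 0).
#' @return Dimensionless ratio(s).
#' @export
standardized_lick_ratio <- function(mean_licks, max_potential) {
  if (any(!is.finite(max_potential)) || any(max_potential <= 0))
    abort("`max_potential` must be strictly positive",
          class = "lickometry_validation_error")
  if (any(mean_licks < 0, na.rm = TRUE))
    abort("`mean_licks` must be non-negative",
          class = "lickometry_validation_error")
  ratio <- mean_licks / max_potential
  if (any(ratio > 1, na.rm = TRUE))
    inform(sprintf("%d standardized lick ratio(s) exceed 1 (licking above the training rate)",
                   sum(ratio > 1, na.rm = TRUE)))
  ratio
}

#' Per-subject baselines from water training
#'
#' Pools all water-training sessions per subject, computes ILIs, keeps the
#' valid (50-200 ms exclusive) ones, and derives each subject's mean valid
#' ILI and maximum potential lick rate for the given trial duration.
#'
#' @param training_events Lick-event tibble with
#'   `session_type == "water_training"` rows.
#' @param trial_duration_s Trial duration the maximum potential rate refers
#'   to (seconds).
#' @param lower,upper Valid-ILI bounds passed to [filter_valid_ilis()].
#' @return A tibble: `subject_id`, `mean_valid_ili`, `n_valid_ilis`,
#'   `max_potential_licks`.
#' @export
compute_baselines <- function(training_events, trial_duration_s = 15,
                              lower = 0.050, upper = 0.200) {
  ev <- validate_lick_events(training_events)
  ev <- ev[ev$session_type == "water_training", ]
  if (!nrow(ev))
    abort("no water-training events supplied", class = "lickometry_validation_error")
  ev |>
    dplyr::group_by(.data$subject_id, .data$session_id) |>
    dplyr::reframe(ili = diff(.data$timestamp_ms) / 1000) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      mean_valid_ili = mean(filter_valid_ilis(.data$ili, lower, upper)),
      n_valid_ilis = length(filter_valid_ilis(.data$ili, lower, upper)),
      .groups = "drop"
    ) |>
    dplyr::mutate(max_potential_licks =
                    max_potential_lick_rate(trial_duration_s, .data$mean_valid_ili))
}

#' Summarize brief-access trials into standardized lick ratios
#'
#' Averages lick counts over the (conventionally three) block presentations
#' of each stimulus for each subject, then divides by the subject's maximum
#' potential lick rate. Non-initiated trials are excluded from the average —
#' treated as missing, not zero — and `n_trials_used` records how many trials
#' entered each mean.
#'
#' @param trial_results Per-trial tibble from [assemble_trials()].
#' @param baselines Per-subject baselines from [compute_baselines()].
#' @param by_session Keep sessions (test days) separate (`TRUE`) or average
#'   over them (default `FALSE`).
#' @return A tibble: `subject_id`, `group`, `tastant`, `concentration`,
#'   `mean_licks`, `n_trials_used`, `slr` (plus `session_id` when
#'   `by_session`).
#' @export
summarize_brief_access <- function(trial_results, baselines,
                                   by_session = FALSE) {
  tr <- as_tibble(trial_results)
  bl <- as_tibble(baselines)
  missing <- setdiff(unique(tr$subject_id), bl$subject_id)
  if (length(missing))
    abort(paste0("no baseline for subject(s): ", paste(missing, collapse = ", ")),
          class = "lickometry_validation_error")
  keys <- c("subject_id", "group",
            if (by_session) "session_id",
            "tastant", "concentration")
  tr |>
    dplyr::filter(.data$initiated) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(mean_licks = mean(.data$n_licks),
                     n_trials_used = dplyr::n(), .groups = "drop") |>
    dplyr::left_join(bl[c("subject_id", "max_potential_licks")],
                     by = "subject_id") |>
    dplyr::mutate(slr = standardized_lick_ratio(.data$mean_licks,
                                                .data$max_potential_licks)) |>
    dplyr::select(dplyr::all_of(keys), "mean_licks", "n_trials_used", "slr")
}
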