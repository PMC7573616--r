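lick_event_columns <- c("subject_id", "group", "session_id", "session_type",
                        "trial_id", "tastant", "concentration_value",
                        "concentration_unit", "timestamp_ms")

#' Validate a lick-event table
#'
#' Checks the standard event schema: required columns present, timestamps
#' integer milliseconds, and strictly increasing within every
#' (subject, session) pair — duplicated or backward timestamps are rejected
#' with the offending row index.
#'
#' @param events A data frame of lick events.
#' @return The events as a tibble, invisibly valid.
#' @export
validate_lick_events <- function(events) {
  events <- as_tibble(events)
  missing <- setdiff(lick_event_columns, names(events))
  if (length(missing))
    abort(paste0("lick-event table is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "lickometry_schema_error")
  ts <- events$timestamp_ms
  if (!is.numeric(ts) || any(!is.finite(ts)))
    abort("timestamp_ms must be finite numbers", class = "lickometry_validation_error")
  if (any(ts != round(ts)))
    abort("timestamp_ms must be integer milliseconds (sub-ms values are rejected, not rounded)",
          class = "lickometry_validation_error")
  key <- paste(events$subject_id, events$session_id, sep = "\r")
  for (k in unique(key)) {
    idx <- which(key == k)
    d <- diff(ts[idx])
    bad <- which(d <= 0)
    if (length(bad))
      abort(sprintf(
        "timestamps not strictly increasing for subject '%s', session '%s' at row %d",
        events$subject_id[idx[1]], events$session_id[idx[1]], idx[bad[1] + 1L]),
        class = "lickometry_validation_error")
  }
  events$timestamp_ms <- as.integer(ts)
  events
}

#' Read lick events from CSV
#'
#' Reads a timestamped lick-event table (one row per lick) and validates it
#' with [validate_lick_events()]. Rows are kept in file order; sessions are
#' identified by the (subject_id, session_id) pair.
#'
#' @param path Path to a CSV file with the standard event columns.
#' @return A validated tibble of lick events.
#' @export
read_lick_events <- function(path) {
  events <- readr::read_csv(path, show_col_types = FALSE,
                            col_types = readr::cols(
                              subject_id = readr::col_character(),
                              group = readr::col_character(),
                              session_id = readr::col_character(),
                              session_type = readr::col_character(),
                              trial_id = readr::col_character(),
                              tastant = readr::col_character(),
                              concentration_value = readr::col_double(),
                              concentration_unit = readr::col_character(),
                              timestamp_ms = readr::col_double(),
                              .default = readr::col_guess()
                            ))
  validate_lick_events(events)
}

#' Write lick events to CSV
#'
#' @param events A lick-event tibble.
#' @param path Output path.
#' @return `events`, invisibly.
#' @export
write_lick_events <- function(events, path) {
  events <- validate_lick_events(events)
  readr::write_csv(events[lick_event_columns], path)
  invisible(events)
}

#' Read / write brief-access trial windows
#'
#' Trial windows record when each stimulus access started; the first lick and
#' the trial window itself are reconstructed from the event stream by
#' [assemble_trials()].
#'
#' @param path CSV path.
#' @param trials A trial-window tibble (`subject_id`, `session_id`,
#'   `trial_id`, `tastant`, `concentration`, `access_start_ms`, ...).
#' @return A tibble of trial windows (read) or `trials` invisibly (write).
#' @export
read_trial_windows <- function(path) {
  tw <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("subject_id", "session_id", "trial_id", "tastant",
            "concentration", "access_start_ms")
  missing <- setdiff(need, names(tw))
  if (length(missing))
    abort(paste0("trial-window table is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "lickometry_schema_error")
  tw
}

#' @rdname read_trial_windows
#' @export
write_trial_windows <- function(trials, path) {
  readr::write_csv(as_tibble(trials), path)
  invisible(trials)
}

#' Assemble per-trial records from a brief-access event stream
#'
#' For every trial window: the first lick within `initiation_limit_s` of
#' access start defines the trial onset; licks are then counted in the
#' half-open window `[first_lick, first_lick + trial_duration_s)` — a lick
#' exactly at the closing boundary is excluded. Latency is first lick minus
#' access start. Trials with no lick within the initiation limit are flagged
#' non-initiated and their lick count is missing (`NA`), not zero. Licks that
#' fall outside every trial window raise a warning and are ignored.
#'
#' @param events A validated lick-event tibble (`session_type`
#'   `"brief_access"`).
#' @param trials Trial windows as from [trial_windows()] or
#'   [read_trial_windows()].
#' @param trial_duration_s Trial duration after the first lick (seconds).
#' @param initiation_limit_s Time allowed to initiate (seconds).
#' @return A tibble with one row per trial: `subject_id`, `group`,
#'   `session_id`, `trial_id`, `tastant`, `concentration`, `initiated`,
#'   `latency_s`, `n_licks`, `mean_ili_s`, `n_ilis`.
#' @export
assemble_trials <- function(events, trials, trial_duration_s = 15,
                            initiation_limit_s = 30) {
  events <- validate_lick_events(events)
  trials <- as_tibble(trials)
  check_number(trial_duration_s, "trial_duration_s", min = 0)
  check_number(initiation_limit_s, "initiation_limit_s", min = 0)
  dur_ms <- round(trial_duration_s * 1000)
  init_ms <- round(initiation_limit_s * 1000)

  if (!("group" %in% names(trials))) {
    grp <- dplyr::distinct(events, .data$subject_id, .data$group)
    trials <- dplyr::left_join(trials, grp, by = "subject_id")
  }

  key_ev <- paste(events$subject_id, events$session_id, sep = "\r")
  key_tr <- paste(trials$subject_id, trials$session_id, sep = "\r")
  sessions <- unique(key_tr)
  n_outside <- 0L
  out <- vector("list", length(sessions))
  for (i in seq_along(sessions)) {
    k <- sessions[i]
    tw <- trials[key_tr == k, ]
    tw <- tw[order(tw$access_start_ms), ]
    ts <- events$timestamp_ms[key_ev == k]
    used <- logical(length(ts))
    nt <- nrow(tw)
    initiated <- logical(nt); latency <- rep(NA_real_, nt)
    n_licks <- rep(NA_integer_, nt); mean_ili <- rep(NA_real_, nt)
    n_ilis <- integer(nt)
    for (j in seq_len(nt)) {
      start <- tw$access_start_ms[j]
      cand <- ts[ts >= start & ts < start + init_ms]
      if (!length(cand)) next
      first <- cand[1]
      in_win <- ts >= first & ts < first + dur_ms
      used <- used | in_win
      w <- ts[in_win]
      ilis <- diff(w) / 1000
      initiated[j] <- TRUE
      latency[j] <- (first - start) / 1000
      n_licks[j] <- length(w)
      mean_ili[j] <- if (length(ilis)) mean(ilis) else NA_real_
      n_ilis[j] <- length(ilis)
    }
    n_outside <- n_outside + sum(!used)
    out[[i]] <- tibble::new_tibble(list(
      subject_id = rep(tw$subject_id[1], nt),
      group = rep(tw$group[1], nt),
      session_id = rep(tw$session_id[1], nt),
      trial_id = tw$trial_id, tastant = tw$tastant,
      concentration = tw$concentration, initiated = initiated,
      latency_s = latency, n_licks = n_licks, mean_ili_s = mean_ili,
      n_ilis = n_ilis), nrow = nt)
  }
  if (n_outside > 0)
    warn(sprintf("%d lick(s) fell outside every trial window and were ignored",
                 n_outside))
  dplyr::bind_rows(out)
}
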