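as_timestamps_ms <- function(licks) {
  if (is.data.frame(licks)) {
    if (!("timestamp_ms" %in% names(licks)))
      abort("lick table needs a `timestamp_ms` column",
            class = "lickometry_validation_error")
    licks <- licks$timestamp_ms
  }
  if (!is.numeric(licks))
    abort("licks must be numeric timestamps (ms)",
          class = "lickometry_validation_error")
  if (length(licks) && is.unsorted(licks, strictly = TRUE))
    abort("lick timestamps must be strictly increasing",
          class = "lickometry_validation_error")
  as.numeric(licks)
}

#' Segment a lick stream into meals
#'
#' A meal is initiated by `init_count` licks within `init_window_s` seconds —
#' the onset is the earliest lick `i` (searching forward from the end of the
#' previous meal) with `t[i + init_count - 1] - t[i] <= init_window_s` — and
#' is terminated by a pause of at least `termination_pause_s` seconds (or the
#' end of the session). Licks that never take part in a qualifying initiation
#' run belong to no meal (orphans).
#'
#' @param licks Strictly increasing lick timestamps in ms, or a data frame
#'   with a `timestamp_ms` column (one session).
#' @param init_count Licks required to initiate a meal.
#' @param init_window_s Window (seconds) the initiating licks must span.
#' @param termination_pause_s Pause (seconds) that terminates a meal;
#'   threshold-inclusive (a gap exactly equal terminates).
#' @return A tibble with one row per meal: `meal_id`, `onset_ms`,
#'   `offset_ms`, `n_licks`, `duration_s`, `start_idx`, `end_idx`. The
#'   per-lick meal assignment (NA for orphans) is attached as attribute
#'   `"assignment"`.
#' @export
segment_meals <- function(licks, init_count = 5, init_window_s = 1,
                          termination_pause_s = 600) {
  t <- as_timestamps_ms(licks)
  check_number(init_count, "init_count", min = 1, strict = FALSE)
  check_number(init_window_s, "init_window_s", min = 0)
  check_number(termination_pause_s, "termination_pause_s", min = 0)
  ic <- as.integer(init_count)
  win_ms <- init_window_s * 1000
  term_ms <- termination_pause_s * 1000
  n <- length(t)

  empty <- tibble(meal_id = integer(), onset_ms = numeric(),
                  offset_ms = numeric(), n_licks = integer(),
                  duration_s = numeric(), start_idx = integer(),
                  end_idx = integer())
  assignment <- rep(NA_integer_, n)
  if (n < ic) {
    attr(empty, "assignment") <- assignment
    return(empty)
  }

  # spans[i] = time covered by the run of ic licks starting at lick i
  spans <- t[ic:n] - t[seq_len(n - ic + 1L)]
  gaps <- c(diff(t), Inf)   # gap after each lick; Inf closes the session

  rows <- list()
  i <- 1L
  meal_id <- 0L
  while (i <= n - ic + 1L) {
    qual <- which(spans[i:(n - ic + 1L)] <= win_ms)
    if (!length(qual)) break
    onset <- i + qual[1L] - 1L
    after <- which(gaps[onset:n] >= term_ms)
    end <- onset + after[1L] - 1L
    meal_id <- meal_id + 1L
    assignment[onset:end] <- meal_id
    rows[[meal_id]] <- tibble(
      meal_id = meal_id, onset_ms = t[onset], offset_ms = t[end],
      n_licks = end - onset + 1L, duration_s = (t[end] - t[onset]) / 1000,
      start_idx = onset, end_idx = end
    )
    i <- end + 1L
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else empty
  attr(out, "assignment") <- assignment
  out
}

#' Per-lick meal assignment
#'
#' @param meals A meal tibble from [segment_meals()].
#' @return Integer vector, one element per input lick; `NA` marks orphans.
#' @export
lick_assignments <- function(meals) attr(meals, "assignment")

#' Segment meal licks into bursts
#'
#' Within a meal, an interlick interval strictly greater than `pause_s`
#' seconds closes the current burst and opens the next; an ILI exactly equal
#' to the threshold stays in the same burst. Every meal lick belongs to
#' exactly one burst. A single-lick burst has duration 0.
#'
#' @param licks The session's lick timestamps (ms) or data frame, as passed
#'   to [segment_meals()].
#' @param meals The meal tibble from [segment_meals()] on the same licks, or
#'   `NULL` to treat the whole stream as one meal.
#' @param pause_s Burst-closing pause threshold in seconds (strict).
#' @return A tibble with one row per burst: `meal_id`, `burst_id`,
#'   `start_ms`, `end_ms`, `n_licks`, `duration_s`.
#' @export
segment_bursts <- function(licks, meals = NULL, pause_s = 1) {
  t <- as_timestamps_ms(licks)
  check_number(pause_s, "pause_s", min = 0)
  pause_ms <- pause_s * 1000
  if (is.null(meals)) {
    meals <- tibble(meal_id = 1L, start_idx = 1L, end_idx = length(t))
    if (!length(t)) meals <- meals[0, ]
  }
  rows <- purrr::pmap(
    list(meals$meal_id, meals$start_idx, meals$end_idx),
    function(meal_id, s, e) {
      mt <- t[s:e]
      breaks <- which(diff(mt) > pause_ms)
      starts <- c(1L, breaks + 1L)
      ends <- c(breaks, length(mt))
      tibble(meal_id = meal_id, burst_id = seq_along(starts),
             start_ms = mt[starts], end_ms = mt[ends],
             n_licks = ends - starts + 1L,
             duration_s = (mt[ends] - mt[starts]) / 1000)
    })
  if (!length(rows))
    return(tibble(meal_id = integer(), burst_id = integer(),
                  start_ms = numeric(), end_ms = numeric(),
                  n_licks = integer(), duration_s = numeric()))
  dplyr::bind_rows(rows)
}

#' Whole-meal and intra-meal microstructure summary
#'
#' Computes each variable per meal, then averages across meals (unweighted by
#' default): meal lick count and duration, number of bursts, mean burst size
#' (meal licks / bursts in the meal), mean burst duration, and mean pause
#' duration (burst offset to next burst onset; only meals with at least two
#' bursts contribute pause observations). Session licks count all licks,
#' including orphans outside any meal. Licks in the first minute are reported
#' both anchored at the session's first lick (the default headline value) and
#' as the across-meal average of licks in each meal's first minute. Licks in
#' the first burst is the lick count of the first burst of the first meal.
#'
#' @param licks Lick timestamps (ms) or data frame for one session.
#' @param meals Optional precomputed meal tibble from [segment_meals()] on
#'   the same licks; segmented with the defaults when `NULL`.
#' @param pause_s Burst-closing pause threshold (seconds).
#' @param init_count,init_window_s,termination_pause_s Meal segmentation
#'   parameters, used when `meals` is `NULL`.
#' @param weight `"meal"` (default, each meal counts once) or `"lick"`
#'   (meals weighted by their lick counts) for the across-meal averages.
#' @return A one-row tibble of session-level microstructure variables;
#'   meal-derived fields are `NA` when the session contains no meal.
#' @export
summarize_microstructure <- function(licks, meals = NULL, pause_s = 1,
                                     init_count = 5, init_window_s = 1,
                                     termination_pause_s = 600,
                                     weight = c("meal", "lick")) {
  weight <- match.arg(weight)
  t <- as_timestamps_ms(licks)
  if (is.null(meals))
    meals <- segment_meals(t, init_count, init_window_s, termination_pause_s)
  bursts <- segment_bursts(t, meals, pause_s = pause_s)

  session_licks <- length(t)
  lfm_session <- if (length(t)) sum(t >= t[1] & t < t[1] + 60000) else 0L

  if (!nrow(meals)) {
    return(tibble(
      session_licks = session_licks, n_meals = 0L,
      meal_licks = NA_real_, meal_duration_s = NA_real_,
      n_bursts = NA_real_, burst_size = NA_real_,
      burst_duration_s = NA_real_, pause_duration_s = NA_real_,
      licks_first_minute = lfm_session,
      licks_first_minute_meal = NA_real_,
      licks_first_burst = NA_integer_
    ))
  }

  per_meal <- bursts |>
    dplyr::group_by(.data$meal_id) |>
    dplyr::summarise(
      n_bursts = dplyr::n(),
      burst_duration_s = mean(.data$duration_s),
      pause_duration_s = if (dplyr::n() > 1)
        mean((.data$start_ms[-1] - .data$end_ms[-dplyr::n()]) / 1000)
      else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::left_join(meals[c("meal_id", "n_licks", "duration_s", "onset_ms")],
                     by = "meal_id") |>
    dplyr::mutate(burst_size = .data$n_licks / .data$n_bursts)
  per_meal$licks_first_minute_meal <- vapply(
    seq_len(nrow(meals)),
    function(m) sum(t >= meals$onset_ms[m] & t < meals$onset_ms[m] + 60000),
    numeric(1))

  w <- if (weight == "meal") rep(1, nrow(per_meal)) else per_meal$n_licks
  wmean <- function(x, wt = w) {
    ok <- !is.na(x)
    if (!any(ok)) return(NA_real_)
    sum(x[ok] * wt[ok]) / sum(wt[ok])
  }

  tibble(
    session_licks = session_licks,
    n_meals = nrow(meals),
    meal_licks = wmean(as.numeric(per_meal$n_licks)),
    meal_duration_s = wmean(per_meal$duration_s),
    n_bursts = wmean(as.numeric(per_meal$n_bursts)),
    burst_size = wmean(per_meal$burst_size),
    burst_duration_s = wmean(per_meal$burst_duration_s),
    pause_duration_s = wmean(per_meal$pause_duration_s),
    licks_first_minute = lfm_session,
    licks_first_minute_meal = wmean(per_meal$licks_first_minute_meal),
    licks_first_burst = bursts$n_licks[bursts$meal_id == meals$meal_id[1]][1]
  )
}

#' Microstructure summaries for many sessions
#'
#' Splits a lick-event table by (subject, session) and summarizes each
#' session with [summarize_microstructure()].
#'
#' @param events A validated lick-event tibble (long-term sessions).
#' @param ... Passed on to [summarize_microstructure()].
#' @return A tibble with one row per subject-session, the identifying columns
#'   first.
#' @export
microstructure_by_session <- function(events, ...) {
  events <- validate_lick_events(events)
  events |>
    dplyr::group_by(.data$subject_id, .data$group, .data$session_id,
                    .data$tastant, .data$concentration_value) |>
    dplyr::group_modify(function(d, key) {
      summarize_microstructure(d$timestamp_ms, ...)
    }) |>
    dplyr::ungroup()
}
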