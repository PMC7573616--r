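get_trace_df <- function(x) {
  if (inherits(x, "ct_trace")) return(x$trace)
  if (is.data.frame(x)) return(as_tibble(x))
  abort("expected a ct_trace object or a data frame with time_s and signal",
        class = "lickometry_validation_error")
}

check_uniform <- function(time_s) {
  if (length(time_s) < 2)
    abort("trace too short", class = "lickometry_validation_error")
  dt <- diff(time_s)
  if (max(dt) - min(dt) > 1e-6 * max(abs(dt)))
    abort("trace must be uniformly sampled", class = "lickometry_validation_error")
  mean(dt)
}

#' Rectify and leaky-integrate a raw nerve trace
#'
#' Full-wave rectification followed by a first-order leaky integrator with
#' the exact exponential update
#' `y[n] = y[n-1] + (1 - exp(-dt/tau)) * (|x[n]| - y[n-1])`, `y[1] = |x[1]|`.
#' This is the discrete analogue of the analogue RC integrator used to
#' summate whole-nerve activity; the default time constant is 1.5 s. The
#' output is bounded by the running maximum of `|x|` and converges to `c`
#' for a constant input `c`.
#'
#' @param x A `ct_trace` object or a data frame with columns `time_s` and
#'   `signal` on a uniform sampling grid.
#' @param tau_s Integrator time constant in seconds.
#' @param signal_col Name of the signal column.
#' @return The trace tibble with an added `integrated` column.
#' @export
integrate_trace <- function(x, tau_s = 1.5, signal_col = "signal") {
  trace <- get_trace_df(x)
  check_number(tau_s, "tau_s", min = 0)
  if (!all(c("time_s", signal_col) %in% names(trace)))
    abort("trace needs `time_s` and signal columns",
          class = "lickometry_validation_error")
  dt <- check_uniform(trace$time_s)
  a <- exp(-dt / tau_s)
  r <- abs(trace[[signal_col]])
  # y[n] = (1-a) r[n] + a y[n-1], seeded so that y[1] = r[1]
  y <- stats::filter((1 - a) * r, a, method = "recursive", init = r[1])
  trace$integrated <- as.numeric(y)
  trace
}

#' Baseline-subtracted response height
#'
#' The integrated-trace value at the sample nearest `onset_s + measure_at_s`
#' minus the mean integrated value over the pre-stimulus baseline window
#' `[onset_s - baseline_window_s, onset_s)`. Negative magnitudes (response
#' below baseline) are reported as-is.
#'
#' @param integrated A tibble from [integrate_trace()] (columns `time_s`,
#'   `integrated`).
#' @param onset_s Stimulus onset (seconds).
#' @param measure_at_s Measurement time after onset (seconds); default 20 s.
#' @param baseline_window_s Length of the pre-onset baseline window
#'   (seconds).
#' @return A single response magnitude in integrated-signal units.
#' @export
response_magnitude <- function(integrated, onset_s, measure_at_s = 20,
                               baseline_window_s = 5) {
  tr <- as_tibble(integrated)
  if (!all(c("time_s", "integrated") %in% names(tr)))
    abort("expected an integrated trace (columns time_s, integrated); run integrate_trace() first",
          class = "lickometry_validation_error")
  t <- tr$time_s
  target <- onset_s + measure_at_s
  if (onset_s - baseline_window_s < t[1] || target > t[length(t)])
    abort("measurement or baseline window falls outside the trace",
          class = "lickometry_validation_error")
  base <- tr$integrated[t >= onset_s - baseline_window_s & t < onset_s]
  if (!length(base))
    abort("baseline window contains no samples", class = "lickometry_validation_error")
  idx <- which.min(abs(t - target))
  tr$integrated[idx] - mean(base)
}

#' Bracketing-reference stability QC
#'
#' A stimulus series is usable only if the reference responses recorded
#' before and after it agree: the deviation is `|pre - post| / mean(pre,
#' post)` and the series passes when the deviation is at most `tol`
#' (inclusive; the conventional criterion is 10%). Symmetric in its two
#' arguments.
#'
#' @param pre_ref,post_ref Reference response magnitudes (> 0).
#' @param tol Maximum allowed deviation (fraction).
#' @return A one-row tibble: `qc_pass`, `deviation`.
#' @export
bracket_qc <- function(pre_ref, post_ref, tol = 0.10) {
  if (!is.finite(pre_ref) || !is.finite(post_ref) ||
      pre_ref <= 0 || post_ref <= 0)
    abort("reference magnitudes must be strictly positive (unusable series)",
          class = "lickometry_validation_error")
  deviation <- abs(pre_ref - post_ref) / mean(c(pre_ref, post_ref))
  tibble(qc_pass = deviation <= tol, deviation = deviation)
}

#' Normalize a stimulus series to its bracketing references
#'
#' Integrates the raw trace, measures every event's baseline-subtracted
#' response height, and expresses each test response relative to the mean of
#' the reference responses bracketing it (the nearest reference before and
#' after). Reference responses are themselves normalized against their own
#' bracket (self plus nearest partner), so equal references normalize to 1.
#' Series whose bracket deviates by more than `qc_tol` are flagged
#' `qc_pass = FALSE`; their normalized values are still computed but marked
#' excluded. One reference application may close one series and open the
#' next.
#'
#' @param x A `ct_trace` object, or a trace data frame (then `events` is
#'   required).
#' @param events Event table (`label`, `onset_s`, `rinse_s`, `is_reference`).
#' @param tau_s Integrator time constant (seconds).
#' @param measure_at_s Measurement time after onset (seconds).
#' @param baseline_window_s Pre-onset baseline window (seconds).
#' @param qc_tol Bracket-deviation tolerance (fraction).
#' @return A tibble with one row per event: `label`, `onset_s`,
#'   `is_reference`, `raw_magnitude`, `ref_pre`, `ref_post`, `normalized`,
#'   `bracket_deviation`, `qc_pass`, `excluded`.
#' @export
normalize_ct_series <- function(x, events = NULL, tau_s = 1.5,
                                measure_at_s = 20, baseline_window_s = 5,
                                qc_tol = 0.10) {
  if (inherits(x, "ct_trace") && is.null(events)) events <- x$events
  if (is.null(events))
    abort("`events` is required when `x` is a plain trace",
          class = "lickometry_validation_error")
  events <- as_tibble(events)
  trace <- integrate_trace(x, tau_s = tau_s)
  if (sum(events$is_reference) < 2)
    abort("need at least two reference applications to bracket the series",
          class = "lickometry_validation_error")

  mags <- vapply(events$onset_s, function(on)
    response_magnitude(trace, on, measure_at_s, baseline_window_s),
    numeric(1))
  ref_idx <- which(events$is_reference)
  ref_on <- events$onset_s[ref_idx]
  ref_mag <- mags[ref_idx]

  n <- nrow(events)
  pre <- post <- numeric(n)
  for (i in seq_len(n)) {
    onset <- events$onset_s[i]
    if (events$is_reference[i]) {
      others <- ref_idx[ref_idx != i]
      partner <- others[which.min(abs(events$onset_s[others] - onset))]
      pre[i] <- mags[i]; post[i] <- mags[partner]
    } else {
      before <- ref_idx[events$onset_s[ref_idx] < onset]
      after <- ref_idx[events$onset_s[ref_idx] > onset]
      if (!length(before) || !length(after))
        abort(sprintf("stimulus '%s' is not bracketed by reference applications",
                      events$label[i]),
              class = "lickometry_validation_error")
      pre[i] <- mags[before[length(before)]]
      post[i] <- mags[after[1]]
    }
  }
  qc <- dplyr::bind_rows(purrr::map2(pre, post, bracket_qc, tol = qc_tol))
  tibble(label = events$label, onset_s = events$onset_s,
         is_reference = events$is_reference, raw_magnitude = mags,
         ref_pre = pre, ref_post = post,
         normalized = mags / (pre + post) * 2,
         bracket_deviation = qc$deviation, qc_pass = qc$qc_pass,
         excluded = !qc$qc_pass)
}
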