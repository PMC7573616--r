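#' Configuration for the whole-nerve trace simulator
#'
#' Describes a chorda tympani (CT) recording session as an ordered series of
#' non-overlapping stimulus applications on a uniform sampling grid. Raw
#' whole-nerve activity is modelled as zero-mean noise whose instantaneous
#' amplitude is modulated by a stimulus-locked envelope: each application
#' ramps to plateau within `ramp_s` of onset, holds until rinse, then decays
#' exponentially. The series must begin and end with a reference
#' (ammonium chloride) application so downstream normalization has a bracket.
#'
#' @param seed Integer seed.
#' @param sampling_rate Samples per second.
#' @param baseline_noise_sd SD of the stimulus-independent baseline noise, in
#'   signal units.
#' @param stimulus_events Data frame with columns `label`, `onset_s`,
#'   `rinse_s`, `amplitude` (true response amplitude, signal units) and
#'   `is_reference`. Events must be ordered, non-overlapping, and bracketed by
#'   reference events. See [ct_stimulus_events()] for a convenience builder.
#' @param reference_amplitude True amplitude of reference applications
#'   (recorded in the event table by [ct_stimulus_events()]).
#' @param tau Integrator time constant (seconds) intended for downstream
#'   analysis; stored for convenience.
#' @param ramp_s Envelope rise time after onset (seconds).
#' @param decay_tau_s Envelope decay time constant after rinse (seconds).
#' @return A validated list with class `"ct_sim_config"`.
#' @export
ct_sim_config <- function(seed = 1L,
                          sampling_rate = 500,
                          baseline_noise_sd = 0.01,
                          stimulus_events = ct_stimulus_events(),
                          reference_amplitude = 1,
                          tau = 1.5,
                          ramp_s = 2,
                          decay_tau_s = 3) {
  check_number(sampling_rate, "sampling_rate", min = 0)
  check_number(baseline_noise_sd, "baseline_noise_sd", min = 0, strict = FALSE)
  check_number(tau, "tau", min = 0)
  check_number(ramp_s, "ramp_s", min = 0)
  check_number(decay_tau_s, "decay_tau_s", min = 0)
  ev <- as_tibble(stimulus_events)
  need <- c("label", "onset_s", "rinse_s", "amplitude", "is_reference")
  if (!all(need %in% names(ev)))
    abort(paste("`stimulus_events` needs columns:", paste(need, collapse = ", ")),
          class = "lickometry_config_error")
  if (!nrow(ev)) abort("`stimulus_events` is empty", class = "lickometry_config_error")
  if (is.unsorted(ev$onset_s, strictly = TRUE))
    abort("stimulus events must be strictly ordered by onset",
          class = "lickometry_config_error")
  if (any(ev$rinse_s <= ev$onset_s))
    abort("each rinse must follow its onset", class = "lickometry_config_error")
  if (nrow(ev) > 1 && any(ev$onset_s[-1] < ev$rinse_s[-nrow(ev)]))
    abort("stimulus events overlap", class = "lickometry_config_error")
  if (!ev$is_reference[1] || !ev$is_reference[nrow(ev)])
    abort("first and last events must be reference applications",
          class = "lickometry_config_error")
  if (any(ev$amplitude < 0))
    abort("amplitudes must be non-negative", class = "lickometry_config_error")

  structure(list(seed = as.integer(seed), sampling_rate = sampling_rate,
                 baseline_noise_sd = baseline_noise_sd, stimulus_events = ev,
                 reference_amplitude = reference_amplitude, tau = tau,
                 ramp_s = ramp_s, decay_tau_s = decay_tau_s),
            class = "ct_sim_config")
}

#' Build a bracketed stimulus-event table
#'
#' Lays out test stimuli between an opening and a closing reference
#' application, with a fixed application duration and rinse interval.
#'
#' @param test_amplitudes Named numeric vector: true amplitude per test
#'   stimulus, in units of the reference amplitude times `reference_amplitude`.
#' @param reference_amplitude Amplitude of the reference applications.
#' @param reference_label Label of the reference stimulus.
#' @param stim_duration_s Application-to-rinse duration (seconds).
#' @param rinse_interval_s Rinse-to-next-onset interval (seconds).
#' @param start_s Onset of the first (reference) application.
#' @param post_reference_amplitude Optional amplitude for the closing
#'   reference; defaults to `reference_amplitude`. Setting it away from the
#'   opening reference injects bracket drift for QC testing.
#' @return An event tibble suitable for [ct_sim_config()].
#' @export
ct_stimulus_events <- function(test_amplitudes = c(sucrose_500 = 0.8,
                                                   nacl_500 = 1.1),
                               reference_amplitude = 1,
                               reference_label = "nh4cl_500",
                               stim_duration_s = 25,
                               rinse_interval_s = 60,
                               start_s = 30,
                               post_reference_amplitude = NULL) {
  if (is.null(post_reference_amplitude))
    post_reference_amplitude <- reference_amplitude
  labels <- c(reference_label, names(test_amplitudes),
              paste0(reference_label, "_post"))
  amps <- c(reference_amplitude, unname(test_amplitudes),
            post_reference_amplitude)
  n <- length(labels)
  onsets <- start_s + (seq_len(n) - 1) * (stim_duration_s + rinse_interval_s)
  tibble(label = labels, onset_s = onsets, rinse_s = onsets + stim_duration_s,
         amplitude = amps,
         is_reference = c(TRUE, rep(FALSE, n - 2), TRUE))
}

#' Simulate a raw CT nerve trace
#'
#' Produces a uniformly sampled, zero-mean raw trace whose local amplitude
#' follows the stimulus envelopes: `signal[t] ~ N(0, sqrt(noise_sd^2 +
#' (amplitude * envelope(t))^2))`. With zero noise and zero amplitudes the
#' trace is identically zero. True amplitudes are retained in the event table
#' for recovery tests.
#'
#' @param config A [ct_sim_config()].
#' @param tail_s Recording time kept after the last rinse (seconds).
#' @return An object of class `"ct_trace"`: a list with `trace` (tibble
#'   `time_s`, `signal`), `events` (the event tibble), and `sampling_rate`.
#' @export
simulate_ct_trace <- function(config, tail_s = 40) {
  stopifnot(inherits(config, "ct_sim_config"))
  ev <- config$stimulus_events
  fs <- config$sampling_rate
  duration <- max(ev$rinse_s) + tail_s
  n <- floor(duration * fs) + 1L
  t <- (seq_len(n) - 1L) / fs

  env_total <- numeric(n)
  for (k in seq_len(nrow(ev))) {
    e <- numeric(n)
    on <- ev$onset_s[k]; off <- ev$rinse_s[k]
    rising <- t >= on & t < on + config$ramp_s
    e[rising] <- (t[rising] - on) / config$ramp_s
    e[t >= on + config$ramp_s & t < off] <- 1
    post <- t >= off
    e[post] <- exp(-(t[post] - off) / config$decay_tau_s) *
      min(1, (off - on) / config$ramp_s)
    env_total <- env_total + ev$amplitude[k] * e
  }
  sds <- sqrt(config$baseline_noise_sd^2 + env_total^2)
  sig <- with_seed(derive_seed(config$seed, "ct_trace"), {
    z <- if (all(sds == 0)) numeric(n) else rnorm(n)
    z * sds
  })
  structure(list(trace = tibble(time_s = t, signal = sig),
                 events = ev, sampling_rate = fs),
            class = "ct_trace")
}

#' @export
print.ct_trace <- function(x, ...) {
  cat(sprintf("<ct_trace> %d samples at %g Hz, %d stimulus events (%d reference)\n",
              nrow(x$trace), x$sampling_rate, nrow(x$events),
              sum(x$events$is_reference)))
  invisible(x)
}
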