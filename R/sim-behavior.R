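#' Configuration for the behavioural lick-stream simulator
#'
#' Bundles and validates every parameter of the hierarchical lick generator.
#' Licking is simulated on three nested timescales: meals recur at renewal
#' times separated by long (heavy-tailed, mean well above the 600-s meal
#' termination threshold) pauses; each meal contains a geometric number of
#' licking bursts separated by intra-meal pauses; each burst contains licks
#' whose interlick intervals (ILIs) are truncated-normal, clustering near the
#' stereotyped rodent lick rhythm of 100-160 ms.
#'
#' The drive to lick a given tastant at a given concentration follows a
#' saturating (Hill-type) curve for appetitive stimuli and a decreasing curve
#' for aversive ones (see [lick_drive()]). Treatment groups other than control
#' can carry a multiplicative suppression factor in (0, 1] applied to the lick
#' drive for suppressible (sweet and salt) tastants.
#'
#' @param seed Master integer seed. Every simulated session derives its own
#'   stream from this seed plus subject/session/purpose keys, so adding
#'   subjects never perturbs existing streams.
#' @param n_subjects_per_group Subjects per treatment group.
#' @param groups Character vector of group labels; the first is the untreated
#'   reference and always has suppression factor 1.
#' @param within_burst_ili_mean,within_burst_ili_sd Mean and SD (seconds) of
#'   the truncated-normal within-burst ILI; truncated to
#'   (`ili_lower`, `ili_upper`).
#' @param ili_lower,ili_upper Truncation bounds (seconds) for within-burst
#'   ILIs.
#' @param burst_length_mean Mean lick count per burst (geometric law).
#' @param bursts_per_meal_mean Mean number of bursts per meal (Poisson,
#'   floored at 1); scaled by the lick drive.
#' @param intra_meal_pause_mean,intra_meal_pause_shape Mean (seconds) and
#'   gamma shape of pauses between bursts within a meal; truncated to stay
#'   strictly above the 1-s burst criterion and below the meal-termination
#'   threshold.
#' @param inter_meal_pause_mean Mean (seconds) of the pause between meals;
#'   must exceed 600 s. Gaps are drawn as 650 s plus an exponential excess so
#'   every generated gap terminates a meal under the default segmentation
#'   rule.
#' @param meals_per_session_mean Mean number of meals in a 23-h session
#'   (Poisson, floored at 1).
#' @param session_hours Session length in hours.
#' @param concentration_response Data frame with columns `tastant`, `kind`
#'   (`"appetitive"`, `"aversive"` or `"neutral"`), `half_max` (concentration
#'   at half-maximal effect, same unit the stimuli are specified in), `hill`
#'   (slope), and `suppressible` (logical: does the group suppression factor
#'   apply). Defaults cover the tastants used in sweet/salt/umami/bitter
#'   testing.
#' @param group_effect Named numeric vector of suppression factors in (0, 1],
#'   one per group.
#' @param baseline_drive Lick drive for water / at zero concentration, in
#'   (0, 1].
#'
#' @return A validated list with class `"behavior_sim_config"`.
#' @seealso [simulate_longterm_session()], [simulate_brief_access_session()],
#'   [simulate_water_training()]
#' @export
behavior_sim_config <- function(seed = 1L,
                                n_subjects_per_group = 8L,
                                groups = c("control", "acute_lps", "chronic_lps"),
                                within_burst_ili_mean = 0.120,
                                within_burst_ili_sd = 0.020,
                                ili_lower = 0.050,
                                ili_upper = 0.300,
                                burst_length_mean = 30,
                                bursts_per_meal_mean = 40,
                                intra_meal_pause_mean = 50,
                                intra_meal_pause_shape = 2,
                                inter_meal_pause_mean = 1800,
                                meals_per_session_mean = 10,
                                session_hours = 23,
                                concentration_response = default_concentration_response(),
                                group_effect = c(control = 1, acute_lps = 0.7,
                                                 chronic_lps = 0.65),
                                baseline_drive = 0.35) {
  check_number(seed, "seed", min = 0, strict = FALSE)
  check_number(n_subjects_per_group, "n_subjects_per_group", min = 0)
  check_number(within_burst_ili_mean, "within_burst_ili_mean", min = 0)
  check_number(within_burst_ili_sd, "within_burst_ili_sd", min = 0)
  check_number(ili_lower, "ili_lower", min = 0)
  check_number(ili_upper, "ili_upper", min = ili_lower)
  check_number(burst_length_mean, "burst_length_mean", min = 1, strict = FALSE)
  check_number(bursts_per_meal_mean, "bursts_per_meal_mean", min = 0)
  check_number(intra_meal_pause_mean, "intra_meal_pause_mean", min = 1)
  check_number(intra_meal_pause_shape, "intra_meal_pause_shape", min = 0)
  check_number(inter_meal_pause_mean, "inter_meal_pause_mean", min = 600)
  check_number(meals_per_session_mean, "meals_per_session_mean", min = 0)
  check_number(session_hours, "session_hours", min = 0)
  check_number(baseline_drive, "baseline_drive", min = 0)
  if (baseline_drive > 1)
    abort("`baseline_drive` must be in (0, 1]", class = "lickometry_config_error")
  if (!is.character(groups) || !length(groups) || anyDuplicated(groups))
    abort("`groups` must be distinct labels", class = "lickometry_config_error")
  if (!all(groups %in% names(group_effect)))
    abort("`group_effect` must name every group", class = "lickometry_config_error")
  if (any(group_effect <= 0 | group_effect > 1))
    abort("suppression factors must lie in (0, 1]", class = "lickometry_config_error")
  cr <- as_tibble(concentration_response)
  need <- c("tastant", "kind", "half_max", "hill", "suppressible")
  if (!all(need %in% names(cr)))
    abort(paste("`concentration_response` needs columns:",
                paste(need, collapse = ", ")),
          class = "lickometry_config_error")
  if (any(cr$half_max <= 0) || any(cr$hill <= 0))
    abort("`half_max` and `hill` must be strictly positive",
          class = "lickometry_config_error")

  structure(list(
    seed = as.integer(seed),
    n_subjects_per_group = as.integer(n_subjects_per_group),
    groups = groups,
    within_burst_ili_mean = within_burst_ili_mean,
    within_burst_ili_sd = within_burst_ili_sd,
    ili_lower = ili_lower, ili_upper = ili_upper,
    burst_length_mean = burst_length_mean,
    bursts_per_meal_mean = bursts_per_meal_mean,
    intra_meal_pause_mean = intra_meal_pause_mean,
    intra_meal_pause_shape = intra_meal_pause_shape,
    inter_meal_pause_mean = inter_meal_pause_mean,
    meals_per_session_mean = meals_per_session_mean,
    session_hours = session_hours,
    concentration_response = cr,
    group_effect = group_effect,
    baseline_drive = baseline_drive
  ), class = "behavior_sim_config")
}

#' Default concentration-response parameters per tastant
#'
#' Half-max concentrations sit inside the ranges typically presented in
#' rodent taste testing (sucrose/saccharin/NaCl in mM and quinine in mM).
#'
#' @return A tibble with one row per tastant.
#' @export
default_concentration_response <- function() {
  tibble(
    tastant = c("sucrose", "saccharin", "acek", "glucose", "nacl",
                "mpg", "quinine", "water"),
    kind = c("appetitive", "appetitive", "appetitive", "appetitive",
             "aversive", "appetitive", "aversive", "neutral"),
    half_max = c(100, 5, 25, 300, 250, 150, 0.1, 1),
    hill = c(1.5, 1.5, 1.5, 1.5, 2, 1.5, 1.5, 1),
    suppressible = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  )
}

#' Lick drive for a tastant at a concentration
#'
#' Maps stimulus identity, concentration, and treatment group to a drive in
#' (0, 1] that scales the simulated rate of licking. Appetitive tastants
#' follow a rising Hill curve from the water baseline towards 1; aversive
#' tastants fall from the baseline towards 0; neutral stimuli stay at the
#' baseline. Treated groups multiply the drive of suppressible tastants by
#' their suppression factor.
#'
#' @param config A [behavior_sim_config()].
#' @param tastant Tastant label (must appear in the concentration-response
#'   table).
#' @param concentration Concentration in the unit the table's `half_max` uses.
#' @param group Group label (default: first group, no suppression).
#' @return A single drive value in (0, 1].
#' @export
lick_drive <- function(config, tastant, concentration, group = config$groups[1]) {
  stopifnot(inherits(config, "behavior_sim_config"))
  cr <- config$concentration_response
  row <- cr[cr$tastant == tastant, ]
  if (!nrow(row))
    abort(sprintf("tastant '%s' not in concentration_response table", tastant),
          class = "lickometry_config_error")
  d0 <- config$baseline_drive
  occ <- if (concentration <= 0) 0 else {
    concentration^row$hill / (concentration^row$hill + row$half_max^row$hill)
  }
  drive <- switch(row$kind,
                  appetitive = d0 + (1 - d0) * occ,
                  aversive = d0 * (1 - occ),
                  neutral = d0,
                  abort("unknown tastant kind", class = "lickometry_config_error"))
  if (isTRUE(row$suppressible)) {
    f <- unname(config$group_effect[group])
    if (is.na(f)) abort(sprintf("group '%s' has no suppression factor", group),
                        class = "lickometry_config_error")
    drive <- drive * f
  }
  max(drive, 1e-3)
}

lick_event_row <- function(n, subject_id, group, session_id, session_type,
                           trial_id, tastant, concentration_value,
                           concentration_unit, timestamp_ms) {
  tibble::new_tibble(list(
    subject_id = rep_len(as.character(subject_id), n),
    group = rep_len(as.character(group), n),
    session_id = rep_len(as.character(session_id), n),
    session_type = rep_len(session_type, n),
    trial_id = rep_len(as.character(trial_id), n),
    tastant = rep_len(as.character(tastant), n),
    concentration_value = rep_len(as.numeric(concentration_value), n),
    concentration_unit = rep_len(concentration_unit, n),
    timestamp_ms = as.integer(timestamp_ms)
  ), nrow = n)
}

#' Simulate a 23-h single-bottle lick session
#'
#' Generates one long-term lickometer session for one subject as a
#' three-level hierarchy: meals at renewal times, geometric-length bursts
#' within meals, truncated-normal ILIs within bursts. The first burst of each
#' meal always has at least five licks, so a meal's first lick satisfies the
#' standard initiation rule (5 licks within 1 s) and the generator's ground
#' truth coincides with rule-based segmentation. Inter-meal gaps are always
#' longer than 600 s.
#'
#' The lick drive ([lick_drive()]) for the tastant/concentration/group scales
#' the expected number of bursts per meal, so expected session licks scale
#' monotonically with the group suppression factor.
#'
#' @param config A [behavior_sim_config()].
#' @param subject_id Subject label.
#' @param tastant Tastant label.
#' @param concentration Stimulus concentration.
#' @param concentration_unit Unit string recorded in the event table.
#' @param group Treatment group label.
#' @param n_meals Optional fixed number of meals; default draws
#'   `max(1, rpois(meals_per_session_mean))`.
#' @return A tibble of lick events (one row per lick, standard event-table
#'   columns) with the generator's ground truth attached as attribute
#'   `"truth"`: a list of `meals` and `bursts` tibbles. Retrieve it with
#'   [session_truth()].
#' @export
simulate_longterm_session <- function(config, subject_id, tastant,
                                      concentration, concentration_unit = "mM",
                                      group = config$groups[1],
                                      n_meals = NULL) {
  stopifnot(inherits(config, "behavior_sim_config"))
  drive <- lick_drive(config, tastant, concentration, group)
  session_id <- sprintf("LT_%s_%s", tastant, format(concentration))
  seed <- derive_seed(config$seed, "longterm", subject_id, tastant,
                      concentration, group)
  limit_ms <- config$session_hours * 3600 * 1000

  with_seed(seed, {
    if (is.null(n_meals)) {
      n_meals <- max(1L, rpois(1, config$meals_per_session_mean))
    } else {
      check_number(n_meals, "n_meals", min = 0)
      n_meals <- as.integer(n_meals)
    }
    t_ms <- floor(runif(1, 0, 300) * 1000)
    licks <- integer(0)
    meal_rows <- list(); burst_rows <- list()
    for (m in seq_len(n_meals)) {
      if (t_ms >= limit_ms - 1000) break
      n_bursts <- max(1L, rpois(1, config$bursts_per_meal_mean * drive))
      meal_licks <- integer(0)
      meal_bursts <- list()
      for (b in seq_len(n_bursts)) {
        len <- rgeom(1, 1 / config$burst_length_mean) + 1L
        if (b == 1L) len <- max(len, 5L)
        ilis <- rtnorm(len - 1L, config$within_burst_ili_mean,
                       config$within_burst_ili_sd,
                       config$ili_lower, config$ili_upper)
        bt <- t_ms + c(0, cumsum(round(ilis * 1000)))
        bt <- as.integer(bt)
        if (max(bt) >= limit_ms) break
        meal_licks <- c(meal_licks, bt)
        meal_bursts[[length(meal_bursts) + 1L]] <- tibble(
          meal_id = m, burst_id = b, start_ms = bt[1], end_ms = bt[len],
          n_licks = len
        )
        # intra-meal pause, strictly > 1 s and < termination threshold
        pause <- rgamma_trunc(config$intra_meal_pause_mean,
                              config$intra_meal_pause_shape, 1.5, 550)
        t_ms <- bt[len] + round(pause * 1000)
      }
      if (!length(meal_licks)) break
      licks <- c(licks, meal_licks)
      meal_rows[[length(meal_rows) + 1L]] <- tibble(
        meal_id = m, onset_ms = meal_licks[1],
        offset_ms = meal_licks[length(meal_licks)],
        n_licks = length(meal_licks), n_bursts = length(meal_bursts)
      )
      burst_rows[[length(burst_rows) + 1L]] <- dplyr::bind_rows(meal_bursts)
      gap <- 650 + rexp(1, 1 / max(config$inter_meal_pause_mean - 650, 1))
      t_ms <- meal_licks[length(meal_licks)] + round(gap * 1000)
    }
    meals <- if (length(meal_rows)) dplyr::bind_rows(meal_rows) else
      tibble(meal_id = integer(), onset_ms = integer(), offset_ms = integer(),
             n_licks = integer(), n_bursts = integer())
    bursts <- if (length(burst_rows)) dplyr::bind_rows(burst_rows) else
      tibble(meal_id = integer(), burst_id = integer(), start_ms = integer(),
             end_ms = integer(), n_licks = integer())
    out <- lick_event_row(length(licks), subject_id, group, session_id,
                          "long_term", NA_character_, tastant, concentration,
                          concentration_unit, licks)
    attr(out, "truth") <- list(meals = meals, bursts = bursts, drive = drive)
    out
  })
}

# Gamma draw truncated to (lower, upper) by rejection.
rgamma_trunc <- function(mean, shape, lower, upper) {
  repeat {
    x <- stats::rgamma(1, shape = shape, scale = mean / shape)
    if (x > lower && x < upper) return(x)
  }
}

#' Ground truth attached to a simulated session
#'
#' @param session A tibble returned by [simulate_longterm_session()].
#' @return The `"truth"` attribute: a list with `meals` and `bursts` tibbles.
#' @export
session_truth <- function(session) attr(session, "truth")

#' Simulate a brief-access gustometer session
#'
#' One daily session: each stimulus in `stimulus_array` is presented once per
#' block in pseudorandom order, for `n_blocks` blocks. Per trial the animal
#' has `initiation_limit_s` to make a first lick; licking then proceeds for
#' `trial_duration_s` from the first lick. Within the trial window the animal
#' alternates stereotyped within-burst ILIs with short pauses; the probability
#' of continuing to lick at each step equals the lick drive, so at drive 1 the
#' animal licks continuously and its trial count approaches the maximum
#' potential rate (standardized lick ratio near 1).
#'
#' @param config A [behavior_sim_config()].
#' @param subject_id Subject label.
#' @param stimulus_array Data frame with columns `tastant` and `concentration`
#'   (conventionally 4 concentrations of a tastant plus water).
#' @param group Treatment group label.
#' @param session_id Session label (e.g. the test day).
#' @param n_blocks Number of presentation blocks.
#' @param trial_duration_s Trial duration after the first lick (seconds).
#' @param initiation_limit_s Time allowed to initiate (seconds).
#' @param intertrial_s Interval between trials (seconds).
#' @param p_fail_initiate Probability a trial is never initiated.
#' @param concentration_unit Unit string for the event table.
#' @return A tibble of lick events with the trial-window table attached as
#'   attribute `"trials"` (retrieve with [trial_windows()]).
#' @export
simulate_brief_access_session <- function(config, subject_id, stimulus_array,
                                          group = config$groups[1],
                                          session_id = "BA_day1",
                                          n_blocks = 3,
                                          trial_duration_s = 15,
                                          initiation_limit_s = 30,
                                          intertrial_s = 10,
                                          p_fail_initiate = 0.02,
                                          concentration_unit = "mM") {
  stopifnot(inherits(config, "behavior_sim_config"))
  stim <- as_tibble(stimulus_array)
  if (!nrow(stim) || !all(c("tastant", "concentration") %in% names(stim)))
    abort("`stimulus_array` must have rows and columns tastant, concentration",
          class = "lickometry_config_error")
  seed <- derive_seed(config$seed, "brief_access", subject_id, session_id)

  with_seed(seed, {
    order_idx <- unlist(lapply(seq_len(n_blocks),
                               function(b) sample.int(nrow(stim))))
    trials <- stim[order_idx, ]
    trials$trial_id <- sprintf("T%02d", seq_len(nrow(trials)))
    trials$block <- rep(seq_len(n_blocks), each = nrow(stim))

    t_ms <- 0
    ev <- list(); starts <- integer(nrow(trials))
    dur_ms <- round(trial_duration_s * 1000)
    for (k in seq_len(nrow(trials))) {
      starts[k] <- t_ms
      drive <- lick_drive(config, trials$tastant[k], trials$concentration[k],
                          group)
      initiated <- runif(1) > p_fail_initiate
      latency <- min(rexp(1, 1 / 3), initiation_limit_s - 0.001)
      if (initiated) {
        first <- t_ms + round(latency * 1000)
        m <- ceiling(trial_duration_s / config$ili_lower) + 5L
        pausing <- runif(m) > drive
        gaps <- ifelse(pausing, runif(m, 1, 3),
                       rtnorm(m, config$within_burst_ili_mean,
                              config$within_burst_ili_sd,
                              config$ili_lower, config$ili_upper))
        lt <- first + c(0, cumsum(round(gaps * 1000)))
        lt <- lt[lt < first + dur_ms]
        ev[[k]] <- lick_event_row(length(lt), subject_id, group, session_id,
                                  "brief_access", trials$trial_id[k],
                                  trials$tastant[k], trials$concentration[k],
                                  concentration_unit, lt)
        t_ms <- first + dur_ms + round(intertrial_s * 1000)
      } else {
        t_ms <- t_ms + round((initiation_limit_s + intertrial_s) * 1000)
      }
    }
    out <- dplyr::bind_rows(ev)
    windows <- tibble(
      subject_id = as.character(subject_id), group = group,
      session_id = session_id, trial_id = trials$trial_id,
      block = trials$block, tastant = trials$tastant,
      concentration = trials$concentration, access_start_ms = starts
    )
    attr(out, "trials") <- windows
    out
  })
}

#' Trial windows attached to a simulated brief-access session
#'
#' @param session A tibble from [simulate_brief_access_session()].
#' @return The trial-window tibble (`trial_id`, `tastant`, `concentration`,
#'   `access_start_ms`, ...).
#' @export
trial_windows <- function(session) attr(session, "trials")

#' Simulate a water-training session
#'
#' Sustained licking to water used to estimate a subject's baseline
#' (intraburst) lick rate: long runs of within-burst ILIs with occasional
#' short pauses, so ILIs outside the 50-200 ms validity window occur and the
#' downstream ILI filter has work to do.
#'
#' @param config A [behavior_sim_config()].
#' @param subject_id Subject label.
#' @param group Group label.
#' @param n_licks Number of licks to generate.
#' @param p_pause Per-step probability of a pause instead of a rhythmic ILI.
#' @return A tibble of lick events (`session_type = "water_training"`).
#' @export
simulate_water_training <- function(config, subject_id,
                                    group = config$groups[1],
                                    n_licks = 1000, p_pause = 0.08) {
  stopifnot(inherits(config, "behavior_sim_config"))
  seed <- derive_seed(config$seed, "water_training", subject_id)
  with_seed(seed, {
    m <- n_licks - 1L
    pausing <- runif(m) < p_pause
    gaps <- ifelse(pausing, runif(m, 0.5, 2.5),
                   rtnorm(m, config$within_burst_ili_mean,
                          config$within_burst_ili_sd,
                          config$ili_lower, config$ili_upper))
    ts <- c(0, cumsum(round(gaps * 1000)))
    lick_event_row(n_licks, subject_id, group, "WT_1", "water_training",
                   NA_character_, "water", 0, "mM", ts)
  })
}

#' Simulate a full brief-access cohort
#'
#' Water training plus one brief-access session for every subject in every
#' group of the configuration.
#'
#' @inheritParams simulate_brief_access_session
#' @param training_licks Licks per water-training session.
#' @return A list with `events`, `trials` and `training` tibbles covering the
#'   whole cohort.
#' @export
simulate_brief_access_cohort <- function(config, stimulus_array,
                                         session_id = "BA_day1",
                                         trial_duration_s = 15,
                                         training_licks = 800) {
  stopifnot(inherits(config, "behavior_sim_config"))
  ev <- list(); tr <- list(); wt <- list()
  for (g in config$groups) {
    for (i in seq_len(config$n_subjects_per_group)) {
      sid <- sprintf("%s_%02d", g, i)
      s <- simulate_brief_access_session(config, sid, stimulus_array,
                                         group = g, session_id = session_id,
                                         trial_duration_s = trial_duration_s)
      ev[[sid]] <- s
      tr[[sid]] <- trial_windows(s)
      wt[[sid]] <- simulate_water_training(config, sid, group = g,
                                           n_licks = training_licks)
    }
  }
  list(events = dplyr::bind_rows(ev), trials = dplyr::bind_rows(tr),
       training = dplyr::bind_rows(wt))
}
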