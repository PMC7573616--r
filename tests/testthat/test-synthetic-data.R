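test_that("long-term sessions are bit-identical under a fixed seed", {
  cfg <- small_config(seed = 11)
  a <- simulate_longterm_session(cfg, "m1", "sucrose", 100)
  b <- simulate_longterm_session(cfg, "m1", "sucrose", 100)
  expect_identical(a, b)
  expect_identical(session_truth(a), session_truth(b))
})

test_that("generated streams are independent of other subjects", {
  cfg <- small_config(seed = 3)
  a1 <- simulate_longterm_session(cfg, "m1", "sucrose", 100)
  invisible(simulate_longterm_session(cfg, "m2", "sucrose", 100))
  invisible(simulate_brief_access_session(cfg, "m9", sucrose_array()))
  a2 <- simulate_longterm_session(cfg, "m1", "sucrose", 100)
  expect_identical(a1, a2)
})

test_that("timestamps are strictly increasing with positive minimum ILI", {
  for (seed in 1:5) {
    cfg <- small_config(seed = seed)
    s <- simulate_longterm_session(cfg, "m1", "saccharin", 10)
    expect_true(all(diff(s$timestamp_ms) > 0))
    expect_true(all(s$timestamp_ms >= 0))
    expect_true(max(s$timestamp_ms) <= 23 * 3600 * 1000)
    ba <- simulate_brief_access_session(cfg, "m1", sucrose_array())
    expect_true(all(diff(ba$timestamp_ms) > 0))
  }
})

test_that("suppression factor lowers mean session licks monotonically", {
  n_subj <- 20
  licks_at <- function(f) {
    cfg <- behavior_sim_config(seed = 99, n_subjects_per_group = n_subj,
                               groups = c("control", "treated"),
                               meals_per_session_mean = 4,
                               bursts_per_meal_mean = 15,
                               burst_length_mean = 10,
                               group_effect = c(control = 1, treated = f))
    mean(vapply(seq_len(n_subj), function(i)
      nrow(simulate_longterm_session(cfg, sprintf("t%02d", i), "sucrose", 150,
                                     group = "treated")),
      numeric(1)))
  }
  m <- vapply(c(1, 0.7, 0.5), licks_at, numeric(1))
  expect_lt(m[2], m[1])
  expect_lt(m[3], m[2])
})

test_that("requested meal count is recovered by downstream segmentation", {
  cfg <- small_config(seed = 5, inter_meal_pause_mean = 1200)
  s <- simulate_longterm_session(cfg, "m1", "sucrose", 100, n_meals = 5)
  meals <- segment_meals(s)
  expect_identical(nrow(meals), 5L)
  truth <- session_truth(s)
  expect_equal(meals$onset_ms, as.numeric(truth$meals$onset_ms))
  expect_equal(meals$n_licks, truth$meals$n_licks)
})

test_that("within-burst ILIs follow the configured distribution", {
  cfg <- behavior_sim_config(seed = 21)
  wt <- simulate_water_training(cfg, "m1", n_licks = 2000, p_pause = 0)
  ilis <- diff(wt$timestamp_ms) / 1000
  se <- cfg$within_burst_ili_sd / sqrt(length(ilis))
  # rounding to ms adds < 0.5 ms of quantization; allow for it in the band
  expect_lt(abs(mean(ilis) - cfg$within_burst_ili_mean), 3 * se + 5e-4)
})

test_that("brief-access sessions have 5 stimuli x 3 blocks = 15 trials", {
  cfg <- small_config(seed = 2)
  s <- simulate_brief_access_session(cfg, "m1", sucrose_array())
  tw <- trial_windows(s)
  expect_identical(nrow(tw), 15L)
  expect_identical(as.integer(table(tw$block)), rep(5L, 3))
  # every stimulus appears once per block
  counts <- table(tw$tastant, tw$concentration, tw$block)
  expect_true(all(apply(counts, 3, sum) == 5))
})

test_that("brief-access trial order and lick times are seed-reproducible", {
  cfg <- small_config(seed = 13)
  a <- simulate_brief_access_session(cfg, "m1", sucrose_array())
  b <- simulate_brief_access_session(cfg, "m1", sucrose_array())
  expect_identical(a, b)
  expect_identical(trial_windows(a), trial_windows(b))
})

test_that("mean simulated licks rise with sucrose concentration", {
  cfg <- behavior_sim_config(seed = 7, n_subjects_per_group = 25,
                             groups = "control",
                             group_effect = c(control = 1))
  coh <- simulate_brief_access_cohort(cfg, sucrose_array())
  tr <- assemble_trials(coh$events, coh$trials)
  suc <- tr[tr$tastant == "sucrose" & tr$initiated, ]
  m <- tapply(suc$n_licks, suc$concentration, mean)
  m <- m[order(as.numeric(names(m)))]
  expect_true(all(diff(m) >= 0))
})

test_that("invalid behaviour configurations are rejected", {
  expect_error(behavior_sim_config(within_burst_ili_mean = -0.1),
               class = "lickometry_config_error")
  expect_error(behavior_sim_config(inter_meal_pause_mean = 300),
               class = "lickometry_config_error")
  expect_error(behavior_sim_config(group_effect = c(control = 1.2,
                                                    acute_lps = 1,
                                                    chronic_lps = 1)),
               class = "lickometry_config_error")
  cfg <- small_config()
  expect_error(simulate_brief_access_session(cfg, "m1", data.frame()),
               class = "lickometry_config_error")
})

test_that("CT traces: flat at zero noise/amplitude, reproducible by seed", {
  ev <- ct_stimulus_events(c(a = 0), reference_amplitude = 0)
  cfg <- ct_sim_config(seed = 1, baseline_noise_sd = 0, stimulus_events = ev)
  ct <- simulate_ct_trace(cfg)
  expect_true(all(ct$trace$signal == 0))

  cfg2 <- ct_sim_config(seed = 4, baseline_noise_sd = 0.01)
  expect_identical(simulate_ct_trace(cfg2)$trace,
                   simulate_ct_trace(cfg2)$trace)
})

test_that("overlapping or unbracketed CT events are rejected", {
  ev <- ct_stimulus_events(c(a = 0.5))
  bad <- ev; bad$onset_s[2] <- bad$rinse_s[1] - 1
  expect_error(ct_sim_config(stimulus_events = bad),
               class = "lickometry_config_error")
  unbr <- ev; unbr$is_reference[nrow(unbr)] <- FALSE
  expect_error(ct_sim_config(stimulus_events = unbr),
               class = "lickometry_config_error")
})
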