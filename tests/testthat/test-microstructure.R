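test_that("meal segmentation matches the worked example", {
  t_ms <- c(0, 200, 400, 600, 800, 2000, 700000)
  meals <- segment_meals(t_ms)
  expect_identical(nrow(meals), 1L)
  expect_equal(meals$onset_ms, 0)
  expect_equal(meals$offset_ms, 2000)
  expect_identical(meals$n_licks, 6L)
  expect_identical(lick_assignments(meals), c(rep(1L, 6), NA))
  # agrees with the lick-by-lick oracle
  om <- oracle_segment_meals(t_ms)
  expect_identical(length(om), 1L)
  expect_identical(unname(om[[1]]), c(1L, 6L))
})

test_that("degenerate streams yield no meals", {
  expect_identical(nrow(segment_meals(c(0, 300, 600, 900))), 0L)
  expect_identical(nrow(segment_meals(numeric(0))), 0L)
  expect_error(segment_meals(c(100, 50)), class = "lickometry_validation_error")
})

test_that("burst segmentation matches the worked example and boundary rule", {
  t_ms <- c(0, 100, 200, 1500, 1600)
  b <- segment_bursts(t_ms)
  expect_identical(b$n_licks, c(3L, 2L))
  expect_equal(b$duration_s, c(0.2, 0.1))
  expect_equal((b$start_ms[2] - b$end_ms[1]) / 1000, 1.3)
  # an ILI of exactly 1 s stays inside the burst (split is strict >)
  expect_identical(nrow(segment_bursts(c(0, 1000, 2000))), 1L)
  expect_identical(nrow(segment_bursts(c(0, 1000, 2001))), 2L)
})

test_that("segmentation equals the exhaustive oracle on random streams", {
  set.seed(404)
  for (i in 1:200) {
    t_ms <- random_lick_stream(200)
    meals <- segment_meals(t_ms)
    om <- oracle_segment_meals(t_ms)
    expect_identical(nrow(meals), length(om))
    if (length(om)) {
      expect_identical(meals$start_idx, vapply(om, `[[`, integer(1), "start"))
      expect_identical(meals$end_idx, vapply(om, `[[`, integer(1), "end"))
    }
    bursts <- segment_bursts(t_ms, meals)
    for (m in seq_len(nrow(meals))) {
      ob <- oracle_segment_bursts(t_ms[meals$start_idx[m]:meals$end_idx[m]])
      bm <- bursts[bursts$meal_id == m, ]
      expect_identical(bm$n_licks, vapply(ob, length, integer(1)))
      expect_equal(bm$start_ms, vapply(ob, `[`, numeric(1), 1))
    }
  }
})

test_that("meal licks are conserved and bursts partition meals", {
  set.seed(505)
  for (i in 1:25) {
    t_ms <- random_lick_stream(300)
    meals <- segment_meals(t_ms)
    bursts <- segment_bursts(t_ms, meals)
    assign <- lick_assignments(meals)
    expect_identical(sum(meals$n_licks) + sum(is.na(assign)), length(t_ms))
    if (nrow(meals))
      expect_identical(tapply(bursts$n_licks, bursts$meal_id, sum),
                       tapply(meals$n_licks, meals$meal_id, sum))
  }
})

test_that("re-segmenting concatenated meal licks reproduces the meals", {
  set.seed(66)
  t_ms <- random_lick_stream(250)
  meals <- segment_meals(t_ms)
  assign <- lick_assignments(meals)
  kept <- t_ms[!is.na(assign)]
  again <- segment_meals(kept)
  expect_identical(nrow(again), nrow(meals))
  expect_equal(again$n_licks, meals$n_licks)
  expect_equal(again$onset_ms, meals$onset_ms)
})

test_that("raising the termination pause never increases the meal count", {
  set.seed(77)
  for (i in 1:20) {
    t_ms <- random_lick_stream(250)
    n <- vapply(c(100, 300, 600, 1200), function(term)
      nrow(segment_meals(t_ms, termination_pause_s = term)), integer(1))
    expect_true(all(diff(n) <= 0))
  }
})

test_that("mean burst size is meal licks over burst count", {
  # one meal (3-lick initiation) holding bursts of 3 and 2 licks
  t_ms <- c(0, 100, 200, 1500, 1600)
  s <- summarize_microstructure(t_ms, init_count = 3)
  expect_equal(s$burst_size, 5 / 2)
  expect_identical(s$n_meals, 1L)
})

test_that("across-meal averages are unweighted by default", {
  # meal 1: 2 bursts x 10 licks (size 20/2 = 10); meal 2: 4 bursts x 20
  # licks (size 80/4 = 20); meals separated by > 600 s
  burst <- function(t0, n) t0 + seq(0, by = 120, length.out = n)
  m1 <- c(burst(0, 10), burst(5000, 10))
  m2_start <- 700000
  m2 <- unlist(lapply(0:3, function(k) burst(m2_start + k * 5000, 20)))
  s <- summarize_microstructure(c(m1, m2))
  expect_identical(s$n_meals, 2L)
  expect_equal(s$n_bursts, 3)        # (2 + 4) / 2
  expect_equal(s$burst_size, 15)     # (10 + 20) / 2
  sw <- summarize_microstructure(c(m1, m2), weight = "lick")
  expect_equal(sw$burst_size, (10 * 20 + 20 * 80) / 100)
})

test_that("single-burst meals contribute no pause observations", {
  burst <- function(t0, n) t0 + seq(0, by = 120, length.out = n)
  m1 <- burst(0, 10)                              # 1 burst, no pause
  m2 <- c(burst(700000, 10), burst(705000, 10))   # pause 5000 - 1080 ms
  s <- summarize_microstructure(c(m1, m2))
  expect_equal(s$pause_duration_s, (705000 - (700000 + 9 * 120)) / 1000)
})

test_that("first-minute and first-burst palatability measures", {
  burst <- function(t0, n) t0 + seq(0, by = 120, length.out = n)
  licks <- c(burst(0, 7), burst(30000, 5), burst(70000, 5))
  s <- summarize_microstructure(licks)
  expect_equal(s$licks_first_minute, 12)   # anchored at first session lick
  expect_identical(s$licks_first_burst, 7L)
})

test_that("sessions without meals report missing meal-derived fields", {
  s <- summarize_microstructure(c(0, 5000, 10000))
  expect_identical(s$n_meals, 0L)
  expect_identical(s$session_licks, 3L)
  expect_true(is.na(s$meal_licks) && is.na(s$burst_size))
})

test_that("generator ground truth is recovered from a synthetic session", {
  cfg <- behavior_sim_config(seed = 44, burst_length_mean = 8,
                             bursts_per_meal_mean = 100,
                             meals_per_session_mean = 5)
  s <- simulate_longterm_session(cfg, "m1", "sucrose", 1e5, n_meals = 5)
  meals <- segment_meals(s)
  expect_identical(nrow(meals), 5L)
  bursts <- segment_bursts(s, meals)
  expect_gte(nrow(bursts), 200)
  # geometric burst length mean 8, but the first burst of each meal is
  # forced to >= 5 licks; the induced bias is well inside the 10% band
  expect_lt(abs(mean(bursts$n_licks) - 8) / 8, 0.1)
})

test_that("per-session wrapper returns one row per subject-session", {
  cfg <- small_config(seed = 9)
  ev <- dplyr::bind_rows(
    simulate_longterm_session(cfg, "m1", "sucrose", 100),
    simulate_longterm_session(cfg, "m2", "sucrose", 100))
  out <- microstructure_by_session(ev)
  expect_identical(nrow(out), 2L)
  expect_true(all(c("subject_id", "session_licks", "n_meals") %in% names(out)))
})
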