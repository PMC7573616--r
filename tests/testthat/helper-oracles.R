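# Independent reference implementations used to cross-check the package.
# These deliberately take the slow, literal route: lick-by-lick scanning for
# segmentation, explicit least-squares projections for the ANOVA.

# Lick-by-lick meal scan: advance one lick at a time; a meal starts at the
# first lick whose run of `ic` licks spans <= win_s; it ends at the first
# lick followed by a gap >= term_s.
oracle_segment_meals <- function(t_ms, ic = 5, win_s = 1, term_s = 600) {
  win <- win_s * 1000; term <- term_s * 1000
  n <- length(t_ms)
  meals <- list()
  i <- 1L
  while (i + ic - 1L <= n) {
    if (t_ms[i + ic - 1L] - t_ms[i] <= win) {
      j <- i
      while (j < n && t_ms[j + 1L] - t_ms[j] < term) j <- j + 1L
      meals[[length(meals) + 1L]] <- c(start = i, end = j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  meals
}

# Burst partition by scanning every ILI.
oracle_segment_bursts <- function(t_ms, pause_s = 1) {
  if (!length(t_ms)) return(list())
  bursts <- list(); cur <- t_ms[1]
  for (k in seq_along(t_ms)[-1]) {
    if (t_ms[k] - t_ms[k - 1L] > pause_s * 1000) {
      bursts[[length(bursts) + 1L]] <- cur
      cur <- t_ms[k]
    } else {
      cur <- c(cur, t_ms[k])
    }
  }
  bursts[[length(bursts) + 1L]] <- cur
  bursts
}

# Random lick stream with all three timescales mixed in, <= n_max licks.
random_lick_stream <- function(n_max = 200) {
  n <- sample.int(n_max, 1)
  gaps <- sample(c(
    runif(n, 0.05, 0.3),      # within-burst
    runif(n, 0.5, 5),         # short pauses around the burst threshold
    runif(n, 400, 800)        # gaps around the meal threshold
  ), n - 1, replace = FALSE)
  cumsum(c(0, pmax(round(gaps * 1000), 1)))
}

# Split-plot sums of squares by explicit design-matrix least squares:
# fit an increasing sequence of models and take differences of fitted
# sums of squares (sequential projections; balanced => orthogonal).
oracle_splitplot_ss <- function(d) {
  d$subject <- factor(d$subject); d$group <- factor(d$group)
  d$level <- factor(d$level)
  fit_ss <- function(form) sum(fitted(lm(form, data = d))^2)
  s0 <- fit_ss(value ~ 1)
  s1 <- fit_ss(value ~ group)
  s2 <- fit_ss(value ~ subject)            # spans group (nesting)
  s3 <- fit_ss(value ~ subject + level)
  s4 <- fit_ss(value ~ subject + level + group:level)
  list(
    group = s1 - s0,
    subjects_within_groups = s2 - s1,
    level = s3 - s2,
    interaction = s4 - s3,
    error = sum(d$value^2) - s4
  )
}

small_config <- function(seed = 1, ...) {
  behavior_sim_config(seed = seed, n_subjects_per_group = 3,
                      meals_per_session_mean = 4, bursts_per_meal_mean = 15,
                      burst_length_mean = 10, ...)
}

sucrose_array <- function() {
  data.frame(tastant = c(rep("sucrose", 4), "water"),
             concentration = c(25, 50, 100, 150, 0))
}
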