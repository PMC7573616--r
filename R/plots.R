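#' Plot standardized lick ratio concentration-response curves
#'
#' Group mean SLR (with standard-error bars) against concentration, one line
#' per treatment group, faceted by tastant. Takes the per-subject table from
#' [summarize_brief_access()].
#'
#' @param slr A tibble from [summarize_brief_access()].
#' @param log_x Use a log10 concentration axis (zero concentrations are
#'   dropped from the plot when `TRUE`).
#' @return A ggplot object.
#' @export
plot_slr <- function(slr, log_x = FALSE) {
  d <- slr |>
    dplyr::group_by(.data$group, .data$tastant, .data$concentration) |>
    dplyr::summarise(mean_slr = mean(.data$slr),
                     sem = sd(.data$slr) / sqrt(dplyr::n()),
                     .groups = "drop")
  if (log_x) d <- d[d$concentration > 0, ]
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$concentration,
                                       y = .data$mean_slr,
                                       colour = .data$group,
                                       group = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_slr - .data$sem,
                                        ymax = .data$mean_slr + .data$sem),
                           width = 0.05) +
    ggplot2::facet_wrap(ggplot2::vars(.data$tastant), scales = "free_x") +
    ggplot2::labs(x = "Concentration", y = "Standardized lick ratio",
                  colour = "Group") +
    ggplot2::theme_minimal()
  if (log_x) p <- p + ggplot2::scale_x_log10()
  p
}

#' Plot an integrated CT trace with stimulus events
#'
#' Rectifies and integrates the raw trace and overlays stimulus application
#' (solid) and rinse (dotted) times; reference applications are highlighted.
#'
#' @param x A `ct_trace` object from [simulate_ct_trace()], or a trace data
#'   frame (then supply `events`).
#' @param events Event table when `x` is a plain trace.
#' @param tau_s Integrator time constant (seconds).
#' @return A ggplot object.
#' @export
plot_ct_trace <- function(x, events = NULL, tau_s = 1.5) {
  if (inherits(x, "ct_trace") && is.null(events)) events <- x$events
  tr <- integrate_trace(x, tau_s = tau_s)
  ev <- as_tibble(events)
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$time_s, y = .data$integrated)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_vline(data = ev,
                        ggplot2::aes(xintercept = .data$onset_s,
                                     colour = .data$is_reference),
                        linetype = "solid", alpha = 0.6) +
    ggplot2::geom_vline(data = ev,
                        ggplot2::aes(xintercept = .data$rinse_s,
                                     colour = .data$is_reference),
                        linetype = "dotted", alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey40"),
                                 labels = c(`TRUE` = "reference",
                                            `FALSE` = "test"),
                                 name = "Stimulus") +
    ggplot2::labs(x = "Time (s)", y = "Integrated response") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.ct_trace <- function(object, ...) plot_ct_trace(object, ...)

#' Plot a 23-h session as a meal raster
#'
#' Meals are drawn as horizontal spans with individual licks as ticks,
#' making the burst/pause structure and orphan licks visible.
#'
#' @param licks Lick timestamps (ms) or data frame for one session.
#' @param meals Optional meal tibble from [segment_meals()]; segmented with
#'   the defaults when `NULL`.
#' @return A ggplot object.
#' @export
plot_meal_raster <- function(licks, meals = NULL) {
  t <- as_timestamps_ms(licks)
  if (is.null(meals)) meals <- segment_meals(t)
  licks_d <- tibble(time_h = t / 3.6e6)
  p <- ggplot2::ggplot() +
    ggplot2::geom_point(data = licks_d,
                        ggplot2::aes(x = .data$time_h, y = 1),
                        shape = "|", size = 2) +
    ggplot2::labs(x = "Time (h)", y = NULL) +
    ggplot2::scale_y_continuous(breaks = NULL, limits = c(0.5, 1.5)) +
    ggplot2::theme_minimal()
  if (nrow(meals)) {
    meals_d <- dplyr::mutate(meals, start_h = .data$onset_ms / 3.6e6,
                             end_h = .data$offset_ms / 3.6e6)
    p <- p + ggplot2::geom_segment(
      data = meals_d,
      ggplot2::aes(x = .data$start_h, xend = .data$end_h, y = 1.2, yend = 1.2),
      linewidth = 3, colour = "steelblue", alpha = 0.7)
  }
  p
}
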