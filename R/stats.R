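#' Two-tailed p-value from a t statistic
#'
#' `p = 2 * (1 - F_t(|t|; df))` under the central t distribution. Full
#' precision is returned; use [format_p_value()] for the conventional 3-decimal
#' display with a `<0.001` floor. Vectorized over `t` and `df`.
#'
#' @param t t statistic(s).
#' @param df Degrees of freedom (>= 1).
#' @return Two-tailed p-value(s) in \[0, 1\].
#' @export
t_p_two_tailed <- function(t, df) {
  if (any(!is.finite(t)))
    abort("`t` must be finite", class = "lickometry_validation_error")
  if (any(df < 1))
    abort("`df` must be at least 1", class = "lickometry_validation_error")
  2 * pt(-abs(t), df)
}

#' Display-format a p-value
#'
#' @param p Numeric p-value(s).
#' @param digits Decimals shown (default 3); values below the floor print as
#'   e.g. `<0.001`.
#' @return Character vector.
#' @export
format_p_value <- function(p, digits = 3) format_p(p, digits)

new_taste_ttest <- function(statistic, df, p_value, kind, n, estimate) {
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 kind = kind, n = n, estimate = estimate),
            class = "taste_ttest")
}

#' Paired two-tailed t test
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` on the paired differences `d = x - y`,
#' with `df = n - 1` and a two-tailed p from the central t distribution.
#' Pairing follows the order of the input vectors. When the two vectors come
#' from different animals (independent groups), the paired formula still
#' computes, but the pairing is arbitrary — pass such data deliberately.
#'
#' @param x,y Equal-length paired numeric vectors, `n >= 2`.
#' @return A `taste_ttest` object; see [tidy.taste_ttest()].
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y))
    abort("`x` and `y` must have equal length", class = "lickometry_validation_error")
  n <- length(x)
  if (n < 2)
    abort("need at least 2 pairs", class = "lickometry_validation_error")
  d <- x - y
  s <- sd(d)
  if (!is.finite(s) || s == 0)
    abort("zero variance of paired differences", class = "lickometry_validation_error")
  tstat <- mean(d) / (s / sqrt(n))
  new_taste_ttest(tstat, n - 1, t_p_two_tailed(tstat, n - 1),
                  "paired", c(n = n), mean(d))
}

#' Unpaired two-sample t test
#'
#' Welch-corrected by default (no equal-variance assumption); set
#' `welch = FALSE` for the classical pooled-variance test.
#'
#' @param x,y Numeric vectors, each with at least 2 observations.
#' @param welch Use the Welch degrees-of-freedom correction.
#' @return A `taste_ttest` object.
#' @export
unpaired_t <- function(x, y, welch = TRUE) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2)
    abort("need at least 2 observations per group", class = "lickometry_validation_error")
  vx <- var(x); vy <- var(y)
  if (welch) {
    se2 <- vx / nx + vy / ny
    if (se2 == 0) abort("zero variance in both groups",
                        class = "lickometry_validation_error")
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
    tstat <- (mean(x) - mean(y)) / sqrt(se2)
    kind <- "welch"
  } else {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    if (sp2 == 0) abort("zero pooled variance", class = "lickometry_validation_error")
    df <- nx + ny - 2
    tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
    kind <- "unpaired"
  }
  new_taste_ttest(tstat, df, t_p_two_tailed(tstat, df), kind,
                  c(n_x = nx, n_y = ny), mean(x) - mean(y))
}

#' @export
print.taste_ttest <- function(x, ...) {
  cat(sprintf("%s t test: t(%s) = %.3f, p = %s\n", x$kind,
              format(round(x$df, 2)), x$statistic, format_p(x$p_value)))
  invisible(x)
}

#' Tidy a t-test result
#'
#' @param x A `taste_ttest` object.
#' @param ... Unused.
#' @return A one-row tibble: `estimate`, `statistic`, `df`, `p.value`,
#'   `kind`, `n`.
#' @export
tidy.taste_ttest <- function(x, ...) {
  tibble(estimate = x$estimate, statistic = x$statistic, df = x$df,
         p.value = x$p_value, kind = x$kind, n = sum(x$n))
}

#' @rdname tidy.taste_ttest
#' @export
glance.taste_ttest <- function(x, ...) tidy.taste_ttest(x)

#' Split-plot (mixed between x within) ANOVA
#'
#' Classical split-plot decomposition for a balanced complete design with one
#' between-subjects factor (treatment group) and one within-subjects factor
#' (e.g. stimulus concentration), every subject measured once at every
#' within level. The between effect is tested against subjects-within-groups;
#' the within effect and the interaction are tested against the
#' level-by-subject-within-group stratum:
#'
#' \describe{
#'   \item{between}{df `g - 1`, error = subjects within groups, df `g(n-1)`}
#'   \item{within}{df `l - 1`, error = within error, df `g(n-1)(l-1)`}
#'   \item{interaction}{df `(g-1)(l-1)`, same error}
#' }
#'
#' With a single group the table reduces to a one-way repeated-measures
#' ANOVA. No sphericity correction is applied (none is assumed by the
#' classical table); unbalanced designs are rejected rather than imputed.
#'
#' @param data Long-format data frame.
#' @param value,subject,between,within Column names (bare or strings) of the
#'   response, subject identifier, between-subjects factor and
#'   within-subjects factor.
#' @return A `taste_anova` object; `tidy()` returns the ANOVA table with
#'   columns `term`, `ss`, `df`, `ms`, `statistic`, `p.value`, `error_term`.
#' @export
mixed_anova <- function(data, value, subject, between, within) {
  data <- as.data.frame(data)
  value <- rlang::as_name(rlang::ensym(value))
  subject <- rlang::as_name(rlang::ensym(subject))
  between <- rlang::as_name(rlang::ensym(between))
  within <- rlang::as_name(rlang::ensym(within))
  y <- data[[value]]
  subj <- as.character(data[[subject]])
  grp <- as.character(data[[between]])
  lev <- as.character(data[[within]])
  if (any(is.na(y)))
    abort("missing values in the response (no imputation)",
          class = "lickometry_validation_error")

  tab <- table(subj, lev)
  if (any(tab != 1))
    abort("unbalanced design: every subject must be measured exactly once at every within level",
          class = "lickometry_validation_error")
  sg <- unique(data.frame(subj, grp))
  if (anyDuplicated(sg$subj))
    abort("each subject must belong to exactly one group",
          class = "lickometry_validation_error")
  n_per_group <- table(sg$grp)
  if (length(unique(n_per_group)) != 1)
    abort("unbalanced design: groups must have equal subject counts",
          class = "lickometry_validation_error")
  g <- length(n_per_group)
  n <- unname(n_per_group[1])
  l <- length(unique(lev))
  if (l < 2)
    abort("need at least 2 within-subject levels", class = "lickometry_validation_error")

  grand <- mean(y)
  m_subj <- tapply(y, subj, mean)
  m_grp <- tapply(y, grp, mean)
  m_lev <- tapply(y, lev, mean)
  m_cell <- tapply(y, list(grp, lev), mean)

  ss_total <- sum((y - grand)^2)
  ss_between_subj <- l * sum((m_subj - grand)^2)
  ss_group <- n * l * sum((m_grp - grand)^2)
  ss_subj_within <- ss_between_subj - ss_group
  ss_level <- g * n * sum((m_lev - grand)^2)
  ss_int <- n * sum((m_cell - outer(m_grp - grand, m_lev - grand, "+") - grand)^2)
  ss_error <- ss_total - ss_between_subj - ss_level - ss_int
  # guard tiny negative round-off
  ss_subj_within <- max(ss_subj_within, 0)
  ss_error <- max(ss_error, 0)
  ss_int <- max(ss_int, 0)

  df_group <- g - 1
  df_subj <- g * (n - 1)
  df_level <- l - 1
  df_int <- (g - 1) * (l - 1)
  df_error <- g * (n - 1) * (l - 1)

  safe_f <- function(ms, ms_err) {
    if (!is.finite(ms_err) || ms_err <= 0) return(NA_real_)
    ms / ms_err
  }
  ms_subj <- if (df_subj > 0) ss_subj_within / df_subj else NA_real_
  ms_error <- if (df_error > 0) ss_error / df_error else NA_real_

  rows <- list()
  if (g > 1) {
    f_g <- safe_f(ss_group / df_group, ms_subj)
    rows$group <- tibble(term = between, ss = ss_group, df = df_group,
                         ms = ss_group / df_group, statistic = f_g,
                         p.value = if (is.na(f_g)) NA_real_ else
                           stats::pf(f_g, df_group, df_subj, lower.tail = FALSE),
                         error_term = "subjects_within_groups")
  }
  rows$subj <- tibble(term = "subjects_within_groups", ss = ss_subj_within,
                      df = df_subj, ms = ms_subj, statistic = NA_real_,
                      p.value = NA_real_, error_term = NA_character_)
  f_l <- safe_f(ss_level / df_level, ms_error)
  rows$level <- tibble(term = within, ss = ss_level, df = df_level,
                       ms = ss_level / df_level, statistic = f_l,
                       p.value = if (is.na(f_l)) NA_real_ else
                         stats::pf(f_l, df_level, df_error, lower.tail = FALSE),
                       error_term = "within_error")
  if (g > 1) {
    f_i <- safe_f(ss_int / df_int, ms_error)
    rows$int <- tibble(term = paste(between, within, sep = ":"), ss = ss_int,
                       df = df_int, ms = ss_int / df_int, statistic = f_i,
                       p.value = if (is.na(f_i)) NA_real_ else
                         stats::pf(f_i, df_int, df_error, lower.tail = FALSE),
                       error_term = "within_error")
  }
  rows$err <- tibble(term = "within_error", ss = ss_error, df = df_error,
                     ms = ms_error, statistic = NA_real_, p.value = NA_real_,
                     error_term = NA_character_)

  structure(list(table = dplyr::bind_rows(rows),
                 design = list(n_groups = g, n_per_group = n, n_levels = l,
                               between = between, within = within,
                               ss_total = ss_total)),
            class = "taste_anova")
}

#' @export
print.taste_anova <- function(x, ...) {
  d <- x$design
  cat(sprintf("Split-plot ANOVA: %d group(s) x %d subjects x %d levels\n",
              d$n_groups, d$n_per_group, d$n_levels))
  tab <- x$table
  tab$p_display <- ifelse(is.na(tab$p.value), "", format_p(tab$p.value))
  print(as.data.frame(tab), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Tidy a split-plot ANOVA
#'
#' @param x A `taste_anova` object.
#' @param ... Unused.
#' @return The ANOVA table as a tibble (one row per effect and error
#'   stratum).
#' @export
tidy.taste_anova <- function(x, ...) x$table

#' @rdname tidy.taste_anova
#' @export
glance.taste_anova <- function(x, ...) {
  d <- x$design
  tibble(n_groups = d$n_groups, n_per_group = d$n_per_group,
         n_levels = d$n_levels, ss_total = d$ss_total)
}

#' Bonferroni adjustment
#'
#' `min(1, p * family_size)`, vectorized.
#'
#' @param p Raw p-value(s).
#' @param family_size Number of tests in the family (>= 1).
#' @return Adjusted p-value(s).
#' @export
bonferroni_adjust <- function(p, family_size) {
  check_number(family_size, "family_size", min = 1, strict = FALSE)
  pmin(1, p * family_size)
}

#' Bonferroni-adjusted pairwise group comparisons
#'
#' Runs two-sample t tests between every pair of groups, separately at each
#' within level when one is given (the post-hoc follow-up to a significant
#' treatment effect or treatment-by-concentration interaction), and applies
#' a Bonferroni correction. The family size defaults to the number of
#' comparisons conducted in the call and is recorded in the output.
#'
#' @param data Long-format data frame.
#' @param value,group Column names (bare or strings) of the response and
#'   grouping factor.
#' @param within Optional within-level column; comparisons are run per level.
#' @param family_size Family size for the correction; default: number of
#'   comparisons in this call.
#' @param welch Use Welch correction in the underlying tests.
#' @return A tibble: `level` (if any), `group1`, `group2`, `n1`, `n2`,
#'   `statistic`, `df`, `p.value`, `p.adjusted`, `family_size`.
#' @export
bonferroni_pairwise <- function(data, value, group, within = NULL,
                                family_size = NULL, welch = FALSE) {
  data <- as.data.frame(data)
  value <- rlang::as_name(rlang::ensym(value))
  group <- rlang::as_name(rlang::ensym(group))
  within_q <- rlang::enquo(within)
  has_within <- !rlang::quo_is_null(within_q)
  if (has_within) within <- rlang::as_name(rlang::ensym(within))

  levels_ <- if (has_within) unique(as.character(data[[within]])) else NA_character_
  groups_ <- unique(as.character(data[[group]]))
  pairs <- utils::combn(groups_, 2, simplify = FALSE)

  rows <- list()
  for (lv in levels_) {
    d <- if (has_within) data[as.character(data[[within]]) == lv, ] else data
    for (pr in pairs) {
      x <- d[[value]][as.character(d[[group]]) == pr[1]]
      y <- d[[value]][as.character(d[[group]]) == pr[2]]
      tt <- unpaired_t(x, y, welch = welch)
      rows[[length(rows) + 1L]] <- tibble(
        level = lv, group1 = pr[1], group2 = pr[2],
        n1 = length(x), n2 = length(y),
        statistic = tt$statistic, df = tt$df, p.value = tt$p_value)
    }
  }
  out <- dplyr::bind_rows(rows)
  fam <- if (is.null(family_size)) nrow(out) else family_size
  out$p.adjusted <- bonferroni_adjust(out$p.value, fam)
  out$family_size <- fam
  if (!has_within) out$level <- NULL
  out
}
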