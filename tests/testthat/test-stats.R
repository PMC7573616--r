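test_that("two-tailed p-values reproduce textbook anchors", {
  expect_equal(round(t_p_two_tailed(3.84, 7), 3), 0.006)
  expect_equal(round(t_p_two_tailed(2.91, 7), 3), 0.023)
  expect_equal(t_p_two_tailed(0, 7), 1)
  expect_equal(t_p_two_tailed(2, 10), 2 * (1 - pt(2, 10)), tolerance = 1e-12)
  expect_error(t_p_two_tailed(1, 0.5), class = "lickometry_validation_error")
  expect_error(t_p_two_tailed(Inf, 7), class = "lickometry_validation_error")
})

test_that("p is decreasing in |t| and in df (tails lighten with df)", {
  ts <- seq(0.2, 5, by = 0.2)
  for (df in c(3, 7, 15, 40))
    expect_true(all(diff(t_p_two_tailed(ts, df)) < 0))
  # for fixed |t| > 0 the t tails lighten towards the normal as df grows,
  # so the two-tailed p shrinks
  for (tval in c(0.5, 1.5, 3))
    expect_true(all(diff(t_p_two_tailed(tval, 2:50)) < 0))
})

test_that("p-value display floors at <0.001 and rounds to 3 decimals", {
  expect_identical(format_p_value(0.0004), "<0.001")
  expect_identical(format_p_value(0.0226), "0.023")
  expect_identical(format_p_value(0.5), "0.500")
})

test_that("paired t matches the direct formula and stats::t.test", {
  set.seed(8)
  x <- rnorm(8, 1); y <- rnorm(8)
  res <- paired_t(x, y)
  d <- x - y
  t_manual <- mean(d) / (sd(d) / sqrt(8))
  expect_equal(res$statistic, t_manual, tolerance = 1e-10)
  expect_identical(res$df, 7)
  ref <- t.test(x, y, paired = TRUE)
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
  td <- tidy(res)
  expect_equal(td$p.value, res$p_value)
  expect_identical(td$kind, "paired")
})

test_that("degenerate paired inputs are rejected or exact", {
  expect_error(paired_t(c(2, 2, 2, 2), c(1, 1, 1, 1)),
               class = "lickometry_validation_error")   # zero-variance d
  x <- c(1, 2, 3, 4)
  res <- paired_t(x, x - c(1, -1, 1, -1))   # differences average to zero
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_error(paired_t(1:3, 1:2), class = "lickometry_validation_error")
})

test_that("unpaired t (pooled and Welch) matches stats::t.test", {
  set.seed(9)
  x <- rnorm(10); y <- rnorm(12, 0.5, 2)
  for (w in c(TRUE, FALSE)) {
    res <- unpaired_t(x, y, welch = w)
    ref <- t.test(x, y, var.equal = !w)
    expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(res$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(res$p_value, ref$p.value, tolerance = 1e-10)
  }
})

make_splitplot <- function(g = 3, n = 8, l = 4, effect = 0, seed = 1) {
  set.seed(seed)
  d <- expand.grid(subject = sprintf("s%02d", seq_len(g * n)),
                   level = sprintf("L%d", seq_len(l)),
                   stringsAsFactors = FALSE)
  grp_of <- rep(sprintf("g%d", seq_len(g)), each = n)
  names(grp_of) <- sprintf("s%02d", seq_len(g * n))
  d$group <- grp_of[d$subject]
  d$value <- rnorm(nrow(d)) + rep(rnorm(g * n), l) +
    effect * as.numeric(factor(d$group))
  d
}

test_that("split-plot ANOVA matches explicit projection least squares", {
  for (seed in 1:5) {
    d <- make_splitplot(seed = seed, effect = 0.5)
    tab <- tidy(mixed_anova(d, value, subject, group, level))
    ss <- function(term) tab$ss[tab$term == term]
    orc <- oracle_splitplot_ss(d)
    expect_equal(ss("group"), orc$group, tolerance = 1e-8)
    expect_equal(ss("subjects_within_groups"), orc$subjects_within_groups,
                 tolerance = 1e-8)
    expect_equal(ss("level"), orc$level, tolerance = 1e-8)
    expect_equal(ss("group:level"), orc$interaction, tolerance = 1e-8)
    expect_equal(ss("within_error"), orc$error, tolerance = 1e-8)
  }
})

test_that("split-plot ANOVA agrees with aov error strata", {
  d <- make_splitplot(seed = 42, effect = 0.4)
  tab <- tidy(mixed_anova(d, value, subject, group, level))
  fit <- summary(aov(value ~ group * level + Error(subject / level),
                     data = transform(d, subject = factor(subject),
                                      group = factor(group),
                                      level = factor(level))))
  s1 <- fit[["Error: subject"]][[1]]
  s2 <- fit[["Error: subject:level"]][[1]]
  expect_equal(tab$statistic[tab$term == "group"], s1[["F value"]][1],
               tolerance = 1e-8)
  expect_equal(tab$p.value[tab$term == "group"], s1[["Pr(>F)"]][1],
               tolerance = 1e-8)
  expect_equal(tab$statistic[tab$term == "level"], s2[["F value"]][1],
               tolerance = 1e-8)
  expect_equal(tab$statistic[tab$term == "group:level"], s2[["F value"]][2],
               tolerance = 1e-8)
})

test_that("sums of squares decompose the total on every input", {
  for (seed in 1:5) {
    d <- make_splitplot(g = 2, n = 5, l = 3, seed = seed)
    a <- mixed_anova(d, value, subject, group, level)
    tab <- tidy(a)
    expect_equal(sum(tab$ss), glance(a)$ss_total, tolerance = 1e-8)
    expect_true(all(tab$ss >= 0))
    expect_identical(sum(tab$df), nrow(d) - 1)
  }
})

test_that("degenerate and symmetric designs behave as constructed", {
  d <- make_splitplot(g = 2, n = 4, l = 3)
  d$value <- 5
  tab <- tidy(mixed_anova(d, value, subject, group, level))
  expect_true(all(tab$ss == 0))
  expect_true(all(is.na(tab$statistic)))
  # additive group and level effects: interaction SS exactly zero
  d2 <- make_splitplot(g = 2, n = 4, l = 3)
  d2$value <- 2 * as.numeric(factor(d2$group)) + 3 * as.numeric(factor(d2$level))
  tab2 <- tidy(mixed_anova(d2, value, subject, group, level))
  expect_equal(tab2$ss[tab2$term == "group:level"], 0, tolerance = 1e-10)
  expect_gt(tab2$ss[tab2$term == "group"], 0)
})

test_that("one-group designs reduce to repeated-measures ANOVA", {
  d <- make_splitplot(g = 1, n = 8, l = 4)
  tab <- tidy(mixed_anova(d, value, subject, group, level))
  expect_false("group" %in% tab$term)
  fit <- summary(aov(value ~ level + Error(factor(subject)), data = d))
  s2 <- fit[["Error: Within"]][[1]]
  expect_equal(tab$statistic[tab$term == "level"], s2[["F value"]][1],
               tolerance = 1e-8)
})

test_that("unbalanced designs are rejected, not imputed", {
  d <- make_splitplot(g = 2, n = 4, l = 3)
  expect_error(mixed_anova(d[-1, ], value, subject, group, level),
               "unbalanced", class = "lickometry_validation_error")
  d2 <- d; d2$group[d2$subject == "s01"] <- "g2"
  expect_error(mixed_anova(d2, value, subject, group, level),
               class = "lickometry_validation_error")
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroni_adjust(0.01, 5), 0.05)
  expect_equal(bonferroni_adjust(0.5, 3), 1)
  expect_equal(bonferroni_adjust(0.2, 1), 0.2)
})

test_that("pairwise comparisons run per level with a recorded family", {
  d <- make_splitplot(g = 3, n = 6, l = 2, effect = 1)
  out <- bonferroni_pairwise(d, value, group, within = level)
  expect_identical(nrow(out), 6L)          # 3 pairs x 2 levels
  expect_true(all(out$family_size == 6))
  expect_equal(out$p.adjusted, pmin(1, out$p.value * 6))
  out2 <- bonferroni_pairwise(d, value, group, family_size = 3)
  expect_true(all(out2$family_size == 3))
})
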