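test_that("paired t handles regular and degenerate inputs", {
  x <- c(1, 2, 4); y <- c(2, 2, 7)
  r <- paired_t(x, y)
  expect_equal(unname(r$statistic), -1.511858, tolerance = 1e-5)
  expect_equal(unname(r$df), 2)
  expect_equal(r$p, 2 * pt(-1.511858, 2), tolerance = 1e-5)

  same <- paired_t(c(3, 5, 9), c(3, 5, 9))
  expect_equal(unname(same$statistic), 0)
  expect_equal(same$p, 1)

  const <- paired_t(c(2, 3, 4), c(1, 2, 3))
  expect_equal(const$p, 0)
  expect_match(const$flags, "zero-variance")
  expect_error(paired_t(1, 2), "at least 2")
})

test_that("one-way ANOVA F, df and Tukey posttests are correct", {
  r <- one_way_anova(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5)))
  expect_equal(unname(r$statistic), 3.0, tolerance = 1e-12)
  expect_equal(unname(r$df), c(2, 6))
  expect_equal(r$p, pf(3, 2, 6, lower.tail = FALSE), tolerance = 1e-12)

  # identical groups: no between-group signal
  r0 <- one_way_anova(list(a = c(1, 2), b = c(1, 2), c = c(1, 2)))
  expect_equal(unname(r0$statistic), 0)
  expect_equal(r0$p, 1)
  expect_true(all(r0$posttests$p_adj == 1))

  # Tukey matches the reference implementation
  set.seed(12)
  gs <- list(a = rnorm(5), b = rnorm(5, 1), c = rnorm(5, 2))
  r2 <- one_way_anova(gs)
  df <- data.frame(value = unlist(gs), group = factor(rep(names(gs), each = 5)))
  ref <- stats::TukeyHSD(stats::aov(value ~ group, df))$group
  expect_equal(r2$posttests$p_adj, unname(ref[, "p adj"]), tolerance = 1e-9)

  expect_error(one_way_anova(list(a = 1:3)), ">= 2 groups")
  expect_error(one_way_anova(list(a = 1, b = 1:2)), "n >= 2")
  flagged <- one_way_anova(list(a = c(1, 1), b = c(1, 1)))
  expect_true(is.na(unname(flagged$statistic)))
})

test_that("mixed ANOVA matches the independent split-plot oracle", {
  cases <- expand.grid(G = 2:3, k = 2:4, n = 2:4)
  for (i in seq_len(nrow(cases))) {
    df <- random_split_plot(cases$G[i], cases$k[i], cases$n[i], seed = i)
    mine <- mixed_anova(df)
    oracle <- aov_oracle(df)
    expect_equal(unname(mine$statistic["F_between"]), oracle$F_between,
                 tolerance = 1e-8)
    expect_equal(unname(mine$statistic["F_within"]), oracle$F_within,
                 tolerance = 1e-8)
    expect_equal(unname(mine$statistic["F_interaction"]),
                 oracle$F_interaction, tolerance = 1e-8)
    expect_equal(unname(mine$p["within"]), oracle$p_within, tolerance = 1e-8)
    # SS conservation
    ss <- mine$ss_table
    expect_equal(sum(ss$SS[ss$term != "total"]), ss$SS[ss$term == "total"],
                 tolerance = 1e-9 * max(1, ss$SS[ss$term == "total"]))
  }
})

test_that("mixed ANOVA degenerate and error paths behave", {
  # within levels identical per subject: zero within and interaction F
  df <- expand.grid(subject = 1:4, within = c("w1", "w2"))
  df$between <- ifelse(df$subject <= 2, "g1", "g2")
  df$value <- c(1, 2, 3, 4, 1, 2, 3, 4)
  r <- mixed_anova(df)
  expect_equal(unname(r$statistic["F_within"]), 0)
  expect_equal(unname(r$statistic["F_interaction"]), 0)

  # single between level reduces to one-way RM ANOVA
  set.seed(77)
  df1 <- expand.grid(subject = 1:5, within = c("w1", "w2", "w3"))
  df1$between <- "g1"
  df1$value <- rnorm(15) + as.numeric(factor(df1$within)) * 0.5
  r1 <- mixed_anova(df1)
  ref <- summary(stats::aov(value ~ within + Error(factor(subject)),
                            data = df1))[["Error: Within"]][[1]]
  expect_equal(unname(r1$statistic["F_within"]), ref[["F value"]][1],
               tolerance = 1e-8)
  expect_true(is.na(unname(r1$statistic["F_between"])))

  # incomplete within-subject data refused
  expect_error(mixed_anova(df[-1, ]), "incomplete")

  # unbalanced between groups allowed, flagged
  df2 <- random_split_plot(2, 2, 3, seed = 5)
  df2 <- df2[df2$subject != 1, ]
  r2 <- mixed_anova(df2)
  expect_match(r2$flags, "unbalanced")
})

test_that("declared posttest families run on the mixed ANOVA", {
  df <- random_split_plot(3, 2, 4, seed = 9)
  rt <- mixed_anova(df, posttest = "tukey")
  expect_equal(nrow(rt$posttests), 3)
  expect_true(all(rt$posttests$p_adj >= 0 & rt$posttests$p_adj <= 1))

  comps <- data.frame(g1 = "g1", g2 = "g2", within = c("w1", "w2"))
  rs <- mixed_anova(df, posttest = "sidak", comparisons = comps)
  expect_equal(nrow(rs$posttests), 2)
  expect_true(all(rs$posttests$p_adj >= rs$posttests$p_raw))
  expect_error(mixed_anova(df, posttest = "sidak"), "declared")
})

test_that("Sidak adjustment formula, caps and family-size guard", {
  expect_equal(sidak_adjust(0.05, 3), 0.142625, tolerance = 1e-9)
  expect_equal(sidak_adjust(0, 5), 0)
  expect_equal(sidak_adjust(1, 5), 1)
  expect_equal(sidak_adjust(0.3, 1), 0.3)
  expect_error(sidak_adjust(c(0.1, 0.2, 0.3), m = 2), "family size")
  # monotone in m, and never below the raw p
  p <- c(0.01, 0.2, 0.7)
  a3 <- sidak_adjust(p, 3); a6 <- sidak_adjust(p, 6)
  expect_true(all(a3 >= p) && all(a6 >= a3))
})

test_that("Shapiro-Wilk gate validates input and calibrates", {
  expect_error(shapiro_wilk(c(1, 2)), "3 <= n")
  expect_error(shapiro_wilk(rep(2, 10)), "zero-variance")
  r <- shapiro_wilk(rnorm(50))
  expect_true(unname(r$statistic) > 0 && unname(r$statistic) <= 1)
})

test_that("noncentral-t power analysis reproduces classical sample sizes", {
  expect_identical(power_sample_size_t(4.81), 3L)
  expect_identical(power_sample_size_t(100), 2L)
  expect_identical(power_sample_size_t(1.0), 17L)
  expect_error(power_sample_size_t(-1), "d must be")
  expect_error(power_sample_size_t(0.001, n_max = 100), "unattainable")

  # n non-increasing in d
  ns <- sapply(c(0.5, 1, 2, 4, 8), power_sample_size_t)
  expect_true(all(diff(ns) <= 0))
  # n non-decreasing in power
  np <- sapply(c(0.5, 0.8, 0.9, 0.99), function(p)
    power_sample_size_t(1, power = p))
  expect_true(all(diff(np) >= 0))
  # n non-decreasing as alpha decreases
  na <- sapply(c(0.1, 0.05, 0.01, 0.001), function(a)
    power_sample_size_t(1, alpha = a))
  expect_true(all(diff(na) >= 0))
  # bracketing: power(n-1) < target <= power(n)
  n <- power_sample_size_t(1.2)
  expect_lt(power_t(n - 1, 1.2), 0.8)
  expect_gte(power_t(n, 1.2), 0.8)
})
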