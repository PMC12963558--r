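test_that("mixed ANOVA matches the brute-force GLM oracle", {
  set.seed(314)
  for (k in 1:60) {
    n1 <- sample(3:12, 1); n2 <- sample(3:12, 1)
    d <- random_mixed_data(n1, n2, sd = runif(1, 0.5, 3),
                           cond_eff = runif(1, -1, 1),
                           group_eff = runif(1, -1, 1))
    fit <- mixed_anova(d)
    o <- oracle_mixed_anova(d)
    expect_equal(fit$table$ss, o$ss, tolerance = 1e-10)
    expect_equal(fit$table$df, o$df)
    expect_equal(fit$table$F[c(1, 2, 4)], o$F[c(1, 2, 4)],
                 tolerance = 1e-10)
    expect_equal(fit$table$p[c(1, 2, 4)], o$p[c(1, 2, 4)],
                 tolerance = 1e-10)
  }
})

test_that("ANOVA degenerate and invariance behaviour", {
  d <- random_mixed_data(4, 4)
  d$value <- 5
  fit <- mixed_anova(d)
  expect_true(all(fit$table$ss == 0))
  expect_equal(fit$table$F[c(1, 2, 4)], c(0, 0, 0))
  expect_equal(fit$table$p[c(1, 2, 4)], c(1, 1, 1))
  # translation invariance of every testable SS
  set.seed(21)
  d2 <- random_mixed_data(5, 7, cond_eff = 0.4)
  f1 <- mixed_anova(d2)
  d3 <- d2; d3$value <- d3$value + 123.456
  f2 <- mixed_anova(d3)
  expect_equal(f1$table$ss, f2$table$ss, tolerance = 1e-9)
  # SS additivity about the grand mean on balanced data
  set.seed(22)
  d4 <- random_mixed_data(6, 6, cond_eff = 0.3, group_eff = 0.5)
  f4 <- mixed_anova(d4)
  expect_equal(sum(f4$table$ss),
               sum((d4$value - mean(d4$value))^2), tolerance = 1e-10)
  # design validation
  expect_error(mixed_anova(d4[-1, ]), "incomplete")
  d5 <- d4; d5$group[d5$subject_id == "s01"] <-
    ifelse(d5$condition[d5$subject_id == "s01"] == "A", "g1", "g2")
  expect_error(mixed_anova(d5), "exactly one group")
  expect_error(mixed_anova(random_mixed_data(1, 4)), "2 subjects")
})

test_that("both eta-squared conventions are computed and ordered", {
  set.seed(5)
  for (k in 1:20) {
    d <- random_mixed_data(sample(3:9, 1), sample(3:9, 1),
                           cond_eff = runif(1, -1, 1))
    fit <- mixed_anova(d)
    ec <- eta_squared(fit, "classical")
    ep <- eta_squared(fit, "partial")
    expect_true(all(ec >= 0 & ec <= 1))
    expect_true(all(ep >= 0 & ep <= 1))
    expect_true(all(ec <= ep + 1e-12))
  }
  # published sums of squares reproduce the printed effect sizes:
  # a 2x2 table whose SS set is {.006,.007,.422,.791,.937} has classical
  # eta^2 = .791/2.163 for the between factor, and one with
  # {.138,.025,.708,...} has partial eta^2 = .138/.846 for the within factor
  expect_equal(round(0.791 / (0.006 + 0.007 + 0.422 + 0.791 + 0.937), 3),
               0.366)
  expect_equal(round(0.138 / (0.138 + 0.708), 3), 0.163)
})

test_that("F-distribution tail probabilities are correct and monotone", {
  expect_equal(p_from_f(0, 1, 19), 1)
  # numerical integration of the F density as an independent oracle
  dens <- function(x, d1, d2) stats::df(x, d1, d2)
  p_num <- stats::integrate(dens, 4.381, Inf, d1 = 1, d2 = 20)$value
  expect_equal(p_from_f(4.381, 1, 20), p_num, tolerance = 1e-6)
  expect_lt(abs(p_from_f(4.381, 1, 20) - 0.0497), 5e-4)
  fs <- seq(0.1, 10, by = 0.5)
  expect_true(all(diff(p_from_f(fs, 1, 20)) < 0))
  expect_error(p_from_f(-1, 1, 10), "non-negative")
})

test_that("Duncan critical values match published significant ranges", {
  # 5% Duncan table, df = 20: r = 2 -> 2.95, r = 3 -> 3.10, r = 5 -> 3.25
  expect_equal(q_duncan(2, 20, 0.05), 2.95, tolerance = 0.01)
  expect_equal(q_duncan(3, 20, 0.05), 3.10, tolerance = 0.015)
  expect_equal(q_duncan(5, 20, 0.05), 3.25, tolerance = 0.015)
  # critical ranges non-decreasing in span
  qs <- vapply(2:6, q_duncan, 0, df = 20)
  expect_true(all(diff(qs) >= 0))
})

test_that("Duncan reduces to the t-test for two means and respects ties", {
  expect_false(any(duncan_mrt(c(a = 1, b = 1), ns = 5, ms_error = 2,
                              df_error = 10)$comparisons$significant))
  set.seed(61)
  for (k in 1:50) {
    m <- rnorm(2, sd = 2)
    n1 <- sample(3:10, 1); n2 <- sample(3:10, 1)
    mse <- runif(1, 0.2, 3); dfe <- sample(5:30, 1)
    alpha <- sample(c(0.01, 0.05, 0.1), 1)
    dd <- duncan_mrt(c(a = m[1], b = m[2]), ns = c(n1, n2),
                     ms_error = mse, df_error = dfe, alpha = alpha)
    tstat <- abs(m[1] - m[2]) / sqrt(mse * (1 / n1 + 1 / n2))
    t_sig <- tstat > stats::qt(1 - alpha / 2, dfe)
    expect_identical(dd$comparisons$significant, t_sig)
  }
  expect_error(duncan_mrt(c(1, 2), 4, ms_error = 0, df_error = 5),
               "positive")
})

test_that("Duncan stepwise non-crossing rule blocks inner pairs", {
  # outer span non-significant => inner pairs cannot be declared significant
  dd <- duncan_mrt(c(a = 1.00, b = 0.99, c = 0.98, d = 0.97), ns = 3,
                   ms_error = 1, df_error = 12)
  expect_false(any(dd$comparisons$significant))
  # clearly separated means are all significant
  dd2 <- duncan_mrt(c(a = 10, b = 5, c = 0), ns = 8, ms_error = 0.5,
                    df_error = 21)
  expect_true(all(dd2$comparisons$significant))
})

test_that("Duncan on a fitted ANOVA uses cell means and the chosen error", {
  set.seed(8)
  d <- random_mixed_data(6, 5, cond_eff = 2, group_eff = 1)
  fit <- mixed_anova(d)
  dd <- duncan(fit, error = "pooled")
  expect_equal(length(dd$means), 4)
  expect_equal(dd$df_error, 2 * (11 - 2))
  expect_true(all(diff(dd$means) <= 0))
  dw <- duncan(fit, error = "within")
  expect_equal(dw$ms_error, fit$error_within$ms)
})
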