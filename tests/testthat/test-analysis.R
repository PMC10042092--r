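# 2x2 effect estimation, chi-square, longitudinal summaries, IRLS oracle.

trial_table <- two_by_two(25, 335, 11, 351)

test_that("abstinence rates report per-arm proportions", {
  r <- abstinence_rates(trial_table)
  expect_equal(r$intervention_pct, 6.9)
  expect_equal(r$control_pct, 3.0)
  expect_equal(r$intervention, 25 / 360)

  expect_equal(abstinence_rates(two_by_two(0, 10, 0, 10))$intervention_pct, 0)
  expect_equal(abstinence_rates(two_by_two(10, 0, 10, 0))$control_pct, 100)
  expect_error(abstinence_rates(two_by_two(0, 0, 1, 1)), "denominator")
})

test_that("the Woolf interval reproduces the trial effect estimate", {
  est <- odds_ratio_ci(trial_table)
  expect_equal(round(est$odds_ratio, 2), 2.38)
  expect_equal(round(est$ci_low, 2), 1.15)
  expect_equal(round(est$ci_high, 2), 4.92)
  expect_true(est$ci_low <= est$odds_ratio && est$odds_ratio <= est$ci_high)

  expect_equal(odds_ratio_ci(two_by_two(7, 13, 7, 13))$odds_ratio, 1)
})

test_that("odds ratio obeys reciprocal and width monotonicity properties", {
  est <- odds_ratio_ci(trial_table)
  swapped <- odds_ratio_ci(two_by_two(11, 351, 25, 335))
  expect_equal(swapped$odds_ratio, 1 / est$odds_ratio)
  expect_equal(swapped$ci_low, 1 / est$ci_high)
  expect_equal(swapped$ci_high, 1 / est$ci_low)

  wider <- odds_ratio_ci(trial_table, alpha = 0.01)   # 99% interval
  expect_gt(log(wider$ci_high / wider$ci_low),
            log(est$ci_high / est$ci_low))
  bigger <- odds_ratio_ci(two_by_two(250, 3350, 110, 3510))
  expect_lt(log(bigger$ci_high / bigger$ci_low),
            log(est$ci_high / est$ci_low))
})

test_that("zero cells error unless the Haldane correction is opted into", {
  z <- two_by_two(0, 20, 5, 15)
  expect_error(odds_ratio_ci(z), "haldane")
  est <- odds_ratio_ci(z, haldane = TRUE)
  expect_equal(est$odds_ratio, (0.5 * 15.5) / (20.5 * 5.5))
})

test_that("chi-square matches the textbook Pearson formula", {
  res <- chi_square(trial_table)
  # independent hand computation: N (ad - bc)^2 / (row and column products)
  a <- 25; b <- 335; c <- 11; d <- 351; N <- a + b + c + d
  hand <- N * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  expect_equal(res$statistic, hand, tolerance = 1e-10)
  expect_equal(res$df, 1)
  expect_lt(res$p_value, 0.05)

  sym <- chi_square(two_by_two(9, 21, 9, 21))
  expect_equal(sym$statistic, 0)
  expect_equal(sym$p_value, 1)

  # invariant to transposing the table (rows <-> columns)
  transposed <- chi_square(two_by_two(25, 11, 335, 351))
  expect_equal(res$statistic, transposed$statistic)

  expect_warning(chi_square(two_by_two(0, 300, 1, 300)), "exact")
})

test_that("arm ordering is consistent across rate, OR and chi-square views", {
  set.seed(8)
  for (i in 1:50) {
    tab <- two_by_two(sample(1:30, 1), sample(200:400, 1),
                      sample(1:30, 1), sample(200:400, 1))
    r <- abstinence_rates(tab)
    est <- odds_ratio_ci(tab)
    expect_equal(est$odds_ratio > 1, r$intervention > r$control)
  }
})

test_that("longitudinal summaries report per-cell n, mean and SD", {
  rec <- data.frame(
    participant_id = c("a", "b", "c", "a", "b", "a"),
    arm = c("INTERVENTION", "INTERVENTION", "CONTROL",
            "INTERVENTION", "INTERVENTION", "CONTROL"),
    visit_month = c(0, 0, 0, 1, 1, 0),
    construct = "severity",
    score = c(6, 5, 4, 7, 6, 2))
  s <- summarize_longitudinal(rec)
  cell <- s[s$arm == "INTERVENTION" & s$visit_month == 0, ]
  expect_equal(cell$n, 2)
  expect_equal(cell$mean, 5.5)
  expect_equal(cell$sd, sd(c(6, 5)))
  single <- s[s$arm == "CONTROL" & s$visit_month == 0 &
                s$construct == "severity", ]
  expect_equal(single$n, 2)  # two control records at month 0
  one <- summarize_longitudinal(rec[5, ])
  expect_true(is.na(one$sd))
  expect_true(all(s$n <= 3))
})

test_that("IRLS logistic matches closed forms and glm", {
  set.seed(21)
  y <- rbinom(400, 1, 0.3)
  fit <- fit_logistic_irls(matrix(1, length(y), 1), y)
  expect_equal(unname(fit$coefficients), qlogis(mean(y)), tolerance = 1e-8)

  X <- cbind(intercept = 1, x1 = rnorm(500), x2 = rnorm(500))
  eta <- X %*% c(-0.5, 1, -2)
  y <- rbinom(500, 1, plogis(eta))
  fit <- fit_logistic_irls(X, y)
  ref <- glm(y ~ X[, 2] + X[, 3], family = binomial())
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(summary(ref)$coefficients[, 2]),
               tolerance = 1e-5)

  # a perfectly balanced null covariate has a near-zero coefficient
  xnull <- rep(c(-1, 1), 250)
  fit0 <- fit_logistic_irls(cbind(1, xnull), rbinom(500, 1, 0.5))
  expect_lt(abs(fit0$coefficients[2]), 0.3)
})

test_that("IRLS reports separation as non-convergence naming the column", {
  x <- c(rep(-1, 20), rep(1, 20))
  y <- c(rep(0, 20), rep(1, 20))
  expect_error(fit_logistic_irls(cbind(intercept = 1, sep_col = x), y),
               "sep_col")
  expect_error(fit_logistic_irls(cbind(1, x, x), y), "rank")
})

test_that("long-format export joins scores, arm and abstinence history", {
  coh <- generate_cohort(cohort_config(n = 40L), seed = 5)
  run <- simulate_trial(coh, seed = 6)
  long <- export_long_format(run)
  expect_named(long, c("participant_id", "arm", "visit_month", "construct",
                       "score", "abstinent_so_far"))
  expect_setequal(unique(long$construct), PMT_CONSTRUCTS)
  expect_true(all(long$score >= 1 & long$score <= 7))
  path <- withr::local_tempfile(fileext = ".csv")
  export_long_format(run, path)
  expect_true(file.exists(path))
})
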