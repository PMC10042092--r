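# Synthetic cohort generator and end-to-end trial simulation.

test_that("generated cohorts match the configured mix and moments", {
  coh <- generate_cohort(cohort_config(), seed = 31)
  expect_equal(nrow(coh), 722L)
  dep <- prop.table(table(coh$dependence))
  expect_lt(abs(dep[["LOW"]] - 0.636), 0.03)
  expect_lt(abs(dep[["MODERATE"]] - 0.282), 0.03)
  expect_lt(abs(dep[["HIGH"]] - 0.082), 0.03)
  for (con in PMT_CONSTRUCTS) {
    expect_true(all(coh[[con]] >= 1 & coh[[con]] <= 7))
  }
  expect_identical(coh, generate_cohort(cohort_config(), seed = 31))

  expect_equal(nrow(generate_cohort(cohort_config(n = 0L))), 0L)
  expect_error(cohort_config(sex = c(MALE = 0.9, FEMALE = 0.2)), "sum to 1")
})

test_that("construct score means obey the law of large numbers", {
  cfg <- cohort_config(n = 100000L)
  coh <- generate_cohort(cfg, seed = 17)
  expect_lt(abs(mean(coh$severity) - cfg$construct_means[["severity"]]), 0.02)
  expect_lt(abs(mean(coh$response_cost) - cfg$construct_means[["response_cost"]]),
            0.02)
})

test_that("simulated baseline profiles reproduce published-scale moments", {
  cfg <- cohort_config()
  coh <- generate_cohort(cfg, seed = 3)
  scores <- coh[, PMT_CONSTRUCTS]
  # means inside the configured value +/- truncation shift + MC error
  for (con in PMT_CONSTRUCTS) {
    expect_lt(abs(mean(scores[[con]]) - cfg$construct_means[[con]]), 0.15)
  }
})

test_that("simulation runs are reproducible and respect score bounds", {
  coh <- generate_cohort(cohort_config(n = 150L), seed = 41)
  run1 <- simulate_trial(coh, seed = 42)
  run2 <- simulate_trial(coh, seed = 42)
  expect_identical(run1, run2)
  expect_true(all(run1$scores$score >= 1 & run1$scores$score <= 7))
  ev <- run1$hazard_events
  expect_true(all(as.matrix(ev[, PMT_CONSTRUCTS]) >= 1 &
                    as.matrix(ev[, PMT_CONSTRUCTS]) <= 7))

  # ITT closure: the 2x2 accounts for every randomized participant
  expect_equal(run1$table$a + run1$table$b + run1$table$c + run1$table$d, 150)
})

test_that("a null intervention produces no arm difference", {
  null_params <- behavior_params(delta = 0)
  diffs <- vapply(1:40, function(k) {
    coh <- generate_cohort(cohort_config(n = 400L), seed = 300 + k)
    run <- simulate_trial(coh, null_params, seed = 600 + k)
    r <- abstinence_rates(run$table)
    r$intervention - r$control
  }, numeric(1))
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * se + 1e-12)
})

test_that("a protective delta raises intervention abstinence", {
  wins <- vapply(1:30, function(k) {
    coh <- generate_cohort(cohort_config(n = 400L), seed = 900 + k)
    run <- simulate_trial(coh, seed = 1200 + k)
    r <- abstinence_rates(run$table)
    r$intervention > r$control
  }, logical(1))
  expect_gte(mean(wins), 0.8)
})

test_that("raising delta raises month-3 self-efficacy, seed held fixed", {
  coh <- generate_cohort(cohort_config(n = 400L), seed = 51)
  m3_se <- function(delta) {
    run <- simulate_trial(coh, behavior_params(delta = delta), seed = 52)
    int_ids <- run$assignments$participant_id[run$assignments$arm ==
                                                "INTERVENTION"]
    s <- run$scores
    mean(s$score[s$visit_month == 3 & s$construct == "self_efficacy" &
                   s$participant_id %in% int_ids])
  }
  expect_gt(m3_se(0.45), m3_se(0))
})

test_that("longitudinal summaries of a run recover the generating baseline", {
  cfg <- cohort_config()
  coh <- generate_cohort(cfg, seed = 61)
  run <- simulate_trial(coh, seed = 62)
  long <- export_long_format(run)
  s <- summarize_longitudinal(long)
  base <- s[s$visit_month == 0, ]
  for (i in seq_len(nrow(base))) {
    target <- cfg$construct_means[[base$construct[i]]]
    tol <- 2 * cfg$construct_sds[[base$construct[i]]] / sqrt(base$n[i]) + 0.1
    expect_lt(abs(base$mean[i] - target), tol)
  }
  expect_true(all(base$n <= table(run$assignments$arm)[as.character(base$arm)]))
})

test_that("dropouts are counted as smokers in the denominator", {
  coh <- generate_cohort(cohort_config(n = 200L), seed = 71)
  heavy_dropout <- behavior_params(dropout = 0.5)
  run <- simulate_trial(coh, heavy_dropout, seed = 72)
  expect_equal(run$table$a + run$table$b + run$table$c + run$table$d, 200)
  # with 50% per-visit dropout almost nobody completes three clean visits
  expect_lt((run$table$a + run$table$c) / 200, 0.05)
})

test_that("parameter recovery finds the generating coefficients", {
  coh <- generate_cohort(cohort_config(n = 2000L), seed = 81)
  run <- simulate_trial(coh, seed = 82)
  rec <- recover_parameters(run)
  expect_true(all(abs(rec$beta$z) < 3.5))
  expect_gt(rec$delta$estimate, 0)

  null_run <- simulate_trial(coh, behavior_params(delta = 0), seed = 83)
  null_rec <- recover_parameters(null_run)
  expect_lte(null_rec$delta$ci_low, 0)
  expect_gte(null_rec$delta$ci_high, 0)
})

test_that("message-engine replay stays consistent with the trial state", {
  coh <- generate_cohort(cohort_config(n = 12L), seed = 91)
  run <- simulate_trial(coh, seed = 92, banks = fixture_banks)
  logs <- run$message_logs
  expect_false(is.null(logs))
  counts <- table(logs$participant_id, logs$day)
  expect_true(all(counts %in% 1:2))
  # control logs identical across participants
  ctrl_ids <- run$assignments$participant_id[run$assignments$arm == "CONTROL"]
  if (length(ctrl_ids) >= 2) {
    l1 <- logs[logs$participant_id == ctrl_ids[1], c("day", "message_id")]
    l2 <- logs[logs$participant_id == ctrl_ids[2], c("day", "message_id")]
    rownames(l1) <- rownames(l2) <- NULL
    expect_identical(l1, l2)
  }
})
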