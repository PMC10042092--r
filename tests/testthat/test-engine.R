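# Calendar, per-day selection, evaluations, control schedule, full protocol.

test_that("phase_for_day partitions days 0..90 per the protocol calendar", {
  expect_equal(phase_for_day(0), "REGISTRATION")
  expect_equal(phase_for_day(c(1, 7)), c("PRE_QUIT", "PRE_QUIT"))
  expect_equal(phase_for_day(8), "QUIT_DAY")
  expect_equal(phase_for_day(c(9, 18)), c("WITHDRAWAL", "WITHDRAWAL"))
  expect_equal(phase_for_day(c(19, 36)), c("EARLY_QUIT", "EARLY_QUIT"))
  expect_equal(phase_for_day(c(37, 90)), c("LATE_QUIT", "LATE_QUIT"))
  expect_error(phase_for_day(91), "0..90")
  expect_error(phase_for_day(-1), "0..90")

  # total and monotone in phase order over the whole window
  phases <- phase_for_day(0:90)
  expect_false(anyNA(phases))
  phase_order <- c("REGISTRATION", "PRE_QUIT", "QUIT_DAY", "WITHDRAWAL",
                   "EARLY_QUIT", "LATE_QUIT")
  expect_true(all(diff(match(phases, phase_order)) >= 0))
  cal <- protocol_calendar()
  expect_true(all(cal$evaluation_days >= 0 & cal$evaluation_days <= cal$last_day))
})

test_that("pre-quit days pair an intention message with a PMT-group message", {
  st <- participant_state("p", "INTERVENTION")
  st$stage_class <- "WEAK_INTENTION"; st$pmt_group <- "SS"
  set.seed(1)
  res <- next_messages(st, 3L, fixture_banks$intervention)
  expect_equal(nrow(res$messages), 2L)
  expect_equal(res$messages$stage_class[1], "WEAK_INTENTION")
  expect_equal(res$messages$pmt_group[2], "SS")
  expect_true(all(res$messages$phase == "PRE_QUIT"))
})

test_that("maintained-abstinence days draw the PMT pool plus a contact filler", {
  st <- participant_state("p", "INTERVENTION")
  st$stage_class <- "MAINTAINED"; st$pmt_group <- "RR"
  set.seed(1)
  res <- next_messages(st, 40L, fixture_banks$intervention)
  expect_equal(nrow(res$messages), 2L)
  expect_equal(res$messages$pmt_group[1], "RR")
  expect_equal(res$messages$kind[2], "CONTACT")

  res1 <- next_messages(st, 40L, fixture_banks$intervention, contact_fill = FALSE)
  expect_equal(nrow(res1$messages), 1L)
})

test_that("pool rotation never repeats a message before exhaustion", {
  st <- participant_state("p", "INTERVENTION")
  st$stage_class <- "RELAPSED"; st$pmt_group <- "EE"
  set.seed(5)
  pool_size <- nrow(pool_for(fixture_banks$intervention, "EARLY_QUIT",
                             "NONE", "EE"))
  picks <- character(0)
  for (d in 1:pool_size) {
    res <- next_messages(st, 20L, fixture_banks$intervention)
    st <- res$state
    picks <- c(picks, res$messages$id[2])
  }
  expect_equal(length(unique(picks)), pool_size)   # one full pass, no repeats
  res <- next_messages(st, 20L, fixture_banks$intervention)
  expect_true(res$messages$id[2] %in% picks)       # rotation restarted
  expect_true(any(grepl("E-EE", res$state$pool_restarts)))
})

test_that("empty required pools raise a configuration error naming the pool", {
  b <- fixture_banks$intervention
  b$messages <- b$messages[bank_labels(b) != "P-SS" | is.na(bank_labels(b)), ]
  st <- participant_state("p", "INTERVENTION")
  st$stage_class <- "WEAK_INTENTION"; st$pmt_group <- "SS"
  expect_error(next_messages(st, 2L, b), "P-SS")
})

test_that("evaluations update stage, status and the target group", {
  st <- participant_state("p", "INTERVENTION")
  prof <- setNames(c(6, 6, 2, 2, 3, 3, 2), PMT_CONSTRUCTS)

  st <- apply_evaluation(st, 0L, prof, intention = 2L)
  expect_equal(st$stage_class, "WEAK_INTENTION")
  expect_equal(st$pmt_group, select_target_group(merged_group_scores(prof)))

  st <- apply_evaluation(st, 19L, prof, self_report_smoked = TRUE)
  expect_equal(st$stage_class, "RELAPSED")
  set.seed(2)
  res <- next_messages(st, 20L, fixture_banks$intervention)
  expect_equal(res$messages$stage_class[1], "RELAPSED")

  # identical inputs leave the state unchanged (idempotent re-evaluation)
  st2 <- apply_evaluation(st, 19L, prof, self_report_smoked = TRUE)
  expect_equal(st2, st)

  expect_error(apply_evaluation(st, 20L, prof, self_report_smoked = FALSE),
               "not an evaluation day")
  expect_warning(apply_evaluation(st, 20L, prof, self_report_smoked = FALSE,
                                  strict = FALSE), "not an evaluation day")
  expect_error(apply_evaluation(st, 0L, prof), "intention")
  expect_error(apply_evaluation(st, 36L, prof), "self-report")
})

test_that("re-evaluated target group always matches the brute-force argmin", {
  set.seed(23)
  st <- participant_state("p", "INTERVENTION")
  for (i in 1:100) {
    prof <- setNames(runif(7, 1, 7), PMT_CONSTRUCTS)
    st <- apply_evaluation(st, 36L, prof, self_report_smoked = FALSE)
    expect_identical(st$pmt_group, brute_force_target(as.list(prof)))
  }
})

test_that("the control schedule is fixed, exhaustive and shared", {
  sched <- schedule_control(fixture_banks$control)
  expect_equal(names(sched), as.character(0:90))
  expect_true(all(lengths(sched) %in% 1:2))
  expect_setequal(unlist(sched), fixture_banks$control$messages$id)

  log1 <- run_protocol("c1", "CONTROL", fixture_banks, seed = 1)
  log2 <- run_protocol("c2", "CONTROL", fixture_banks,
                       assessments = make_stream(), seed = 99)
  expect_equal(log1$message_id, log2$message_id)  # content-independent
  expect_equal(log1$day, log2$day)

  # an unvalidated undersized bank cannot cover the 91 days
  broken <- structure(list(arm = "CONTROL", version = "x",
                           messages = fixture_banks$control$messages[1:50, ]),
                      class = "message_bank")
  expect_error(schedule_control(broken), "cannot cover")
})

test_that("run_protocol produces a complete, replayable 91-day log", {
  stream <- make_stream(intention = 2L,
                        smoked = c(NA, FALSE, TRUE, FALSE, TRUE, FALSE))
  log <- run_protocol("p1", "INTERVENTION", fixture_banks, stream, seed = 31)

  expect_s3_class(log, "message_log")
  expect_setequal(unique(log$day), 0:90)
  counts <- table(log$day)
  expect_true(all(counts %in% 1:2))
  expect_gte(nrow(log), 91L); expect_lte(nrow(log), 182L)
  expect_equal(log$phase[log$day == 8], "QUIT_DAY")

  # byte-for-byte reproducible under the same inputs
  log2 <- run_protocol("p1", "INTERVENTION", fixture_banks, stream, seed = 31)
  expect_identical(log, log2)

  # every personalized pick lies in the pool implied by the latest evaluation
  expect_true(replay_check(log, stream, fixture_banks$intervention))

  expect_error(run_protocol("p1", "INTERVENTION", fixture_banks,
                            stream[stream$day != 45, ], seed = 1),
               "day 45")
})

test_that("message logs export to CSV and JSON-lines", {
  log <- run_protocol("p1", "CONTROL", fixture_banks, seed = 1)
  csv <- withr::local_tempfile(fileext = ".csv")
  save_log(log, csv)
  back <- utils::read.csv(csv, stringsAsFactors = FALSE)
  expect_equal(nrow(back), nrow(log))
  jl <- withr::local_tempfile(fileext = ".jsonl")
  save_log(log[1:3, ], jl)
  expect_equal(length(readLines(jl)), 3L)
})
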