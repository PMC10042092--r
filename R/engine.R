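# The 90-day per-participant delivery state machine: phase calendar,
# evaluation scheduling, per-day message selection for both arms, and a
# replayable message log.

#' The 91-day protocol calendar
#'
#' Day 0 is registration; days 1-7 the pre-quitting phase; day 8 the quit
#' day; days 9-18 withdrawal-symptom management; days 19-36 the early
#' quitting phase; days 37-90 the late quitting phase. In-app evaluations of
#' motivation and status run on days 0, 19, 36, 45, 60 and 75.
#'
#' @return list with `quit_day`, `last_day`, `evaluation_days` and the
#'   per-phase day ranges.
#' @export
protocol_calendar <- function() {
  list(
    registration_day = 0L,
    pre_quit_days    = 1:7,
    quit_day         = 8L,
    withdrawal_days  = 9:18,
    early_quit_days  = 19:36,
    late_quit_days   = 37:90,
    last_day         = 90L,
    evaluation_days  = c(0L, 19L, 36L, 45L, 60L, 75L)
  )
}

#' Programme phase containing a study day
#'
#' @param day integer day(s) in 0..90.
#' @return character vector of phases, one per day.
#' @examples
#' phase_for_day(c(0, 3, 8, 12, 19, 40))
#' @export
phase_for_day <- function(day) {
  if (any(is.na(day)) || any(day < 0 | day > 90 | day != trunc(day))) {
    stop("day must be an integer in 0..90", call. = FALSE)
  }
  cuts <- c(-1, 0, 7, 8, 18, 36, 90)
  labels <- c("REGISTRATION", "PRE_QUIT", "QUIT_DAY", "WITHDRAWAL",
              "EARLY_QUIT", "LATE_QUIT")
  labels[as.integer(cut(day, cuts))]
}

#' Initial per-participant delivery state
#'
#' Tracks the participant's current stage class and PMT target group, the
#' per-pool rotation cursors, and the message history. The state is updated
#' functionally: [next_messages()] and [apply_evaluation()] return modified
#' copies.
#'
#' @param participant_id identifier recorded in logs.
#' @param arm `"INTERVENTION"` or `"CONTROL"`.
#' @return an object of class `participant_state`.
#' @export
participant_state <- function(participant_id, arm) {
  arm <- match_enum(arm, ARMS)
  structure(
    list(participant_id = participant_id, arm = arm,
         stage_class = "NONE", pmt_group = "NONE",
         intention = NA_integer_, last_assessment_day = NA_integer_,
         cursors = list(), pool_restarts = character(0),
         history = list()),
    class = "participant_state")
}

# Rotation-without-repetition draw. Pool order is shuffled (consuming the
# RNG stream) when the pool is entered and again at each exhaustion; within
# one pass no id repeats. Restarts are recorded on the state.
draw_from_pool <- function(state, key, ids) {
  if (length(ids) == 0L) {
    stop(sprintf("message pool '%s' is empty; check the bank configuration", key),
         call. = FALSE)
  }
  cur <- state$cursors[[key]]
  if (is.null(cur) || cur$pos >= length(cur$order) ||
      !setequal(cur$order, ids)) {
    if (!is.null(cur)) state$pool_restarts <- c(state$pool_restarts, key)
    cur <- list(order = sample(ids), pos = 0L)
  }
  cur$pos <- cur$pos + 1L
  state$cursors[[key]] <- cur
  list(id = cur$order[cur$pos], state = state)
}

# ids of messages in a bank matching a predicate, in bank order
bank_ids <- function(bank, phase = NULL, kind = NULL) {
  m <- bank$messages
  sel <- rep(TRUE, nrow(m))
  if (!is.null(phase)) sel <- sel & m$phase == phase
  if (!is.null(kind)) sel <- sel & m$kind == kind
  m$id[sel]
}

#' Select the day's messages for an intervention participant
#'
#' Implements the per-phase delivery rules. Registration and quit day emit
#' their single fixed message; withdrawal days emit one withdrawal-management
#' message; pre-quitting days emit two messages (one from the intention pool,
#' one from the current PMT-group pool); early/late quitting days emit two
#' messages (the relapse pool plus the PMT-group pool for relapsed
#' participants; the PMT-group pool plus a contact message for maintained
#' participants, so the two-messages-per-day cadence holds even though their
#' programme rows carry no stage component). Selection within a pool is
#' rotation without repetition; the RNG stream is consumed only to shuffle
#' rotation order at pool entry/exhaustion.
#'
#' @param state a `participant_state` (intervention arm) whose stage class
#'   and target group reflect the latest evaluation.
#' @param day study day 0..90.
#' @param bank the intervention `message_bank`.
#' @param contact_fill fill the second slot of maintained-abstinence days
#'   with a contact message (default) or send one message only.
#' @return list with `messages` (data.frame of the day's picks, with `slot`)
#'   and the updated `state`.
#' @export
next_messages <- function(state, day, bank, contact_fill = TRUE) {
  stopifnot(inherits(state, "participant_state"),
            inherits(bank, "message_bank"))
  if (state$arm != "INTERVENTION") {
    stop("next_messages() drives the intervention arm; control delivery is a ",
         "fixed schedule (see schedule_control())", call. = FALSE)
  }
  phase <- phase_for_day(day)
  picks <- character(0)

  draw <- function(key, ids) {
    res <- draw_from_pool(state, key, ids)
    state <<- res$state
    picks <<- c(picks, res$id)
  }

  if (phase %in% c("REGISTRATION", "QUIT_DAY")) {
    draw(phase, bank_ids(bank, phase = phase))
  } else if (phase == "WITHDRAWAL") {
    draw("WITHDRAWAL", bank_ids(bank, phase = "WITHDRAWAL"))
  } else if (phase == "PRE_QUIT") {
    if (!state$stage_class %in% c("WEAK_INTENTION", "STRONG_INTENTION")) {
      stop(sprintf("pre-quitting day %d reached with no intention classification; ",
                   day) %+% "run the day-0 evaluation first", call. = FALSE)
    }
    draw(stage_label(phase, state$stage_class),
         pool_ids(bank, phase, stage = state$stage_class))
    draw(group_label(phase, state$pmt_group),
         pool_ids(bank, phase, group = state$pmt_group))
  } else { # EARLY_QUIT / LATE_QUIT
    if (!state$stage_class %in% c("RELAPSED", "MAINTAINED")) {
      stop(sprintf("post-quit day %d reached with no smoking-status classification",
                   day), call. = FALSE)
    }
    if (state$stage_class == "RELAPSED") {
      draw(stage_label(phase, "RELAPSED"),
           pool_ids(bank, phase, stage = "RELAPSED"))
      draw(group_label(phase, state$pmt_group),
           pool_ids(bank, phase, group = state$pmt_group))
    } else {
      draw(group_label(phase, state$pmt_group),
           pool_ids(bank, phase, group = state$pmt_group))
      if (contact_fill) {
        draw(paste0("CONTACT-", PHASE_PREFIX[[phase]]),
             bank_ids(bank, phase = phase, kind = "CONTACT"))
      }
    }
  }

  rows <- bank$messages[match(picks, bank$messages$id), , drop = FALSE]
  rows <- cbind(slot = seq_along(picks), rows)
  rownames(rows) <- NULL
  state$history[[as.character(day)]] <- picks
  list(messages = rows, state = state)
}

`%+%` <- function(a, b) paste0(a, b)

stage_label <- function(phase, stage) {
  paste0(PHASE_PREFIX[[phase]], "-", STAGE_SUFFIX[[stage]])
}
group_label <- function(phase, group) paste0(PHASE_PREFIX[[phase]], "-", group)

pool_ids <- function(bank, phase, stage = NULL, group = NULL) {
  m <- bank$messages
  if (!is.null(stage)) {
    m$id[m$kind == "MOTIVATIONAL" & m$phase == phase & m$stage_class == stage]
  } else {
    if (group == "NONE") {
      stop("no PMT target group set; run an evaluation first", call. = FALSE)
    }
    m$id[m$kind == "MOTIVATIONAL" & m$phase == phase & m$pmt_group == group]
  }
}

#' Apply an in-app evaluation to a participant's state
#'
#' On evaluation days the application re-scores the participant: before the
#' quit day the 5-point intention item sets the stage class (weak/strong
#' intention); after the quit day the self-reported status (optionally
#' CO-verified) sets relapsed/maintained; and in both cases the PMT target
#' group is reset to the weakest merged group of the fresh profile.
#'
#' @param state a `participant_state`.
#' @param day study day; must be one of the calendar's evaluation days in
#'   strict mode, otherwise a warning is raised and the update applied.
#' @param profile `pmt_profile` from [score_pmt()] (or named construct vector).
#' @param intention intention score 1..5 (required before the quit day).
#' @param self_report_smoked logical (required after the quit day).
#' @param co_ppm expired CO reading; used when `verify_co`.
#' @param verify_co biochemically verify the self-report? In-app evaluations
#'   have no CO meter, so the default is `FALSE`.
#' @param tie_order tie-break priority for [select_target_group()].
#' @param calendar protocol calendar.
#' @param strict error (default) or warn on non-evaluation days.
#' @return the updated `participant_state`.
#' @export
apply_evaluation <- function(state, day, profile, intention = NULL,
                             self_report_smoked = NULL, co_ppm = NULL,
                             verify_co = FALSE,
                             tie_order = c("SS", "RR", "EE"),
                             calendar = protocol_calendar(), strict = TRUE) {
  stopifnot(inherits(state, "participant_state"))
  if (!day %in% calendar$evaluation_days) {
    msg <- sprintf("day %d is not an evaluation day (%s)", day,
                   paste(calendar$evaluation_days, collapse = ", "))
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  if (day < calendar$quit_day) {
    if (is.null(intention)) {
      stop(sprintf("evaluation on day %d (pre-quit) needs an intention score", day),
           call. = FALSE)
    }
    state$intention <- as.integer(intention)
    state$stage_class <- classify_intention(intention)
  } else {
    if (is.null(self_report_smoked)) {
      stop(sprintf("evaluation on day %d (post-quit) needs a smoking self-report",
                   day), call. = FALSE)
    }
    state$stage_class <- classify_status(self_report_smoked, co_ppm,
                                         verify_co = verify_co)
  }
  state$pmt_group <- select_target_group(merged_group_scores(profile),
                                         tie_order = tie_order)
  state$last_assessment_day <- as.integer(day)
  state
}

#' Fixed delivery schedule for the control arm
#'
#' Every control participant receives the same messages on the same days
#' with no personalized evaluation. The 91 bank messages are laid out one
#' per day over days 0..90 in bank order; banks holding up to 182 messages
#' are accommodated by doubling up the earliest days, so every message is
#' used at least once and every day carries 1-2 messages.
#'
#' @param bank the control `message_bank`.
#' @return named list mapping each day (`"0"`..`"90"`) to its message ids.
#' @export
schedule_control <- function(bank) {
  stopifnot(inherits(bank, "message_bank"))
  if (bank$arm != "CONTROL") stop("expected a control bank", call. = FALSE)
  n <- nrow(bank$messages)
  n_days <- 91L
  if (n < n_days || n > 2L * n_days) {
    stop(sprintf(
      "control bank size %d cannot cover 91 days at 1-2 messages/day", n),
      call. = FALSE)
  }
  ids <- bank$messages$id
  sched <- as.list(ids[seq_len(n_days)])
  extra <- ids[-seq_len(n_days)]
  for (i in seq_along(extra)) sched[[i]] <- c(sched[[i]], extra[i])
  names(sched) <- as.character(0:90)
  sched
}

#' Run the full 91-day protocol for one participant
#'
#' Drives the delivery state machine from registration (day 0) to day 90.
#' Intervention participants are re-evaluated on the calendar's evaluation
#' days from the supplied assessment stream and receive personalized
#' messages; control participants receive the fixed schedule and their
#' assessment stream is ignored. The log is fully reproducible: the same
#' seed, banks and assessments yield the identical log.
#'
#' @param participant_id identifier recorded in the log.
#' @param arm `"INTERVENTION"` or `"CONTROL"`.
#' @param banks list with elements `intervention` and `control`
#'   (`message_bank` objects); only the participant's arm's bank is used.
#' @param assessments data.frame with one row per evaluation day: columns
#'   `day`, the seven [PMT_CONSTRUCTS] scores, `intention` (used on day 0)
#'   and `self_report_smoked` (used from day 19); optional `co_ppm`.
#' @param seed integer seed for rotation-order shuffles.
#' @param contact_fill see [next_messages()].
#' @param tie_order see [select_target_group()].
#' @return data.frame of class `message_log` with columns `participant_id`,
#'   `day`, `slot`, `message_id`, `phase`, `stage_class`, `pmt_group` (the
#'   participant's classification at selection time); the final
#'   `participant_state` is attached as attribute `"state"`.
#' @export
run_protocol <- function(participant_id, arm, banks, assessments = NULL,
                         seed = 1L, contact_fill = TRUE,
                         tie_order = c("SS", "RR", "EE")) {
  arm <- match_enum(arm, ARMS)
  calendar <- protocol_calendar()
  set.seed(seed)

  if (arm == "CONTROL") {
    sched <- schedule_control(banks$control)
    days <- rep(0:90, times = lengths(sched))
    ids <- unlist(sched, use.names = FALSE)
    m <- banks$control$messages
    log <- data.frame(
      participant_id = participant_id, day = days,
      slot = unlist(lapply(lengths(sched), seq_len), use.names = FALSE),
      message_id = ids, phase = m$phase[match(ids, m$id)],
      stage_class = "NONE", pmt_group = "NONE", stringsAsFactors = FALSE)
    class(log) <- c("message_log", "data.frame")
    attr(log, "state") <- participant_state(participant_id, arm)
    return(log)
  }

  state <- participant_state(participant_id, arm)
  rows <- vector("list", 91L)
  for (day in 0:90) {
    if (day %in% calendar$evaluation_days) {
      if (is.null(assessments)) {
        stop(sprintf("no assessment stream supplied but day %d needs an evaluation",
                     day), call. = FALSE)
      }
      a <- assessments[assessments$day == day, , drop = FALSE]
      if (nrow(a) != 1L) {
        stop(sprintf("assessment stream has no (unique) record for evaluation day %d",
                     day), call. = FALSE)
      }
      profile <- structure(as.numeric(a[1, PMT_CONSTRUCTS]),
                           names = PMT_CONSTRUCTS, class = "pmt_profile")
      state <- apply_evaluation(
        state, day, profile,
        intention = if (day < calendar$quit_day) a$intention[1],
        self_report_smoked = if (day >= calendar$quit_day)
          as.logical(a$self_report_smoked[1]),
        co_ppm = if ("co_ppm" %in% names(a)) a$co_ppm[1],
        tie_order = tie_order, calendar = calendar)
    }
    res <- next_messages(state, day, banks$intervention,
                         contact_fill = contact_fill)
    state <- res$state
    rows[[day + 1L]] <- data.frame(
      participant_id = participant_id, day = day, slot = res$messages$slot,
      message_id = res$messages$id, phase = res$messages$phase,
      stage_class = state$stage_class, pmt_group = state$pmt_group,
      stringsAsFactors = FALSE)
  }
  log <- do.call(rbind, rows)
  rownames(log) <- NULL
  class(log) <- c("message_log", "data.frame")
  attr(log, "state") <- state
  log
}

#' Export a message log to CSV or JSON-lines
#'
#' @param log a `message_log`.
#' @param path destination; `.csv` or `.jsonl` by extension.
#' @return `path`, invisibly.
#' @export
save_log <- function(log, path) {
  ext <- tolower(tools::file_ext(path))
  df <- as.data.frame(log)
  if (ext == "csv") {
    utils::write.csv(df, path, row.names = FALSE)
  } else if (ext %in% c("jsonl", "ndjson")) {
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    for (i in seq_len(nrow(df))) {
      writeLines(jsonlite::toJSON(as.list(df[i, ]), auto_unbox = TRUE), con)
    }
  } else {
    stop("unrecognized log file extension: .", ext, call. = FALSE)
  }
  invisible(path)
}
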