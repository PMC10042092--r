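# Shared fixtures and oracles. Banks are generated in code (no stored data).

fixture_banks <- generate_fixture_banks(seed = 101L)

# A valid assessment stream covering every evaluation day.
make_stream <- function(intention = 5L,
                        smoked = c(NA, FALSE, FALSE, FALSE, FALSE, FALSE),
                        scores = NULL, seed = 7L) {
  set.seed(seed)
  days <- protocol_calendar()$evaluation_days
  a <- data.frame(day = days)
  for (con in PMT_CONSTRUCTS) {
    a[[con]] <- if (is.null(scores)) round(runif(length(days), 1.5, 6.5), 2)
                else rep(scores[[con]], length(days))
  }
  a$intention <- intention
  a$self_report_smoked <- smoked
  a
}

# Brute-force weakest-group oracle, written out independently of
# merged_group_scores()/select_target_group().
brute_force_target <- function(p) {
  ss <- (p[["severity"]] + p[["vulnerability"]]) / 2
  rr <- ((8 - p[["intrinsic_rewards"]]) + (8 - p[["extrinsic_rewards"]]) +
           (8 - p[["response_cost"]])) / 3
  ee <- (p[["self_efficacy"]] + p[["response_efficacy"]]) / 2
  scores <- c(SS = ss, RR = rr, EE = ee)
  best <- names(scores)[scores == min(scores)]
  best[1]  # first in SS > RR > EE priority on ties
}

# Log-replay oracle: re-derives, from the assessment stream alone, the pool
# each personalized pick must come from, and checks every logged message.
# Independent of the engine's internal state machine.
replay_check <- function(log, stream, bank, intention_threshold = 4L) {
  m <- bank$messages
  ids_for <- function(phase, stage = NULL, group = NULL) {
    sel <- m$kind == "MOTIVATIONAL" & m$phase == phase
    if (!is.null(stage)) sel <- sel & m$stage_class == stage
    if (!is.null(group)) sel <- sel & m$pmt_group == group
    m$id[sel]
  }
  ok <- TRUE
  for (day in unique(log$day)) {
    rows <- log[log$day == day, , drop = FALSE]
    phase <- phase_for_day(day)
    if (!phase %in% c("PRE_QUIT", "EARLY_QUIT", "LATE_QUIT")) next
    ev <- stream[stream$day <= day, , drop = FALSE]
    ev <- ev[which.max(ev$day), , drop = FALSE]
    p <- as.list(ev[1, PMT_CONSTRUCTS])
    group <- brute_force_target(p)
    picked <- rows$message_id
    if (phase == "PRE_QUIT") {
      stage <- if (stream$intention[stream$day == 0] >= intention_threshold)
        "STRONG_INTENTION" else "WEAK_INTENTION"
      allowed1 <- ids_for(phase, stage = stage)
      allowed2 <- ids_for(phase, group = group)
      ok <- ok && length(picked) == 2L &&
        picked[1] %in% allowed1 && picked[2] %in% allowed2
    } else {
      relapsed <- isTRUE(as.logical(ev$self_report_smoked[1]))
      if (relapsed) {
        ok <- ok && length(picked) == 2L &&
          picked[1] %in% ids_for(phase, stage = "RELAPSED") &&
          picked[2] %in% ids_for(phase, group = group)
      } else {
        contact_ids <- m$id[m$kind == "CONTACT" & m$phase == phase]
        ok <- ok && length(picked) %in% c(1L, 2L) &&
          picked[1] %in% ids_for(phase, group = group) &&
          (length(picked) == 1L || picked[2] %in% contact_ids)
      }
    }
    if (!ok) return(FALSE)
  }
  ok
}
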