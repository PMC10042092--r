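# Message-bank data model: the three-layer personalized bank used by the
# intervention arm and the fixed 91-message bank used by the control arm.
#
# Layer 1 is the programme phase (calendar), layer 2 the transtheoretical-model
# stage class (quitting intention before the quit day, relapse status after),
# layer 3 the protection-motivation-theory target group. A motivational
# message carries exactly one non-NONE label from layers 2-3, giving the 13
# atomic bank labels P-W, P-S, P-SS, P-RR, P-EE, E-R, E-SS, E-RR, E-EE,
# L-R, L-SS, L-RR, L-EE.

#' Enumerations used by the message bank and delivery engine
#'
#' @format Character vectors of the admissible values.
#' @name textquit-enums
NULL

#' @rdname textquit-enums
#' @export
PHASES <- c("REGISTRATION", "PRE_QUIT", "QUIT_DAY", "WITHDRAWAL",
            "EARLY_QUIT", "LATE_QUIT")

#' @rdname textquit-enums
#' @export
STAGE_CLASSES <- c("WEAK_INTENTION", "STRONG_INTENTION", "RELAPSED",
                   "MAINTAINED", "NONE")

#' @rdname textquit-enums
#' @export
PMT_GROUPS <- c("SS", "RR", "EE", "NONE")

#' @rdname textquit-enums
#' @export
MESSAGE_KINDS <- c("MOTIVATIONAL", "CONTACT", "FIXED")

#' @rdname textquit-enums
#' @export
ARMS <- c("INTERVENTION", "CONTROL")

# Phases whose daily messages are personalized; the other three rows of the
# programme carry fixed content only.
PERSONALIZED_PHASES <- c("PRE_QUIT", "EARLY_QUIT", "LATE_QUIT")

PHASE_PREFIX <- c(PRE_QUIT = "P", EARLY_QUIT = "E", LATE_QUIT = "L")
STAGE_SUFFIX <- c(WEAK_INTENTION = "W", STRONG_INTENTION = "S", RELAPSED = "R")

# The 13 atomic motivational bank labels.
BANK_LABELS <- c("P-W", "P-S", "P-SS", "P-RR", "P-EE",
                 "E-R", "E-SS", "E-RR", "E-EE",
                 "L-R", "L-SS", "L-RR", "L-EE")

MESSAGE_COLUMNS <- c("id", "phase", "stage_class", "pmt_group", "kind", "text")

#' Construct a message bank
#'
#' A bank is a validated table of messages plus the arm it serves. The
#' intervention bank mixes motivational, contact and fixed (registration,
#' quit-day, withdrawal-management) messages; the control bank is exactly 91
#' fixed messages delivered identically to every control participant.
#'
#' @param messages data.frame with columns `id`, `phase`, `stage_class`,
#'   `pmt_group`, `kind`, `text`.
#' @param arm `"INTERVENTION"` or `"CONTROL"`.
#' @param version free-form version string recorded in exports.
#' @return An object of class `message_bank`.
#' @seealso [load_bank()], [generate_fixture_banks()], [pool_for()]
#' @export
message_bank <- function(messages, arm, version = "0") {
  arm <- match_enum(arm, ARMS)
  messages <- as.data.frame(messages, stringsAsFactors = FALSE)
  rownames(messages) <- NULL
  bank <- structure(
    list(arm = arm, version = as.character(version), messages = messages),
    class = "message_bank")
  validate_bank(bank)
}

#' @export
print.message_bank <- function(x, ...) {
  cat(sprintf("<message_bank> arm=%s version=%s messages=%d\n",
              x$arm, x$version, nrow(x$messages)))
  tab <- table(x$messages$kind)
  cat("  kinds:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

#' Validate a message bank against its structural invariants
#'
#' Checks column presence, enum membership, id uniqueness, the
#' no-personalization rule for registration/quit-day/withdrawal rows, the
#' atomic-label rule for motivational messages, and the 91-fixed-message
#' contract for control banks. Errors list the offending ids.
#'
#' @param bank a `message_bank`.
#' @return `bank`, invisibly intact, on success.
#' @export
validate_bank <- function(bank) {
  stopifnot(inherits(bank, "message_bank"))
  m <- bank$messages
  missing_cols <- setdiff(MESSAGE_COLUMNS, names(m))
  if (length(missing_cols)) {
    stop("bank is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(m) == 0L) stop("a message bank must be non-empty", call. = FALSE)

  bad_enum <- function(col, choices) m$id[!m[[col]] %in% choices]
  for (chk in list(list("phase", PHASES), list("stage_class", STAGE_CLASSES),
                   list("pmt_group", PMT_GROUPS), list("kind", MESSAGE_KINDS))) {
    bad <- bad_enum(chk[[1]], chk[[2]])
    if (length(bad)) {
      stop(sprintf("invalid %s for message id(s): %s", chk[[1]],
                   paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
    }
  }

  dup <- unique(m$id[duplicated(m$id)])
  if (length(dup)) {
    stop("duplicated message id(s): ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }

  fixed_phase <- m$phase %in% c("REGISTRATION", "QUIT_DAY", "WITHDRAWAL")
  bad <- m$id[fixed_phase & (m$stage_class != "NONE" | m$pmt_group != "NONE")]
  if (length(bad)) {
    stop("registration/quit-day/withdrawal messages carry no personalization; ",
         "offending id(s): ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  }

  mot <- m$kind == "MOTIVATIONAL"
  bad <- m$id[mot & !(m$phase %in% PERSONALIZED_PHASES)]
  if (length(bad)) {
    stop("motivational messages must sit in a personalized phase; id(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  # atomic label: exactly one of stage_class / pmt_group is non-NONE
  n_labels <- (m$stage_class != "NONE") + (m$pmt_group != "NONE")
  bad <- m$id[mot & n_labels != 1L]
  if (length(bad)) {
    stop("motivational messages carry exactly one stage-class or PMT-group ",
         "label; offending id(s): ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  bad <- m$id[mot & m$stage_class %in% c("MAINTAINED")]
  if (length(bad)) {
    stop("maintained-abstinence rows take no stage-class messages ",
         "(PMT-group pools only); offending id(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  # intention labels only before the quit day, relapse labels only after
  bad <- m$id[mot & m$phase == "PRE_QUIT" & m$stage_class == "RELAPSED"]
  if (length(bad)) {
    stop("relapse-labelled messages cannot sit in the pre-quitting phase; ",
         "id(s): ", paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  bad <- m$id[mot & m$phase != "PRE_QUIT" &
                m$stage_class %in% c("WEAK_INTENTION", "STRONG_INTENTION")]
  if (length(bad)) {
    stop("intention-labelled messages belong to the pre-quitting phase; ",
         "id(s): ", paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }

  if (bank$arm == "CONTROL") {
    if (nrow(m) != 91L) {
      stop(sprintf("a control bank holds exactly 91 messages (got %d)", nrow(m)),
           call. = FALSE)
    }
    bad <- m$id[m$kind != "FIXED" | m$stage_class != "NONE" | m$pmt_group != "NONE"]
    if (length(bad)) {
      stop("control-bank messages are fixed and unpersonalized; id(s): ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
  }
  invisible(bank)
}

#' Atomic bank label of each message
#'
#' Maps motivational messages to their Table-style label (`"P-W"`, `"E-RR"`,
#' ...); fixed and contact messages get `NA`.
#'
#' @param bank a `message_bank`.
#' @return character vector, one element per message.
#' @export
bank_labels <- function(bank) {
  m <- bank$messages
  out <- rep(NA_character_, nrow(m))
  mot <- m$kind == "MOTIVATIONAL"
  pref <- PHASE_PREFIX[m$phase[mot]]
  suff <- ifelse(m$pmt_group[mot] != "NONE", m$pmt_group[mot],
                 STAGE_SUFFIX[m$stage_class[mot]])
  out[mot] <- paste0(pref, "-", suff)
  out
}

#' Read a message bank from JSON or CSV
#'
#' The canonical dialect is JSON with top-level fields `arm`, `version` and a
#' `messages` array; a CSV mirror with the same column names is accepted for
#' hand-edited banks (`arm`/`version` then come from the arguments).
#'
#' @param path file path; dialect chosen by extension (`.json` vs `.csv`).
#' @param arm expected arm; the file's own `arm` field must agree.
#' @param version fallback version for CSV files.
#' @return a validated `message_bank`.
#' @export
load_bank <- function(path, arm, version = "0") {
  arm <- match_enum(arm, ARMS)
  if (!file.exists(path)) stop("no such bank file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    parsed <- tryCatch(jsonlite::fromJSON(path),
                       error = function(e) stop(sprintf(
                         "malformed bank file %s: %s", path, conditionMessage(e)),
                         call. = FALSE))
    for (field in c("arm", "messages")) {
      if (is.null(parsed[[field]])) {
        stop(sprintf("bank file %s lacks required field '%s'", path, field),
             call. = FALSE)
      }
    }
    if (!identical(parsed$arm, arm)) {
      stop(sprintf("bank file %s is for arm %s, expected %s", path,
                   parsed$arm, arm), call. = FALSE)
    }
    msgs <- as.data.frame(parsed$messages, stringsAsFactors = FALSE)
    version <- parsed$version %||% version
  } else if (ext == "csv") {
    msgs <- utils::read.csv(path, stringsAsFactors = FALSE,
                            colClasses = "character", fileEncoding = "UTF-8")
  } else {
    stop("unrecognized bank file extension: .", ext, call. = FALSE)
  }
  message_bank(msgs, arm = arm, version = version)
}

#' Write a message bank to JSON or CSV
#'
#' @param bank a `message_bank`.
#' @param path destination; dialect chosen by extension.
#' @return `path`, invisibly.
#' @export
save_bank <- function(bank, path) {
  validate_bank(bank)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(
      list(arm = bank$arm, version = bank$version, messages = bank$messages),
      path, auto_unbox = TRUE, pretty = TRUE)
  } else if (ext == "csv") {
    utils::write.csv(bank$messages, path, row.names = FALSE,
                     fileEncoding = "UTF-8")
  } else {
    stop("unrecognized bank file extension: .", ext, call. = FALSE)
  }
  invisible(path)
}

placeholder_text <- function(label, i, topic) {
  sprintf("[%s #%d] Placeholder %s message.", label, i, topic)
}

#' Generate deterministic fixture banks
#'
#' Builds a complete intervention bank and control bank with placeholder
#' texts so the delivery engine and trial simulator can run without the real
#' (Chinese-language) message content. The intervention bank holds exactly
#' 200 motivational messages spread over the 13 atomic labels (every label
#' non-empty), about 200 contact messages, one registration and one quit-day
#' message, and a 10-message withdrawal-management rotation. The control bank
#' holds exactly 91 fixed messages. Each placeholder text embeds its own
#' label and index so selections are auditable in logs.
#'
#' @param seed integer; the generator is byte-identical under the same seed.
#' @param n_motivational total motivational messages (default 200).
#' @param n_contact total contact messages (default 200).
#' @param n_control control-bank size (default, and required by
#'   [validate_bank()], 91).
#' @return list with elements `intervention` and `control`, both
#'   `message_bank` objects.
#' @export
generate_fixture_banks <- function(seed = 1L, n_motivational = 200L,
                                   n_contact = 200L, n_control = 91L) {
  stopifnot(is_scalar_int(seed), n_motivational >= length(BANK_LABELS))
  set.seed(seed)

  # spread motivational counts as evenly as the total allows, extras going to
  # the earliest labels; every label non-empty by construction
  k <- length(BANK_LABELS)
  counts <- rep(n_motivational %/% k, k) +
    c(rep(1L, n_motivational %% k), rep(0L, k - n_motivational %% k))
  names(counts) <- BANK_LABELS

  label_fields <- function(label) {
    parts <- strsplit(label, "-", fixed = TRUE)[[1]]
    phase <- names(PHASE_PREFIX)[PHASE_PREFIX == parts[1]]
    if (parts[2] %in% PMT_GROUPS) {
      list(phase = phase, stage_class = "NONE", pmt_group = parts[2])
    } else {
      stage <- names(STAGE_SUFFIX)[STAGE_SUFFIX == parts[2]]
      list(phase = phase, stage_class = stage, pmt_group = "NONE")
    }
  }

  topics <- sample(c("encouragement", "health-fact", "coping-tip",
                     "family", "cost-saving", "self-image"),
                   n_motivational, replace = TRUE)
  rows <- vector("list", 0L)
  t_i <- 0L
  for (label in BANK_LABELS) {
    f <- label_fields(label)
    n <- counts[[label]]
    idx <- seq_len(n)
    rows[[label]] <- data.frame(
      id = sprintf("%s-%03d", label, idx),
      phase = f$phase, stage_class = f$stage_class, pmt_group = f$pmt_group,
      kind = "MOTIVATIONAL",
      text = placeholder_text(label, idx, topics[t_i + idx]),
      stringsAsFactors = FALSE)
    t_i <- t_i + n
  }

  contact_phase <- rep(c("EARLY_QUIT", "LATE_QUIT"), length.out = n_contact)
  contact <- data.frame(
    id = sprintf("C-%s-%03d", ifelse(contact_phase == "EARLY_QUIT", "E", "L"),
                 seq_len(n_contact)),
    phase = contact_phase, stage_class = "NONE", pmt_group = "NONE",
    kind = "CONTACT",
    text = sprintf("[CONTACT #%d] Placeholder check-in message.", seq_len(n_contact)),
    stringsAsFactors = FALSE)

  fixed <- data.frame(
    id = c("REG-001", "QD-001", sprintf("WD-%03d", 1:10)),
    phase = c("REGISTRATION", "QUIT_DAY", rep("WITHDRAWAL", 10)),
    stage_class = "NONE", pmt_group = "NONE", kind = "FIXED",
    text = c("[REG #1] Placeholder registration message announcing the quit date.",
             "[QD #1] Placeholder quit-day message.",
             sprintf("[WD #%d] Placeholder withdrawal-management tip.", 1:10)),
    stringsAsFactors = FALSE)

  intervention <- message_bank(
    rbind(do.call(rbind, rows), contact, fixed),
    arm = "INTERVENTION", version = sprintf("fixture-seed%d", seed))

  control <- message_bank(
    data.frame(
      id = sprintf("CTRL-%03d", seq_len(n_control)),
      phase = phase_for_day(seq_len(n_control) - 1L),
      stage_class = "NONE", pmt_group = "NONE", kind = "FIXED",
      text = sprintf("[CTRL #%d] Placeholder non-personalized cessation message.",
                     seq_len(n_control)),
      stringsAsFactors = FALSE),
    arm = "CONTROL", version = sprintf("fixture-seed%d", seed))

  list(intervention = intervention, control = control)
}

#' Per-day personalized message pool
#'
#' Returns the motivational messages a participant is eligible for on a
#' personalized day: the union of the phase's stage-class pool and the
#' phase's PMT-group pool. Maintained-abstinence participants have no
#' stage-class pool (their programme rows carry no transtheoretical-model
#' component), so the union degenerates to the PMT-group pool.
#'
#' @param bank a `message_bank`.
#' @param phase one of `"PRE_QUIT"`, `"EARLY_QUIT"`, `"LATE_QUIT"`.
#' @param stage_class stage class of the participant.
#' @param pmt_group current PMT target group (`"SS"`, `"RR"`, `"EE"`).
#' @return data.frame of matching messages, in bank order.
#' @export
pool_for <- function(bank, phase, stage_class, pmt_group) {
  stopifnot(inherits(bank, "message_bank"))
  if (!phase %in% PERSONALIZED_PHASES) {
    stop(sprintf("phase %s carries no personalized pool", phase), call. = FALSE)
  }
  match_enum(stage_class, STAGE_CLASSES)
  match_enum(pmt_group, PMT_GROUPS)
  m <- bank$messages
  sel <- m$kind == "MOTIVATIONAL" & m$phase == phase &
    ((m$stage_class == stage_class & stage_class != "NONE") |
       (m$pmt_group == pmt_group & pmt_group != "NONE"))
  m[sel, , drop = FALSE]
}
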