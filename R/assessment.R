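# Scoring of the 21-item protection-motivation-theory (PMT) scale, merging of
# the seven constructs into the three intervention target groups, selection of
# the weakest group, and classification of quitting intention and smoking
# status.

#' The seven PMT constructs, in canonical order
#' @export
PMT_CONSTRUCTS <- c("severity", "vulnerability", "intrinsic_rewards",
                    "extrinsic_rewards", "self_efficacy", "response_efficacy",
                    "response_cost")

# Constructs whose high scores are maladaptive (reflected before merging).
MALADAPTIVE_CONSTRUCTS <- c("intrinsic_rewards", "extrinsic_rewards",
                            "response_cost")

# Fixed item->construct map for the 21-item scale: items 1-3 -> severity,
# 4-6 -> vulnerability, ..., 19-21 -> response_cost, in PMT_CONSTRUCTS order.
#' Item-to-construct map of the 21-item PMT scale
#'
#' @return data.frame with columns `item` (1..21) and `construct`.
#' @export
pmt_item_map <- function() {
  data.frame(item = 1:21,
             construct = rep(PMT_CONSTRUCTS, each = 3L),
             stringsAsFactors = FALSE)
}

#' Score the 21-item PMT scale into seven construct means
#'
#' Each construct is measured by three 7-point Likert items (1 = definitely
#' disagree, 7 = definitely agree); the construct score is the arithmetic
#' mean of its three items. No imputation is performed: a missing or
#' out-of-range item is an error naming the construct and item position.
#'
#' @param items either a named list mapping each construct to its 3 integer
#'   responses, or an unnamed numeric vector of all 21 responses in
#'   [pmt_item_map()] order.
#' @return named numeric vector of length 7 (class `pmt_profile`), each
#'   entry in `[1, 7]`.
#' @examples
#' score_pmt(rep(7, 21))
#' @export
score_pmt <- function(items) {
  if (is.numeric(items)) {
    items <- unname(items)
    if (length(items) != 21L) {
      stop(sprintf("the scale has exactly 21 items (got %d)", length(items)),
           call. = FALSE)
    }
    items <- split(items, rep(PMT_CONSTRUCTS, each = 3L))
  }
  missing_con <- setdiff(PMT_CONSTRUCTS, names(items))
  if (length(missing_con)) {
    stop("missing responses for construct(s): ",
         paste(missing_con, collapse = ", "), call. = FALSE)
  }
  out <- vapply(PMT_CONSTRUCTS, function(con) {
    x <- items[[con]]
    if (length(x) != 3L) {
      stop(sprintf("construct '%s' needs exactly 3 item responses (got %d)",
                   con, length(x)), call. = FALSE)
    }
    bad <- which(is.na(x) | !(x %in% 1:7))
    if (length(bad)) {
      stop(sprintf("invalid response for construct '%s', item %d (values must be 1..7)",
                   con, bad[1]), call. = FALSE)
    }
    mean(x)
  }, numeric(1))
  structure(out, class = "pmt_profile")
}

#' Reflect a Likert score about the scale midpoint
#'
#' `reflect(x) = 8 - x` maps `[1, 7]` onto itself and is its own inverse.
#' Applied to the maladaptive constructs (rewards of smoking, response cost
#' of quitting) so that "higher = more protected" holds for every merged
#' group score.
#'
#' @param x scores in `[1, 7]`.
#' @export
reflect <- function(x) {
  stopifnot(all(x >= 1 & x <= 7))
  8 - x
}

#' Merge the seven construct scores into the three target-group scores
#'
#' The intervention targets one of three merged groups: SS (severity and
#' susceptibility), RR (rewards of smoking and response cost of quitting,
#' all reflected) and EE (self-efficacy and response efficacy). Each merged
#' score is the mean of its constituent construct scores after direction
#' alignment, so every group score reads "higher = more protected".
#'
#' @param profile a `pmt_profile` (or named numeric vector over
#'   [PMT_CONSTRUCTS]).
#' @return named numeric vector `c(SS=, RR=, EE=)`, each in `[1, 7]`.
#' @export
merged_group_scores <- function(profile) {
  p <- unclass(profile)
  missing_con <- setdiff(PMT_CONSTRUCTS, names(p))
  if (length(missing_con)) {
    stop("profile lacks construct(s): ", paste(missing_con, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(all(p[PMT_CONSTRUCTS] >= 1 & p[PMT_CONSTRUCTS] <= 7))
  c(SS = mean(c(p[["severity"]], p[["vulnerability"]])),
    RR = mean(reflect(c(p[["intrinsic_rewards"]], p[["extrinsic_rewards"]],
                        p[["response_cost"]]))),
    EE = mean(c(p[["self_efficacy"]], p[["response_efficacy"]])))
}

#' Select the target group that needs to be strengthened
#'
#' Returns the merged group with the lowest protection score — the weakest
#' link, which the next block of personalized messages will address. Ties
#' are broken by a fixed priority order so targeting is deterministic.
#'
#' @param scores output of [merged_group_scores()].
#' @param tie_order priority order used on exact ties (default SS, RR, EE).
#' @return `"SS"`, `"RR"` or `"EE"`.
#' @export
select_target_group <- function(scores, tie_order = c("SS", "RR", "EE")) {
  stopifnot(setequal(names(scores), c("SS", "RR", "EE")),
            setequal(tie_order, c("SS", "RR", "EE")))
  ordered <- scores[tie_order]
  tie_order[which.min(ordered)]
}

#' Classify quitting intention as strong or weak
#'
#' Intention to quit within 6 months is measured on a 5-point scale from
#' "not at all likely" (1) to "very likely" (5). Scores at or above the
#' threshold are classified as strong intention.
#'
#' @param score integer 1..5.
#' @param threshold cut point; default 4.
#' @return `"STRONG_INTENTION"` or `"WEAK_INTENTION"`.
#' @export
classify_intention <- function(score, threshold = 4L) {
  if (!is_scalar_int(score) || score < 1 || score > 5) {
    stop("intention score must be a single integer in 1..5", call. = FALSE)
  }
  if (score >= threshold) "STRONG_INTENTION" else "WEAK_INTENTION"
}

#' Classify smoking status from a self-report and optional CO verification
#'
#' A participant is maintained-abstinent only when they report no smoking
#' since the last assessment and, when verification is requested, their
#' expired carbon monoxide is strictly below 6 ppm (consistent with recent
#' non-smoking). A positive self-report dominates any CO reading.
#'
#' @param self_report_smoked logical; smoked since last assessment?
#' @param co_ppm expired CO in ppm (required when `verify_co`).
#' @param verify_co require biochemical verification?
#' @param co_threshold strict upper bound in ppm; default 6.
#' @return `"MAINTAINED"` or `"RELAPSED"`.
#' @export
classify_status <- function(self_report_smoked, co_ppm = NULL,
                            verify_co = TRUE, co_threshold = 6) {
  stopifnot(is.logical(self_report_smoked), length(self_report_smoked) == 1L,
            !is.na(self_report_smoked))
  if (verify_co && (is.null(co_ppm) || is.na(co_ppm))) {
    stop("CO verification requested but no co_ppm reading supplied",
         call. = FALSE)
  }
  if (!is.null(co_ppm) && !is.na(co_ppm) && co_ppm < 0) {
    stop("co_ppm must be non-negative", call. = FALSE)
  }
  ok <- !self_report_smoked && (!verify_co || co_ppm < co_threshold)
  if (ok) "MAINTAINED" else "RELAPSED"
}
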