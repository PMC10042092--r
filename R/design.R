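# Trial design: stratified randomization (simple within strata, or
# Pocock-Simon minimization), two-proportion sample-size planning with
# attrition inflation, and Russell-standard intention-to-treat outcome
# adjudication.

#' Randomization plan
#'
#' Participants are first split by nicotine dependence into a low stratum
#' and a moderate/high stratum; within each stratum allocation is either
#' simple (fair coin) or Pocock-Simon minimization over the configured
#' balance covariates.
#'
#' @param method `"SIMPLE_WITHIN_STRATA"` (default) or `"MINIMIZATION"`.
#' @param covariates covariate column names balanced under minimization.
#' @param seed integer seed; assignment depends only on (seed, cohort order,
#'   method).
#' @param strata function mapping the `dependence` column to stratum labels;
#'   the default pools moderate and high dependence.
#' @return list of class `randomization_plan`.
#' @export
randomization_plan <- function(method = c("SIMPLE_WITHIN_STRATA", "MINIMIZATION"),
                               covariates = character(0), seed = 1L,
                               strata = default_strata) {
  method <- match.arg(method)
  stopifnot(is_scalar_int(seed))
  structure(list(method = method, covariates = covariates,
                 seed = as.integer(seed), strata = strata),
            class = "randomization_plan")
}

default_strata <- function(dependence) {
  ifelse(dependence == "LOW", "LOW", "MODERATE_HIGH")
}

#' Randomize a cohort to trial arms
#'
#' Fully computerized 1:1 allocation. Under simple randomization each
#' participant is assigned by an independent fair coin within their
#' dependence stratum; under minimization each arrival goes to the arm that
#' minimizes the summed absolute arm imbalance over the plan's covariates
#' (within stratum), with ties broken by a fair coin.
#'
#' @param cohort data.frame with `participant_id` and `dependence`
#'   (`"LOW"`, `"MODERATE"`, `"HIGH"`), plus any minimization covariates.
#' @param plan a [randomization_plan()].
#' @return data.frame `participant_id`, `stratum`, `arm`.
#' @export
randomize <- function(cohort, plan = randomization_plan()) {
  stopifnot(inherits(plan, "randomization_plan"),
            all(c("participant_id", "dependence") %in% names(cohort)))
  bad <- !cohort$dependence %in% c("LOW", "MODERATE", "HIGH")
  if (any(bad)) {
    stop("unknown dependence level for participant(s): ",
         paste(utils::head(cohort$participant_id[bad], 5), collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(cohort)
  stratum <- plan$strata(cohort$dependence)
  arm <- character(n)
  set.seed(plan$seed)

  if (plan$method == "SIMPLE_WITHIN_STRATA") {
    # fair coin per participant; drawing stratum-by-stratum keeps each
    # stratum's sequence reproducible regardless of interleaving
    for (s in unique(stratum)) {
      idx <- which(stratum == s)
      arm[idx] <- ifelse(stats::runif(length(idx)) < 0.5,
                         "INTERVENTION", "CONTROL")
    }
  } else {
    missing_cov <- setdiff(plan$covariates, names(cohort))
    if (length(missing_cov)) {
      stop("minimization covariates absent from cohort: ",
           paste(missing_cov, collapse = ", "), call. = FALSE)
    }
    covs <- c("stratum", plan$covariates)
    tab <- cohort
    tab$stratum <- stratum
    # running per-(covariate, level, arm) counts
    counts <- new.env(parent = emptyenv())
    key <- function(cov, lev, a) paste(cov, lev, a, sep = "\r")
    get0n <- function(k) if (is.null(counts[[k]])) 0L else counts[[k]]
    for (i in seq_len(n)) {
      imbalance <- function(a) {
        sum(vapply(covs, function(cov) {
          lev <- as.character(tab[[cov]][i])
          ni <- get0n(key(cov, lev, "INTERVENTION")) + (a == "INTERVENTION")
          nc <- get0n(key(cov, lev, "CONTROL")) + (a == "CONTROL")
          abs(ni - nc)
        }, numeric(1)))
      }
      di <- imbalance("INTERVENTION"); dc <- imbalance("CONTROL")
      arm[i] <- if (di < dc) "INTERVENTION"
        else if (dc < di) "CONTROL"
        else if (stats::runif(1) < 0.5) "INTERVENTION" else "CONTROL"
      for (cov in covs) {
        k <- key(cov, as.character(tab[[cov]][i]), arm[i])
        counts[[k]] <- get0n(k) + 1L
      }
    }
  }
  data.frame(participant_id = cohort$participant_id, stratum = stratum,
             arm = arm, stringsAsFactors = FALSE)
}

#' Per-group sample size for a two-proportion comparison
#'
#' Unpooled-variance normal approximation:
#' `n = ceil( (z[1-a/2] + z[power])^2 * (p1(1-p1) + p2(1-p2)) / (p1-p2)^2 )`.
#' With 4% vs 10% abstinence, two-sided alpha 0.05 and 80% power this gives
#' 280 per group.
#'
#' @param p1,p2 anticipated proportions in the two arms (unequal).
#' @param alpha two-sided significance level.
#' @param power desired power (1 - beta).
#' @return integer per-group n.
#' @examples
#' sample_size_two_props(0.04, 0.10, alpha = 0.05, power = 0.80)
#' @export
sample_size_two_props <- function(p1, p2, alpha = 0.05, power = 0.80) {
  stopifnot(p1 > 0, p1 < 1, p2 > 0, p2 < 1, alpha > 0, alpha < 1,
            power > 0, power < 1)
  if (p1 == p2) stop("p1 and p2 must differ", call. = FALSE)
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  as.integer(ceiling(z^2 * (p1 * (1 - p1) + p2 * (1 - p2)) / (p1 - p2)^2))
}

#' Inflate a per-group sample size for anticipated attrition
#'
#' Total N = `ceil(2 * n * (1 + attrition))` — the multiply-by-(1+rate)
#' convention, which turns 280 per group at 20% attrition into 672 total.
#'
#' @param per_group_n integer per-group sample size.
#' @param attrition anticipated attrition proportion in `[0, 1)`.
#' @return integer total sample size over both groups.
#' @export
inflate_attrition <- function(per_group_n, attrition) {
  stopifnot(is_scalar_int(per_group_n), per_group_n > 0)
  if (attrition < 0 || attrition >= 1) {
    stop("attrition must lie in [0, 1)", call. = FALSE)
  }
  as.integer(ceiling(2 * per_group_n * (1 + attrition)))
}

#' Russell-standard continuous abstinence from one outcome record
#'
#' A participant counts as continuously abstinent only if all three
#' scheduled follow-up visits (months 1, 3 and 6) took place, every visit's
#' self-report is no cigarettes since the designated quit day, and every
#' visit's expired CO is strictly below the threshold. Any missed visit —
#' including loss to follow-up — counts as smoking.
#'
#' @param record data.frame with one row per scheduled visit: columns
#'   `visit_month`, `self_report_smoked` (logical, `NA` = missing visit),
#'   `co_ppm` (`NA` = missing reading).
#' @param co_threshold strict ppm bound, default 6.
#' @param visit_months required visits, default `c(1, 3, 6)`.
#' @return logical scalar.
#' @export
russell_abstinence <- function(record, co_threshold = 6,
                               visit_months = c(1, 3, 6)) {
  stopifnot(all(c("visit_month", "self_report_smoked", "co_ppm") %in%
                  names(record)))
  for (m in visit_months) {
    v <- record[record$visit_month == m, , drop = FALSE]
    if (nrow(v) != 1L) return(FALSE)                      # unscheduled/missing
    if (is.na(v$self_report_smoked) || is.na(v$co_ppm)) return(FALSE)
    if (v$self_report_smoked) return(FALSE)
    if (v$co_ppm >= co_threshold) return(FALSE)
  }
  TRUE
}

#' Adjudicate trial outcomes into a 2x2 table
#'
#' Applies [russell_abstinence()] per participant under intention to treat:
#' every randomized participant appears in their assigned arm's denominator,
#' with dropouts counted as smokers.
#'
#' @param outcomes long data.frame: `participant_id`, `visit_month`,
#'   `self_report_smoked`, `co_ppm`.
#' @param assignments data.frame `participant_id`, `arm` (from [randomize()]).
#' @param co_threshold strict ppm bound, default 6.
#' @return a [two_by_two()] table.
#' @export
adjudicate_outcomes <- function(outcomes, assignments, co_threshold = 6,
                                visit_months = c(1, 3, 6)) {
  sub <- outcomes[outcomes$visit_month %in% visit_months, , drop = FALSE]
  ok <- !is.na(sub$self_report_smoked) & !is.na(sub$co_ppm) &
    !sub$self_report_smoked & sub$co_ppm < co_threshold
  pm <- paste(sub$participant_id, sub$visit_month, sep = "\r")
  agg <- rowsum(cbind(n = rep(1, nrow(sub)), ok = as.numeric(ok)), pm)
  good <- agg[, "n"] == 1 & agg[, "ok"] == 1        # exactly one clean record
  pid_of <- vapply(strsplit(rownames(agg), "\r", fixed = TRUE), `[[`, "", 1L)
  n_good <- tapply(good, pid_of, sum)
  abstinent_ids <- names(n_good)[n_good == length(visit_months)]
  abst <- assignments$participant_id %in% abstinent_ids
  int <- assignments$arm == "INTERVENTION"
  two_by_two(a = sum(abst & int), b = sum(!abst & int),
             c = sum(abst & !int), d = sum(!abst & !int))
}
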