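# Trial analysis: ITT abstinence rates, 2x2 odds ratio with Woolf interval,
# chi-square comparison, longitudinal construct-score summaries, and an
# independence-working logistic (IRLS) fitter used as the simulation-recovery
# oracle.

#' A 2x2 trial outcome table
#'
#' Cell layout: `a` = intervention abstinent, `b` = intervention
#' not-abstinent, `c` = control abstinent, `d` = control not-abstinent.
#' Row totals are the randomized arm sizes (intention to treat).
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @return object of class `two_by_two`.
#' @export
two_by_two <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  stopifnot(all(cells >= 0), all(cells == trunc(cells)))
  structure(as.list(cells), class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, byrow = TRUE,
              dimnames = list(c("intervention", "control"),
                              c("abstinent", "not abstinent")))
  print(m)
  invisible(x)
}

as_matrix_2x2 <- function(tab) {
  matrix(c(tab$a, tab$b, tab$c, tab$d), nrow = 2, byrow = TRUE)
}

#' Per-arm abstinence proportions
#'
#' @param tab a [two_by_two()].
#' @return list with `intervention` and `control` proportions and their
#'   one-decimal percent renderings (`intervention_pct`, `control_pct`).
#' @examples
#' abstinence_rates(two_by_two(25, 335, 11, 351))
#' @export
abstinence_rates <- function(tab) {
  stopifnot(inherits(tab, "two_by_two"))
  n1 <- tab$a + tab$b; n0 <- tab$c + tab$d
  if (n1 == 0L || n0 == 0L) stop("empty arm: zero denominator", call. = FALSE)
  p1 <- tab$a / n1; p0 <- tab$c / n0
  list(intervention = p1, control = p0,
       intervention_pct = round(100 * p1, 1), control_pct = round(100 * p0, 1))
}

#' Odds ratio with Woolf (log-normal) confidence interval
#'
#' `OR = ad / bc`; `CI = exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`.
#' Zero cells make the Woolf variance undefined; the Haldane-Anscombe
#' correction (add 0.5 to every cell) is available as an explicit opt-in.
#'
#' @param tab a [two_by_two()].
#' @param alpha two-sided level (default 0.05 for a 95% interval).
#' @param haldane apply the +0.5 continuity correction to all cells.
#' @return list of class `effect_estimate`: `odds_ratio`, `ci_low`,
#'   `ci_high`, `alpha`.
#' @examples
#' odds_ratio_ci(two_by_two(25, 335, 11, 351))
#' @export
odds_ratio_ci <- function(tab, alpha = 0.05, haldane = FALSE) {
  stopifnot(inherits(tab, "two_by_two"), alpha > 0, alpha < 1)
  cells <- c(tab$a, tab$b, tab$c, tab$d)
  if (any(cells == 0)) {
    if (!haldane) {
      stop("zero cell in 2x2 table: the Woolf interval is undefined; ",
           "re-run with haldane = TRUE to apply the Haldane-Anscombe +0.5 ",
           "correction", call. = FALSE)
    }
    cells <- cells + 0.5
  }
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - alpha / 2)
  structure(list(odds_ratio = or, ci_low = exp(log(or) - z * se),
                 ci_high = exp(log(or) + z * se), alpha = alpha),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("OR: %.2f; %d%% CI: %.2f-%.2f\n", x$odds_ratio,
              round(100 * (1 - x$alpha)), x$ci_low, x$ci_high))
  invisible(x)
}

#' Chi-square comparison of the two arms' abstinence rates
#'
#' Pearson chi-square on the 2x2 table with 1 degree of freedom, optionally
#' Yates-corrected. A warning recommending an exact test is raised when any
#' expected cell count falls below 1.
#'
#' @param tab a [two_by_two()].
#' @param yates apply the Yates continuity correction (default `FALSE`).
#' @return list `statistic`, `p_value`, `df`.
#' @export
chi_square <- function(tab, yates = FALSE) {
  stopifnot(inherits(tab, "two_by_two"))
  m <- as_matrix_2x2(tab)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected < 1)) {
    warning("expected cell count below 1; consider Fisher's exact test",
            call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(m, correct = yates))
  list(statistic = unname(res$statistic), p_value = unname(res$p.value),
       df = unname(res$parameter))
}

#' Summarize longitudinal construct scores by arm and visit
#'
#' Produces the per-cell n / mean / SD layout of a repeated-measures score
#' table: one row per (arm, visit, construct).
#'
#' @param records long data.frame: `participant_id`, `arm`, `visit_month`,
#'   `construct`, `score` (scores in `[1, 7]`).
#' @return data.frame `arm`, `visit_month`, `construct`, `n`, `mean`, `sd`
#'   (`sd` is `NA` for single-record cells).
#' @export
summarize_longitudinal <- function(records) {
  need <- c("participant_id", "arm", "visit_month", "construct", "score")
  stopifnot(all(need %in% names(records)))
  ok <- !is.na(records$score)
  stopifnot(all(records$score[ok] >= 1 & records$score[ok] <= 7))
  records <- records[ok, , drop = FALSE]
  agg <- stats::aggregate(
    score ~ arm + visit_month + construct, data = records,
    FUN = function(x) c(n = length(x), mean = mean(x),
                        sd = if (length(x) > 1) stats::sd(x) else NA_real_))
  out <- data.frame(arm = agg$arm, visit_month = agg$visit_month,
                    construct = agg$construct,
                    n = agg$score[, "n"], mean = agg$score[, "mean"],
                    sd = agg$score[, "sd"], stringsAsFactors = FALSE)
  out[order(out$arm, out$visit_month, out$construct), , drop = FALSE]
}

#' Logistic regression by iteratively reweighted least squares
#'
#' Plain maximum-likelihood logistic fit under working independence, used as
#' the parameter-recovery oracle for simulated trial data. Convergence is
#' declared when the largest coefficient update falls below `tol`;
#' quasi-separation is reported as a non-convergence error naming the
#' runaway column.
#'
#' @param X numeric design matrix (include an intercept column yourself).
#' @param y 0/1 outcome vector, `length(y) == nrow(X)`.
#' @param max_iter iteration cap (default 50).
#' @param tol convergence tolerance on `max |delta beta|` (default 1e-8).
#' @return list of class `irls_fit`: `coefficients`, `se`, `vcov`,
#'   `iterations`, `converged`.
#' @export
fit_logistic_irls <- function(X, y, max_iter = 50L, tol = 1e-8) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank-deficient", call. = FALSE)
  p <- ncol(X)
  cn <- colnames(X) %||% paste0("x", seq_len(p))
  beta <- rep(0, p)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    if (any(w < 1e-12)) w <- pmax(w, 1e-12)    # guard flat weights
    z <- eta + (y - mu) / w
    fit <- stats::lm.wfit(X, z, w)
    delta <- max(abs(fit$coefficients - beta))
    beta <- fit$coefficients
    if (!all(is.finite(beta)) || max(abs(beta)) > 30) {
      worst <- cn[which.max(abs(beta))]
      stop("IRLS did not converge (possible separation on column '",
           worst, "')", call. = FALSE)
    }
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    worst <- cn[which.max(abs(beta))]
    stop("IRLS did not converge within ", max_iter,
         " iterations (largest coefficient on column '", worst, "')",
         call. = FALSE)
  }
  mu <- stats::plogis(drop(X %*% beta))
  w <- pmax(mu * (1 - mu), 1e-12)
  xtwx <- crossprod(X * sqrt(w))
  vcov <- solve(xtwx)
  names(beta) <- cn
  dimnames(vcov) <- list(cn, cn)
  structure(list(coefficients = beta, se = sqrt(diag(vcov)), vcov = vcov,
                 iterations = it, converged = TRUE),
            class = "irls_fit")
}

#' Export simulated trial data in long format for repeated-measures tools
#'
#' One row per (participant, visit, construct) with the participant's arm
#' and whether they were still continuously abstinent at that visit, suited
#' to GEE-style analyses in external software.
#'
#' @param run a `simulation_run` from [simulate_trial()].
#' @param path optional CSV destination; when given the data.frame is also
#'   written there.
#' @return the long data.frame, invisibly when `path` is given.
#' @export
export_long_format <- function(run, path = NULL) {
  stopifnot(inherits(run, "simulation_run"))
  long <- merge(run$scores,
                run$assignments[, c("participant_id", "arm")],
                by = "participant_id")
  abst <- run$abstinence_by_visit
  long <- merge(long, abst, by = c("participant_id", "visit_month"),
                all.x = TRUE)
  long <- long[order(long$participant_id, long$visit_month, long$construct),
               c("participant_id", "arm", "visit_month", "construct",
                 "score", "abstinent_so_far")]
  rownames(long) <- NULL
  if (!is.null(path)) {
    utils::write.csv(long, path, row.names = FALSE)
    return(invisible(long))
  }
  long
}
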