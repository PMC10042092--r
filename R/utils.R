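# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Truncated-normal draws on a closed interval
#'
#' Inverse-CDF sampler for a normal distribution truncated to
#' `[lower, upper]`. Used for Likert-scale construct scores, which live on
#' `[1, 7]`, and for expired-CO readings, which are non-negative.
#'
#' @param n number of draws.
#' @param mean,sd moments of the parent normal; `sd > 0`.
#' @param lower,upper truncation bounds.
#' @return numeric vector of length `n` inside `[lower, upper]`.
#' @keywords internal
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  stopifnot(sd > 0, lower < upper)
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, plo, phi)
  q <- stats::qnorm(u, mean, sd)
  # guard against qnorm(1) = Inf from floating point at extreme truncation
  pmin(pmax(q, lower), upper)
}

# Mean of a normal(mu, sd) truncated to [lower, upper].
truncnorm_mean <- function(mu, sd, lower, upper) {
  a <- (lower - mu) / sd
  b <- (upper - mu) / sd
  mu + sd * (stats::dnorm(a) - stats::dnorm(b)) / (stats::pnorm(b) - stats::pnorm(a))
}

# Parent mean whose truncated-to-[lower, upper] distribution has the target
# mean: truncation pulls scores away from the bounds, so near-ceiling
# constructs need a parent mean above the target. Monotone in mu -> uniroot.
truncnorm_match_mean <- function(target, sd, lower, upper) {
  stopifnot(target > lower, target < upper)
  stats::uniroot(function(mu) truncnorm_mean(mu, sd, lower, upper) - target,
                 interval = c(target - 6 * sd, target + 6 * sd),
                 tol = 1e-10)$root
}

# Clamp values to a closed interval (Likert scores stay in [1, 7]).
clip <- function(x, lower, upper) pmin(pmax(x, lower), upper)

# Consistent error for enum-like arguments.
match_enum <- function(value, choices, arg = deparse(substitute(value))) {
  if (length(value) != 1L || !value %in% choices) {
    stop(sprintf("`%s` must be one of: %s (got %s)", arg,
                 paste(choices, collapse = ", "),
                 paste(utils::head(value, 3), collapse = ", ")),
         call. = FALSE)
  }
  value
}

is_scalar_int <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x == trunc(x)
}
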