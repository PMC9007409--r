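# Risk/reward attitude from the sure-bet versus gamble assay.
#
# Two estimators: a linear point of equivalence (used in the first two
# experiments to set the base reward value, clamped to 5-20 cents), and a
# logistic psychometric fit of gamble choice against the reward difference
# (gamble EV minus sure bet), whose 0.5 crossing is the indifference point.
# Larger indifference points mean a more risk-averse, less reward-seeking
# attitude.

new_risk_profile <- function(indifference, slope, method, clamped = FALSE,
                             separation = FALSE, n = NA_integer_) {
  structure(
    list(
      indifference_point_cents = indifference, slope = slope,
      method = method, clamped = clamped, separation = separation, n = n
    ),
    class = "risk_profile"
  )
}

#' @export
print.risk_profile <- function(x, ...) {
  cat(sprintf(
    "<risk_profile> %s: indifference point = %.2f cents%s%s (n = %d)\n",
    x$method, x$indifference_point_cents,
    if (x$clamped) " [clamped]" else "",
    if (x$separation) " [separation]" else "", x$n
  ))
  invisible(x)
}

#' @export
tidy.risk_profile <- function(x, ...) {
  tibble::tibble(
    indifference_point_cents = x$indifference_point_cents,
    slope = x$slope, method = x$method,
    clamped = x$clamped, separation = x$separation, n = x$n
  )
}

#' Linear point of equivalence
#'
#' Trialwise OLS of the sure-bet choice indicator on the sure-bet value (the
#' gamble's expected outcome held at 10 cents): the fitted value at which the
#' sure bet is chosen with probability 0.5 is the point of equivalence,
#' clamped into `[5, 20]` cents with a flag, as used to set each participant's
#' base reward.
#'
#' @param choices tibble with `sure_bet_cents` and `choice`
#'   (1 = gamble, 0 = sure bet).
#' @param clamp_range allowed range of the returned value in cents.
#' @return a `risk_profile` with `method = "linear"`.
#' @export
fit_linear_equivalence <- function(choices, clamp_range = c(5, 20)) {
  check_columns(choices, c("sure_bet_cents", "choice"), "choice table")
  if (dplyr::n_distinct(choices$sure_bet_cents) < 2) {
    abort("choices must span at least 2 distinct sure-bet values.",
      class = "reachbias_insufficient_data"
    )
  }
  p_sure <- 1 - choices$choice
  fit <- lm(p_sure ~ choices$sure_bet_cents)
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || abs(slope) < 1e-12) {
    abort("flat choice pattern: point of equivalence undefined.",
      class = "reachbias_degenerate_fit"
    )
  }
  raw <- (0.5 - unname(coef(fit)[1])) / slope
  clamped <- raw < clamp_range[1] || raw > clamp_range[2]
  new_risk_profile(
    min(max(raw, clamp_range[1]), clamp_range[2]), slope,
    "linear", clamped = clamped, n = nrow(choices)
  )
}

#' Sigmoid indifference point
#'
#' Logistic fit of gamble choice against the reward difference (gamble EV
#' minus sure bet); the indifference point is the difference at which the
#' curve crosses 0.5. Under complete separation (all-gamble or all-sure-bet
#' regions with no overlap) the fit is regularized by two half-weight
#' pseudo-observations at the extreme differences and flagged.
#'
#' @param choices tibble with `reward_diff` (cents) and `choice`
#'   (1 = gamble, 0 = sure bet).
#' @param ... unused.
#' @return a `risk_profile` with `method = "sigmoid"` and the logistic slope
#'   (per cent).
#' @export
fit_indifference <- function(choices, ...) {
  check_columns(choices, c("reward_diff", "choice"), "choice table")
  y <- choices$choice
  x <- choices$reward_diff
  separation <- length(unique(y)) < 2 || {
    fit0 <- suppressWarnings(glm(y ~ x, family = binomial()))
    !fit0$converged || max(abs(coef(fit0))) > 25 ||
      all(fit0$fitted.values > 1 - 1e-6) || all(fit0$fitted.values < 1e-6)
  }
  if (separation) {
    # half-weight success/failure pseudo-observations at the design extremes
    xa <- c(x, min(x), max(x))
    ya <- c(y, 0.5, 0.5)
    w <- c(rep(1, length(y)), 1, 1)
    fit <- suppressWarnings(glm(ya ~ xa, family = binomial(), weights = w))
  } else {
    fit <- suppressWarnings(glm(y ~ x, family = binomial()))
  }
  b <- coef(fit)
  new_risk_profile(
    indifference = unname(-b[1] / b[2]), slope = unname(b[2]),
    method = "sigmoid", separation = separation, n = length(y)
  )
}

#' Flag risk-attitude outliers in a cohort
#'
#' Mirrors the outlier policy of the individual-differences analysis: a
#' participant whose indifference point lies more than `z` cohort SDs from
#' the cohort mean is flagged (and excluded from correlations, with both
#' versions reported).
#'
#' @param profiles tibble with `participant_id` and
#'   `indifference_point_cents`.
#' @param z flagging threshold in SD units.
#' @return `profiles` with a logical `risk_outlier` column.
#' @export
flag_risk_outliers <- function(profiles, z = 3) {
  ip <- profiles$indifference_point_cents
  s <- sd(ip)
  dplyr::mutate(
    profiles,
    risk_outlier = if (is.na(s) || s == 0) FALSE else abs(ip - mean(ip)) > z * s
  )
}
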