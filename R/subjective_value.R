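# Subjective-value power law.
#
# The neuroeconomic reading of the bias: each target's subjective value is
# SV = P * R^alpha (likelihood times discounted reward), and the observed
# bias is proportional to the ratio of the two subjective values,
# bias ~ (P1/P2) * (R1/R2)^alpha. With target 1 the more-rewarded (and hence
# less-likely) target, dividing the bias by the likelihood ratio isolates the
# power law in the reward ratio; alpha is fit by OLS in log-log space
# (exact for noiseless power laws). Larger alpha means less discounting of
# reward relative to likelihood.

#' Rescale intermediate-reach angles to the unit bias range
#'
#' Divides the initial direction by the angular separation of the two targets
#' and recenters on 0.5, mapping the midline to 0.5 and the two target
#' directions to 0 and 1, so intermediate biases live on the same scale as
#' direct-reach choice proportions.
#'
#' @param angle_deg aligned initial direction(s), degrees.
#' @param separation_deg angular distance between the targets (45 deg).
#' @return unit-scale bias.
#' @export
rescale_intermediate <- function(angle_deg, separation_deg = 45) {
  if (separation_deg <= 0) abort("separation must be positive.", class = "reachbias_config_error")
  angle_deg / separation_deg + 0.5
}

#' Fit the subjective-value exponent
#'
#' For each bootstrap iteration (or participant), takes the mixed conditions
#' (both ratios different from 1:1), forms `bias / (P1/P2)` — the bias times
#' the likelihood ratio, since the rewarded target's likelihood ratio is the
#' reciprocal of the frequent side's — and fits
#' `log(bias * f) = log(c) + alpha * log(r)` by OLS. Direct-reach biases
#' enter as raw choice proportions; intermediate biases are first passed
#' through [rescale_intermediate()]. Conditions with a nonpositive bias are
#' dropped (log undefined); an iteration with fewer than 2 distinct reward
#' ratios left yields `NA` with `ok = FALSE`.
#'
#' @param bias_table tibble with `iteration` (or `participant_id`),
#'   `reward_ratio`, `likelihood_ratio` and the measure column.
#' @param measure `"d_choice"` or `"i_bias"`.
#' @param separation_deg target separation used to rescale `i_bias`.
#' @param by grouping column; guessed if absent.
#' @return tibble with the grouping column, `alpha`, `log_c`, `n_points`,
#'   `ok`, `measure`.
#' @export
fit_alpha <- function(bias_table, measure = c("d_choice", "i_bias"),
                      separation_deg = 45, by = NULL) {
  measure <- match.arg(measure)
  if (inherits(bias_table, "bias_bootstrap")) bias_table <- bias_table$draws
  by <- by %||% intersect(c("iteration", "participant_id"), names(bias_table))[1]
  if (is.na(by)) abort("no `iteration` or `participant_id` column found.")
  check_columns(bias_table, c("reward_ratio", "likelihood_ratio", measure), "bias table")

  bias_table |>
    dplyr::group_by(.data[[by]]) |>
    dplyr::group_modify(function(df, key) {
      mixed <- dplyr::filter(df, .data$reward_ratio != 1, .data$likelihood_ratio != 1)
      bias <- if (measure == "i_bias") {
        rescale_intermediate(mixed[[measure]], separation_deg)
      } else {
        mixed[[measure]]
      }
      y <- bias * mixed$likelihood_ratio # bias / (P1/P2), P1/P2 = 1/f
      keep <- !is.na(y) & y > 0
      if (sum(keep) < 2 || dplyr::n_distinct(mixed$reward_ratio[keep]) < 2) {
        return(tibble::tibble(
          alpha = NA_real_, log_c = NA_real_,
          n_points = sum(keep), ok = FALSE
        ))
      }
      fit <- lm(log(y[keep]) ~ log(mixed$reward_ratio[keep]))
      tibble::tibble(
        alpha = unname(coef(fit)[2]), log_c = unname(coef(fit)[1]),
        n_points = sum(keep), ok = TRUE
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(measure = measure)
}
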