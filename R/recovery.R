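# Parameter-recovery simulation validating the weight-estimation method.
#
# Generative model: on each simulated trial the preference for the more
# frequent target is scaled toward indifference by the frequency weight, the
# preference for the more rewarded target by the reward weight (1 minus the
# frequency weight); the product of the two preferences is each target's
# expected value, and normalizing the two expected values gives the choice
# probability. Direct reaches are Bernoulli draws against it; intermediate
# reach directions are the probability mapped linearly onto [-15, +15] deg.
# The same weight-estimation path used on real data is then applied.

#' Weight-scaled preference for target 1
#'
#' `(f1 / (f1 + f2) - 0.5) * weight + 0.5`: the raw preference implied by a
#' ratio, shrunk toward indifference (0.5) by the weight. At full weight a
#' 2:1 ratio gives the unscaled preference 2/3 (0.67); at zero weight any
#' ratio gives 0.5. The counterpart preference for target 2 is one minus
#' this.
#'
#' @param ratio ratio of target 1 to target 2 (frequency or reward); may be
#'   a vector.
#' @param weight scaling weight in `[0, 1]`.
#' @return preference for target 1.
#' @export
scaled_preference <- function(ratio, weight) {
  stopifnot(all(ratio > 0), all(weight >= 0 & weight <= 1))
  (ratio / (ratio + 1) - 0.5) * weight + 0.5
}

#' Choice probability from scaled preferences
#'
#' Each target's expected value is the product of its frequency-scaled and
#' reward-scaled preferences; the probability of choosing target 1 is its
#' expected value normalized by the sum over both targets.
#'
#' @param freq_ratio,reward_ratio target-1-over-target-2 ratios.
#' @param w_f frequency weight; the reward weight defaults to `1 - w_f`.
#' @param w_r reward weight override.
#' @return `P(choose target 1)`.
#' @export
choice_probability <- function(freq_ratio, reward_ratio, w_f, w_r = 1 - w_f) {
  pf <- scaled_preference(freq_ratio, w_f)
  pr <- scaled_preference(reward_ratio, w_r)
  ev1 <- pf * pr
  ev2 <- (1 - pf) * (1 - pr)
  if (any(ev1 + ev2 == 0)) {
    abort("both expected values are zero.", class = "reachbias_config_error")
  }
  ev1 / (ev1 + ev2)
}

#' Map a choice probability onto a reach direction
#'
#' `30 * p - 15`: probability 0.5 maps to the midline, the extremes to
#' +/- 15 deg.
#'
#' @param p probability in `[0, 1]`.
#' @return direction in degrees.
#' @export
prob_to_direction <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  30 * p - 15
}

#' Run the parameter-recovery simulation
#'
#' For every weight on the grid and every iteration: simulate, for each cell
#' of the frequency-by-reward ratio design, `n_trials` direct choices
#' (Bernoulli draws against the choice probability, with the rewarded target
#' taken as the less frequent one) and `n_trials` intermediate directions
#' (the deterministic probability-to-direction mapping plus optional angular
#' noise), then recover the frequency weight with the same axis-regression /
#' weighted-sum estimator used on real data (count-proportion biases, as in
#' the explicit-choice experiment). Estimation failures are flagged, not
#' dropped.
#'
#' @param weight_grid simulated frequency weights (nine weightings 0.1-0.9).
#' @param n_iter iterations per weight.
#' @param n_trials simulated trials per condition.
#' @param ratios the frequency and reward ratio levels of the design.
#' @param seed integer seed.
#' @param noise_sd_deg angular noise added to intermediate directions
#'   (0 = the deterministic mapping).
#' @return a `recovery_result`: tibble with `simulated_w_f`, `iteration`,
#'   `recovered_w_f_direct`, `recovered_w_f_intermediate`, `ok`,
#'   `n_trials_per_condition`.
#' @export
run_recovery <- function(weight_grid = seq(0.1, 0.9, by = 0.1), n_iter = 100,
                         n_trials = 200, ratios = c(1, 2, 4), seed = 1,
                         noise_sd_deg = 0) {
  design <- tidyr::expand_grid(likelihood_ratio = ratios, reward_ratio = ratios)
  if (!any(design$likelihood_ratio != 1 & design$reward_ratio != 1)) {
    abort("design must include mixed conditions.", class = "reachbias_config_error")
  }
  # P(choose rewarded target): the rewarded target is the less frequent one,
  # so its frequency ratio is the reciprocal of the likelihood ratio.
  with_seed(seed, {
    out <- vector("list", length(weight_grid) * n_iter)
    k <- 0
    for (w in weight_grid) {
      p <- choice_probability(1 / design$likelihood_ratio, design$reward_ratio, w)
      for (it in seq_len(n_iter)) {
        k <- k + 1
        d_choice <- rbinom(nrow(design), n_trials, p) / n_trials
        dirs <- prob_to_direction(p)
        i_bias <- if (noise_sd_deg > 0) {
          dirs + rnorm(nrow(design), 0, noise_sd_deg / sqrt(n_trials))
        } else {
          dirs
        }
        tab <- dplyr::mutate(design, d_choice = d_choice, i_bias = i_bias)
        rec <- function(measure) {
          tryCatch(
            {
              eff <- fit_axis_effects(tab, measure)
              estimate_weight(eff, tab)$w_f
            },
            error = function(e) NA_real_
          )
        }
        wd <- rec("d_choice")
        wi <- rec("i_bias")
        out[[k]] <- tibble::tibble(
          simulated_w_f = w, iteration = it,
          recovered_w_f_direct = wd, recovered_w_f_intermediate = wi,
          ok = !is.na(wd) && !is.na(wi)
        )
      }
    }
    structure(
      list(
        results = dplyr::bind_rows(out) |>
          dplyr::mutate(n_trials_per_condition = n_trials),
        weight_grid = weight_grid, n_iter = n_iter, n_trials = n_trials,
        ratios = ratios, seed = seed
      ),
      class = "recovery_result"
    )
  })
}

#' @export
print.recovery_result <- function(x, ...) {
  cat(sprintf(
    "<recovery_result> %d weights x %d iterations, %d trials/condition\n",
    length(x$weight_grid), x$n_iter, x$n_trials
  ))
  print(summary(x))
  invisible(x)
}

#' Per-grid-point recovery summary
#'
#' @param object a `recovery_result`.
#' @param ... unused.
#' @return tibble with median and IQR of the recovered weights per simulated
#'   weight and strategy.
#' @export
summary.recovery_result <- function(object, ...) {
  object$results |>
    tidyr::pivot_longer(
      c("recovered_w_f_direct", "recovered_w_f_intermediate"),
      names_to = "strategy", values_to = "recovered",
      names_pattern = "recovered_w_f_(.*)"
    ) |>
    dplyr::group_by(.data$simulated_w_f, .data$strategy) |>
    dplyr::summarise(
      median = median(.data$recovered, na.rm = TRUE),
      q25 = quantile(.data$recovered, 0.25, na.rm = TRUE),
      q75 = quantile(.data$recovered, 0.75, na.rm = TRUE),
      n_ok = sum(.data$ok),
      .groups = "drop"
    )
}

#' @export
tidy.recovery_result <- function(x, ...) x$results

#' @export
glance.recovery_result <- function(x, ...) {
  s <- summary(x)
  tibble::tibble(
    max_median_abs_error = max(abs(s$median - s$simulated_w_f)),
    direct_intermediate_cor = cor(
      x$results$recovered_w_f_direct, x$results$recovered_w_f_intermediate,
      use = "complete.obs"
    ),
    n_failed = sum(!x$results$ok)
  )
}
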