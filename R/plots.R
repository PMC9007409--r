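# ggplot2 convenience plots for the main result types.

#' Reach-direction histograms by condition
#'
#' Aligned initial reach directions binned at 5 deg, colored by strategy and
#' faceted by the reward (columns) and likelihood (rows) ratios — the
#' standard presentation of pooled reach distributions for this task.
#'
#' @param classified output of [classify_trials()].
#' @param binwidth histogram bin width in degrees.
#' @return a ggplot object.
#' @export
plot_reach_histogram <- function(classified, binwidth = 5) {
  dplyr::filter(classified, .data$keep) |>
    ggplot2::ggplot(ggplot2::aes(
      x = .data$aligned_initial_direction_deg,
      fill = .data$strategy
    )) +
    ggplot2::geom_histogram(binwidth = binwidth, position = "identity", alpha = 0.6) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$likelihood_ratio),
      cols = ggplot2::vars(.data$reward_ratio),
      labeller = ggplot2::label_both
    ) +
    ggplot2::labs(
      x = "aligned initial reach direction (deg, + toward higher reward)",
      y = "reaches", fill = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Weight-distribution plot
#'
#' Histograms of the per-iteration (or per-participant) frequency weights for
#' direct and intermediate reaches, with the equal-weighting reference at
#' 0.5.
#'
#' @param weights_direct,weights_intermediate [estimate_weights()] outputs.
#' @return a ggplot object.
#' @export
plot_weight_distributions <- function(weights_direct, weights_intermediate) {
  dplyr::bind_rows(
    dplyr::mutate(weights_direct, strategy = "direct"),
    dplyr::mutate(weights_intermediate, strategy = "intermediate")
  ) |>
    dplyr::filter(.data$ok) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$w_f, fill = .data$strategy)) +
    ggplot2::geom_histogram(binwidth = 0.02, position = "identity", alpha = 0.6) +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = "frequency weight w_f", y = "iterations", fill = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn run_recovery Recovered-versus-simulated weight plot: per-grid
#'   medians with IQR ribbons against the identity line, per strategy.
#' @param object a `recovery_result`.
#' @param ... unused.
#' @export
autoplot.recovery_result <- function(object, ...) {
  s <- summary(object)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$simulated_w_f, y = .data$median)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", color = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$q25, ymax = .data$q75)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$strategy)) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "simulated weight", y = "recovered weight (median, IQR)") +
    ggplot2::theme_minimal()
}

#' Psychometric-curve plot for a utility assay
#'
#' Choices (vertically jittered) against the reward difference, with the
#' fitted logistic and the indifference point marked.
#'
#' @param choices tibble with `reward_diff` and `choice`.
#' @param profile a `risk_profile` from [fit_indifference()].
#' @return a ggplot object.
#' @export
plot_psychometric <- function(choices, profile) {
  grid <- tibble::tibble(
    reward_diff = seq(min(choices$reward_diff), max(choices$reward_diff), length.out = 200)
  )
  grid$p <- plogis(profile$slope * (grid$reward_diff - profile$indifference_point_cents))
  ggplot2::ggplot(choices, ggplot2::aes(x = .data$reward_diff, y = .data$choice)) +
    ggplot2::geom_jitter(width = 0, height = 0.04, alpha = 0.4) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$p), color = "steelblue") +
    ggplot2::geom_vline(
      xintercept = profile$indifference_point_cents,
      linetype = "dashed"
    ) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::labs(
      x = "gamble EV - sure bet (cents)",
      y = "P(choose gamble)"
    ) +
    ggplot2::theme_minimal()
}
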