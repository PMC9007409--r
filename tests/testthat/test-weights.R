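make_bias_table <- function(w_f, lik_line = function(f) 0.5 - 0.04 * (f - 1),
                            rew_line = function(r) 0.5 + 0.01 * (r - 1),
                            ratios = c(1, 2, 5, 10)) {
  tidyr::expand_grid(likelihood_ratio = ratios, reward_ratio = ratios) |>
    dplyr::mutate(d_choice = dplyr::case_when(
      likelihood_ratio > 1 & reward_ratio > 1 ~
        w_f * lik_line(likelihood_ratio) + (1 - w_f) * rew_line(reward_ratio),
      likelihood_ratio > 1 ~ lik_line(likelihood_ratio),
      TRUE ~ rew_line(reward_ratio)
    ))
}

test_that("axis regressions recover exact lines and reject single-ratio axes", {
  tab <- make_bias_table(0.5)
  eff <- fit_axis_effects(tab, "d_choice")
  expect_equal(unname(eff$reward), c(0.5 - 0.01, 0.01), tolerance = 1e-10)
  expect_equal(unname(eff$likelihood), c(0.5 + 0.04, -0.04), tolerance = 1e-10)
  # constant biases give zero slope
  flat <- dplyr::mutate(tab, d_choice = 0.5)
  eff_flat <- fit_axis_effects(flat, "d_choice")
  expect_equal(unname(eff_flat$reward["slope"]), 0, tolerance = 1e-12)
  # a single-ratio axis errors
  one <- dplyr::filter(tab, likelihood_ratio == 1, reward_ratio == 1)
  expect_error(fit_axis_effects(one, "d_choice"), class = "reachbias_insufficient_data")
  # log-ratio predictor recovers a line that is exact in log space
  tab_log <- tab |>
    dplyr::mutate(d_choice = dplyr::case_when(
      likelihood_ratio > 1 ~ 0.5 - 0.1 * log(likelihood_ratio),
      TRUE ~ 0.5 + 0.05 * log(reward_ratio)
    ))
  eff_log <- fit_axis_effects(tab_log, "d_choice", predictor = "log_ratio")
  expect_equal(unname(eff_log$likelihood), c(0.5, -0.1), tolerance = 1e-10)
  expect_equal(
    predict_bias(eff_log, 1, tibble::tibble(likelihood_ratio = 5, reward_ratio = 2)),
    0.5 - 0.1 * log(5),
    tolerance = 1e-10
  )
})

test_that("predict_bias reproduces hand arithmetic and the boundary identities", {
  eff <- structure(
    list(
      measure = "d_choice",
      reward = c(intercept = 0.5 - 0.01, slope = 0.01),
      likelihood = c(intercept = 0.5 + 0.04, slope = -0.04)
    ),
    class = "axis_effects"
  )
  cond <- tibble::tibble(likelihood_ratio = 5, reward_ratio = 5)
  # L(5) = 0.5 - 0.04*(5-1) = 0.34; R(5) = 0.5 + 0.01*4 = 0.54
  expect_equal(predict_bias(eff, 1, cond), 0.34)
  expect_equal(predict_bias(eff, 0.5, cond), (0.34 + 0.54) / 2)
  expect_equal(
    predict_bias(eff, 0.66, cond),
    0.5 + 0.66 * (-0.16) + 0.34 * 0.04
  ) # = 0.4080
  expect_equal(predict_bias(eff, 0.66, cond), 0.4080, tolerance = 1e-12)
})

test_that("the weight grid search is exact on noiseless weighted-sum data", {
  for (w_true in c(0, 0.25, 0.43, 0.66, 0.7, 1)) {
    tab <- make_bias_table(w_true)
    eff <- fit_axis_effects(tab, "d_choice")
    est <- estimate_weight(eff, tab)
    expect_equal(est$w_f, w_true, tolerance = 5e-4)
    expect_equal(est$w_f + est$w_r, 1)
  }
  # data exactly on the reward line at mixed conditions -> w_f = 0
  tab0 <- make_bias_table(0)
  est0 <- estimate_weight(fit_axis_effects(tab0, "d_choice"), tab0)
  expect_equal(est0$w_f, 0)
  expect_error(
    estimate_weight(
      fit_axis_effects(make_bias_table(0.5), "d_choice"),
      dplyr::filter(make_bias_table(0.5), reward_ratio == 1)
    ),
    class = "reachbias_insufficient_data"
  )
})

test_that("grid search agrees with the closed-form least-squares oracle", {
  set.seed(21)
  for (rep in 1:20) {
    tab <- make_bias_table(runif(1)) |>
      dplyr::mutate(d_choice = d_choice + rnorm(dplyr::n(), 0, 0.02))
    eff <- fit_axis_effects(tab, "d_choice")
    mixed <- dplyr::filter(tab, reward_ratio != 1, likelihood_ratio != 1)
    est <- estimate_weight(eff, mixed)
    oracle <- oracle_closed_form_weight(eff, mixed, "d_choice")
    expect_lt(abs(est$w_f - oracle), 5.1e-4) # grid resolution 1e-3
  }
})

test_that("the estimated weight responds monotonically to the data", {
  tab <- make_bias_table(0.5)
  eff <- fit_axis_effects(tab, "d_choice")
  mixed <- dplyr::filter(tab, reward_ratio != 1, likelihood_ratio != 1)
  lik_vals <- predict_bias(eff, 1, mixed)
  w_seq <- vapply(seq(0, 1, 0.25), function(a) {
    shifted <- dplyr::mutate(mixed, d_choice = (1 - a) * d_choice + a * lik_vals)
    estimate_weight(eff, shifted)$w_f
  }, numeric(1))
  expect_true(all(diff(w_seq) >= 0))
  expect_equal(w_seq[length(w_seq)], 1, tolerance = 5e-4)
})

test_that("weight comparisons compute the textbook statistics", {
  x <- c(0.61, 0.63, 0.66, 0.70, 0.72)
  y <- c(0.41, 0.44, 0.43, 0.47, 0.40)
  cmp <- compare_weights(x, y)
  # closed-form one-sample t against 0.5
  t_hand <- (mean(x) - 0.5) / (sd(x) / sqrt(length(x)))
  expect_equal(cmp$t_direct_vs_mu$statistic, t_hand, tolerance = 1e-10)
  d <- x - y
  t_pair <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(cmp$t_paired$statistic, t_pair, tolerance = 1e-10)
  expect_equal(cmp$t_paired$df, 4)
  # identical distributions: paired t = 0, KS distance 0
  same <- compare_weights(x, x)
  expect_equal(same$t_paired$statistic, 0)
  expect_equal(same$ks$statistic, 0)
  # degenerate zero-variance input is flagged rather than infinite
  flat <- compare_weights(rep(0.6, 100), rep(0.6, 100))
  expect_true(flat$t_direct_vs_mu$degenerate)
  expect_true(is.na(flat$t_direct_vs_mu$statistic))
  expect_error(compare_weights(x, y[1:3]), class = "reachbias_insufficient_data")
  expect_error(compare_weights(numeric(0), y), class = "reachbias_insufficient_data")
})

test_that("per-iteration estimation returns one weight per bootstrap draw", {
  tab <- dplyr::bind_rows(
    dplyr::mutate(make_bias_table(0.3), iteration = 1L),
    dplyr::mutate(make_bias_table(0.8), iteration = 2L)
  )
  out <- estimate_weights(tab, "d_choice")
  expect_equal(nrow(out), 2)
  expect_true(all(out$ok))
  expect_equal(out$w_f, c(0.3, 0.8), tolerance = 5e-4)
})
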