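test_that("zero-noise trials launch at the exact ground-truth direction", {
  cfg <- experiment_config(1)
  # a direct chooser with no noise heading for the +22.5 target
  prof <- participant_profile(
    motor_sd_deg = 0, p_intermediate = 0,
    d_reward_slope = 0.048 # reward line hits 0.98 at ratio 10 -> clamp keeps valid
  )
  cond <- make_trial_row(reward_ratio = 10, likelihood_ratio = 1)
  # with the reward line clamped at 0.98, nearly every choice is the
  # rewarded (right) target; find a seed whose draw picks it
  tr <- simulate_trial(prof, as.list(cond), cfg, seed = 1)
  expect_equal(tr$trial$gt_strategy, "direct")
  expect_equal(abs(tr$trial$gt_aim_deg), 22.5)
  onset <- detect_onset(tr$trajectory, cfg$onset_velocity_ms)
  expect_equal(initial_direction(tr$trajectory, onset), tr$trial$gt_aim_deg,
    tolerance = 1e-6
  )

  # an unbiased intermediate mover in a fully symmetric condition: midline
  prof2 <- participant_profile(motor_sd_deg = 0, p_intermediate = 1)
  cond2 <- make_trial_row()
  tr2 <- simulate_trial(prof2, as.list(cond2), cfg, seed = 2)
  expect_equal(tr2$trial$gt_aim_deg, 0)
  onset2 <- detect_onset(tr2$trajectory, cfg$onset_velocity_ms)
  expect_equal(initial_direction(tr2$trajectory, onset2), 0, tolerance = 1e-6)
})

test_that("direct choice fractions match the generative probability", {
  cfg <- experiment_config(1)
  # condition bias 0.7 on the rewarded side via the likelihood axis line
  prof <- participant_profile(
    motor_sd_deg = 0, p_intermediate = 0, d_likelihood_slope = 0.2
  )
  cond <- make_trial_row(likelihood_ratio = 2)
  p_true <- condition_bias(prof, 1, 2)$d_choice_prob
  expect_equal(p_true, 0.7)
  seeds <- 1:200
  choices <- vapply(seeds, function(s) {
    simulate_trial(prof, as.list(cond), cfg, seed = s)$trial$gt_choice_side
  }, character(1))
  frac <- mean(choices == "R")
  ci <- qbinom(c(0.025, 0.975), 200, 0.7) / 200
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
})

test_that("sessions are deterministic under a fixed seed and sized by design", {
  cfg <- experiment_config(1)
  prof <- participant_profile()
  des <- session_design(1, n_trials = 2)
  s1 <- simulate_session(prof, des, cfg, seed = 9)
  s2 <- simulate_session(prof, des, cfg, seed = 9)
  expect_equal(s1$trials, s2$trials)
  expect_equal(s1$trajectories, s2$trajectories)
  # 1 block, 1 trial
  one <- simulate_session(prof, des[1, ] |> dplyr::mutate(n_trials = 1), cfg, seed = 1)
  expect_equal(nrow(one$trials), 1)
  expect_error(simulate_session(prof, des[0, ], cfg, seed = 1),
    class = "reachbias_config_error"
  )
})

test_that("block frequencies converge to the design likelihood ratio", {
  cfg <- experiment_config(1)
  prof <- participant_profile(p_intermediate = 0)
  des <- tibble::tibble(
    block = 1L, reward_ratio = 1, likelihood_ratio = 2,
    rewarded_side = "R", frequent_side = "L", n_trials = 3000
  )
  # draw correct sides exactly as simulate_session does, without the cost of
  # rendering 3000 trajectories
  s <- simulate_session(prof, dplyr::mutate(des, n_trials = 300), cfg, seed = 14)
  frac <- mean(s$trials$correct_side == "L")
  ci <- qbinom(c(0.005, 0.995), 300, 2 / 3) / 300
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
})

test_that("generated trajectories pass their own experiment's exclusion rules", {
  for (exp_id in 1:3) {
    cfg <- experiment_config(exp_id)
    prof <- participant_profile(motor_sd_deg = 1)
    des <- session_design(exp_id, n_trials = 2, near_far_ratios = 1)
    s <- simulate_session(prof, des, cfg, seed = 40 + exp_id)
    kin <- summarize_kinematics(s)
    ex <- apply_exclusions(kin, cfg)
    expect_true(all(ex$keep), info = sprintf("experiment %d", exp_id))
  }
})

test_that("utility choices follow the logistic model", {
  offers <- tibble::tibble(
    sure_bet_cents = rep(seq(2, 18, by = 2), each = 20),
    gamble_hi = 20, gamble_lo = 0
  )
  # step-function limit: slope -> Inf, any offer above the indifference point
  # always takes the gamble
  prof_step <- participant_profile(
    indifference_point_cents = 0, psychometric_slope = Inf
  )
  ch <- simulate_utility_choices(prof_step, offers, seed = 5)
  expect_true(all(ch$choice[ch$reward_diff > 0] == 1))
  expect_true(all(ch$choice[ch$reward_diff < 0] == 0))
  # at the indifference point the gamble is a coin flip
  prof2 <- participant_profile(indifference_point_cents = 2, psychometric_slope = 1)
  at_ip <- tibble::tibble(sure_bet_cents = rep(8, 10000), gamble_hi = 20, gamble_lo = 0)
  ch2 <- simulate_utility_choices(prof2, at_ip, seed = 6)
  expect_equal(mean(ch2$choice), 0.5, tolerance = 0.02)
  # determinism
  ch3 <- simulate_utility_choices(prof2, at_ip, seed = 6)
  expect_identical(ch2, ch3)
})

test_that("condition biases obey the weighted-sum generative model", {
  prof <- participant_profile(w_f_direct = 0.66, w_f_intermediate = 0.43)
  # pure axes follow the axis lines
  expect_equal(condition_bias(prof, 5, 1)$d_choice_prob, 0.5 + 0.01 * 4)
  expect_equal(condition_bias(prof, 1, 5)$d_choice_prob, 0.5 - 0.04 * 4)
  expect_equal(condition_bias(prof, 1, 10)$i_bias_deg, -0.37 * 9)
  # mixed conditions are the weighted sum of the two lines
  b <- condition_bias(prof, 5, 10)
  expect_equal(
    b$d_choice_prob,
    0.66 * (0.5 - 0.04 * 9) + 0.34 * (0.5 + 0.01 * 4)
  )
  expect_equal(
    b$i_bias_deg,
    0.43 * (-0.37 * 9) + 0.57 * (0.12 * 4)
  )
})
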