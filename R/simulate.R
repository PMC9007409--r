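# Synthetic go-before-you-know sessions with known ground truth.
#
# The generator realizes the estimand of the analysis directly: per-condition
# biases follow the weighted-sum-of-axis-effects model that the estimation
# stage fits (pure-axis conditions follow the axis effect lines; conditions
# where both ratios differ from 1 follow w_f * likelihood_line + (1 - w_f) *
# reward_line). Per-trial choices are Bernoulli draws against the condition's
# direct-choice probability, and a kinematic layer renders each trial as a
# planar hand path with a minimum-jerk speed profile.

#' Ground-truth participant profile for the synthetic generator
#'
#' @param w_f_direct,w_f_intermediate frequency (success-likelihood) weight in
#'   `[0, 1]` for each reach strategy; the reward weight is `1 - w_f`.
#' @param p_intermediate probability of adopting the intermediate strategy on
#'   a trial, drawn independently per trial.
#' @param motor_sd_deg SD (degrees) of angular motor noise on the launch
#'   direction. The default 2 deg corresponds to ~0.7 cm endpoint scatter at
#'   20 cm, typical of rapid planar reaches.
#' @param reaction_ms latency from target reveal to the start of the
#'   corrective turn on intermediate reaches.
#' @param indifference_point_cents,psychometric_slope risk-attitude parameters
#'   for the utility assay: the gamble-vs-sure-bet reward difference (cents) at
#'   which the gamble is chosen with probability 0.5, and the logistic slope
#'   (per cent).
#' @param near_far_slope change in `p_intermediate` per unit near-to-far
#'   reward ratio (experiment 3); negative values make direct reaches more
#'   attractive as the near targets become relatively more valuable.
#' @param d_likelihood_slope,d_reward_slope axis-effect slopes for the direct
#'   choice bias (probability units per unit ratio). Defaults are the
#'   group-level values observed in the blockwise-frequency experiment
#'   (-0.04 and +0.01).
#' @param i_likelihood_slope,i_reward_slope axis-effect slopes for the
#'   intermediate initial-direction bias (degrees per unit ratio; defaults
#'   -0.37 and +0.12).
#' @param move_duration_ms nominal movement duration; `NULL` picks a value
#'   compatible with the experiment's movement-time limit.
#'
#' @return a `participant_profile` (named list).
#' @export
participant_profile <- function(w_f_direct = 0.66,
                                w_f_intermediate = 0.43,
                                p_intermediate = 0.5,
                                motor_sd_deg = 2,
                                reaction_ms = 200,
                                indifference_point_cents = 0,
                                psychometric_slope = 0.5,
                                near_far_slope = 0,
                                d_likelihood_slope = -0.04,
                                d_reward_slope = 0.01,
                                i_likelihood_slope = -0.37,
                                i_reward_slope = 0.12,
                                move_duration_ms = NULL) {
  p <- list(
    w_f_direct = w_f_direct, w_f_intermediate = w_f_intermediate,
    p_intermediate = p_intermediate, motor_sd_deg = motor_sd_deg,
    reaction_ms = reaction_ms,
    indifference_point_cents = indifference_point_cents,
    psychometric_slope = psychometric_slope,
    near_far_slope = near_far_slope,
    d_likelihood_slope = d_likelihood_slope, d_reward_slope = d_reward_slope,
    i_likelihood_slope = i_likelihood_slope, i_reward_slope = i_reward_slope,
    move_duration_ms = move_duration_ms
  )
  stopifnot(
    w_f_direct >= 0, w_f_direct <= 1,
    w_f_intermediate >= 0, w_f_intermediate <= 1,
    p_intermediate >= 0, p_intermediate <= 1,
    motor_sd_deg >= 0, reaction_ms > 0
  )
  structure(p, class = "participant_profile")
}

#' Block design for a synthetic session
#'
#' Crosses the experiment's stated reward and likelihood ratio sets, with the
#' rewarded side counterbalanced across blocks and the frequent side always
#' opposite the rewarded side (as in the task: the more rewarding target is
#' the less frequent one).
#'
#' @param experiment 1, 2 or 3.
#' @param n_trials trials per condition row.
#' @param near_far_ratios near-to-far reward ratios crossed into the design
#'   for experiment 3.
#' @return a tibble with columns `block`, `reward_ratio`, `likelihood_ratio`,
#'   `rewarded_side`, `frequent_side`, `n_trials` and (experiment 3)
#'   `near_far_ratio`.
#' @export
session_design <- function(experiment = 1L, n_trials = 32,
                           near_far_ratios = c(1, 2.5, 4)) {
  experiment <- as.integer(experiment)
  grid <- switch(experiment,
    tidyr::expand_grid(reward_ratio = c(1, 2, 5, 10), likelihood_ratio = c(1, 2, 5, 10)),
    # probability cues 50:50 / 70:30 / 80:20 expressed as odds p/(1-p)
    tidyr::expand_grid(reward_ratio = c(1, 2, 5), likelihood_ratio = c(1, 7 / 3, 4)),
    tidyr::expand_grid(
      reward_ratio = c(1, 2, 4), likelihood_ratio = c(1, 2, 4),
      near_far_ratio = near_far_ratios
    )
  )
  if (is.null(grid)) abort("`experiment` must be 1, 2 or 3.", class = "reachbias_config_error")
  grid |>
    dplyr::mutate(
      block = dplyr::row_number(),
      rewarded_side = ifelse(.data$block %% 2 == 0, "L", "R"),
      frequent_side = ifelse(.data$rewarded_side == "R", "L", "R"),
      n_trials = n_trials
    ) |>
    dplyr::relocate("block")
}

#' Ground-truth condition biases under a profile
#'
#' The generative bias model: on each pure axis the bias follows a straight
#' line in the raw ratio; when both ratios differ from 1 the bias is the
#' weighted sum `w_f * likelihood_line + (1 - w_f) * reward_line`. Values are
#' in the aligned convention (positive toward the more-rewarded side).
#'
#' @param profile a [participant_profile()].
#' @param reward_ratio,likelihood_ratio condition ratios (>= 1, rewarded /
#'   frequent side over the other).
#' @return tibble with `d_choice_prob` (probability a direct reach picks the
#'   rewarded side) and `i_bias_deg` (mean intermediate launch direction).
#' @export
condition_bias <- function(profile, reward_ratio, likelihood_ratio) {
  wsum <- function(w, lik_line, rew_line, f, r) {
    dplyr::case_when(
      f > 1 & r > 1 ~ w * lik_line + (1 - w) * rew_line,
      f > 1 ~ lik_line,
      r > 1 ~ rew_line,
      TRUE ~ (lik_line + rew_line) / 2 # both 1:1 -> both lines at intercept
    )
  }
  dl <- 0.5 + profile$d_likelihood_slope * (likelihood_ratio - 1)
  dr <- 0.5 + profile$d_reward_slope * (reward_ratio - 1)
  il <- profile$i_likelihood_slope * (likelihood_ratio - 1)
  ir <- profile$i_reward_slope * (reward_ratio - 1)
  tibble::tibble(
    d_choice_prob = pmin(pmax(
      wsum(profile$w_f_direct, dl, dr, likelihood_ratio, reward_ratio), 0.02
    ), 0.98),
    i_bias_deg = wsum(profile$w_f_intermediate, il, ir, likelihood_ratio, reward_ratio)
  )
}

# side label helpers ---------------------------------------------------------

other_side <- function(s) ifelse(s == "L", "R", "L")
side_sign <- function(s) ifelse(s == "R", 1, -1)

#' Simulate a single trial
#'
#' Draws the strategy (Bernoulli in `p_intermediate`), the target choice or
#' launch direction from the condition's ground-truth bias, and renders the
#' hand path: a minimum-jerk speed profile along a straight launch direction,
#' with intermediate reaches turning toward the revealed target at constant
#' heading rate starting `reaction_ms` after the reveal. The reveal is
#' triggered when the hand has moved beyond the configured distance or speed
#' (experiments 1-2) or when it crosses the central rectangle (experiment 3).
#'
#' @param profile a [participant_profile()].
#' @param condition one-row data frame (or list) with `reward_ratio`,
#'   `likelihood_ratio`, `rewarded_side`, `frequent_side`, `correct_side`, and
#'   for experiment 3 `near_far_ratio`.
#' @param config a [experiment_config()].
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @return list with `trial` (one-row tibble: condition columns, `t_reveal`,
#'   and ground truth `gt_strategy`, `gt_choice_side`, `gt_aim_deg`) and
#'   `trajectory` (tibble `t`, `x`, `y`).
#' @export
simulate_trial <- function(profile, condition, config, seed = NULL) {
  run <- function() simulate_trial_impl(profile, condition, config)
  if (is.null(seed)) run() else with_seed(seed, run())
}

simulate_trial_impl <- function(profile, condition, config) {
  validate_config(config)
  cond <- as.list(condition)
  exp3 <- config$experiment_id == 3
  sign_pos <- side_sign(cond$rewarded_side)

  p_int <- profile$p_intermediate
  if (exp3 && !is.null(cond$near_far_ratio) && !is.na(cond$near_far_ratio)) {
    p_int <- min(max(p_int + profile$near_far_slope * (cond$near_far_ratio - 1), 0.02), 0.98)
  }
  strategy <- if (runif(1) < p_int) "intermediate" else "direct"

  bias <- condition_bias(profile, cond$reward_ratio, cond$likelihood_ratio)
  noise <- rnorm(1, 0, profile$motor_sd_deg)

  if (strategy == "direct") {
    choice_side <- if (runif(1) < bias$d_choice_prob) cond$rewarded_side else other_side(cond$rewarded_side)
    aim_deg <- side_sign(choice_side) * max(abs(config$target_angles_deg)) + noise
  } else {
    choice_side <- NA_character_
    aim_deg <- sign_pos * bias$i_bias_deg + noise
  }

  # direct reaches steer toward the target they chose; intermediate reaches
  # steer toward the revealed (correct) target after the reaction latency
  goal_side <- if (strategy == "direct") choice_side else cond$correct_side
  path <- render_path(aim_deg, strategy, goal_side, profile, config)

  trial <- tibble::as_tibble(cond[!vapply(cond, is.null, logical(1))])
  trial$t_reveal <- path$t_reveal
  trial$gt_strategy <- strategy
  trial$gt_choice_side <- choice_side
  trial$gt_aim_deg <- aim_deg
  list(trial = trial, trajectory = path$trajectory)
}

# Integrate one hand path. Headings in degrees from +y; speed in m/s
# (1 m/s = 0.1 cm/ms). Returns the trajectory and the reveal time.
# Direct reaches are closed-loop from movement start: the heading homes on
# the chosen target with a slow (~200 ms) time constant, the open-loop
# launch noise surviving in the initial direction while the endpoint
# converges on the target, as online feedback correction does in practice.
# Intermediate reaches stay on their launch heading until reaction_ms after
# the reveal, then home on the revealed target with a fast (~40 ms) constant.
render_path <- function(aim_deg, strategy, goal_side, profile, config) {
  exp3 <- config$experiment_id == 3
  dt <- 1000 / config$sampling_rate_hz # ms per sample
  hold_ms <- 100

  goal_dist <- if (exp3 && strategy == "intermediate") config$far_target_distance_cm else config$target_distance_cm
  goal_angles <- if (exp3 && strategy == "intermediate") config$far_target_angles_deg else config$target_angles_deg
  goal_deg <- side_sign(goal_side) * max(abs(goal_angles))
  goal <- c(goal_dist * sin(goal_deg * pi / 180), goal_dist * cos(goal_deg * pi / 180))

  t_move <- profile$move_duration_ms %||%
    switch(config$experiment_id, 600, 500, 900)
  path_len <- goal_dist * (if (strategy == "intermediate") 1.25 else 1.05)
  v_peak <- 1.875 * path_len / t_move # cm/ms scale folded in below

  n_move <- ceiling(t_move / dt)
  n_hold <- round(hold_ms / dt)
  n <- n_hold + n_move + 1

  t <- (seq_len(n) - 1) * dt
  x <- numeric(n)
  y <- numeric(n)
  heading <- aim_deg
  revealed <- FALSE
  t_reveal <- NA_real_
  turn_started <- strategy == "direct"
  turn_tau_ms <- if (strategy == "direct") 200 else 40

  trig_d <- config$reveal_trigger$distance_cm
  trig_v <- config$reveal_trigger$velocity_ms

  for (i in seq_len(n)[-1]) {
    tm <- t[i] - hold_ms
    if (tm <= 0) next
    tau <- min(tm / t_move, 1)
    speed_ms <- 30 * (path_len / t_move) * tau^2 * (1 - tau)^2 * 10 # cm/ms -> m/s
    step_cm <- speed_ms * 0.1 * dt

    if (strategy == "intermediate" && revealed && !turn_started &&
      (t[i] - t_reveal) >= profile$reaction_ms) {
      turn_started <- TRUE
    }
    if (turn_started) {
      # steer toward the revealed target: proportional correction of the
      # heading gap, closing it exponentially with a ~40 ms time constant
      tgt_dir <- vec_angle_deg(goal[1] - x[i - 1], goal[2] - y[i - 1])
      gap <- wrap_deg(tgt_dir - heading)
      heading <- heading + gap * min(dt / turn_tau_ms, 1)
    }
    x[i] <- x[i - 1] + step_cm * sin(heading * pi / 180)
    y[i] <- y[i - 1] + step_cm * cos(heading * pi / 180)

    if (!revealed) {
      crossed <- if (exp3) {
        strategy == "intermediate" && y[i] >= config$rect_depth_cm &&
          abs(x[i]) <= config$rect_half_width_cm
      } else {
        sqrt(x[i]^2 + y[i]^2) >= trig_d || speed_ms >= trig_v
      }
      if (crossed) {
        revealed <- TRUE
        t_reveal <- t[i]
      }
    }
    if (sqrt(x[i]^2 + y[i]^2) >= goal_dist + 2) {
      n <- i
      break
    }
  }
  list(
    trajectory = tibble::tibble(t = t[seq_len(n)], x = x[seq_len(n)], y = y[seq_len(n)]),
    t_reveal = t_reveal
  )
}

#' Simulate a full session for one participant
#'
#' Batches [simulate_trial()] over a [session_design()]; the correct side is
#' drawn per trial so that the frequent side is correct with probability
#' `f / (f + 1)` where `f` is the block's likelihood ratio. Deterministic
#' under a fixed seed.
#'
#' @param profile a [participant_profile()].
#' @param design a [session_design()] tibble.
#' @param config a [experiment_config()].
#' @param seed integer seed.
#' @param participant_id identifier stored in the tables.
#' @return a `reach_session` whose trial table carries the ground-truth
#'   columns `gt_strategy`, `gt_choice_side`, `gt_aim_deg`.
#' @export
simulate_session <- function(profile, design, config, seed,
                             participant_id = "P01") {
  if (nrow(design) < 1) abort("empty design.", class = "reachbias_config_error")
  with_seed(seed, {
    rows <- vector("list", sum(design$n_trials))
    trajs <- vector("list", sum(design$n_trials))
    k <- 0
    for (b in seq_len(nrow(design))) {
      blk <- design[b, ]
      f <- blk$likelihood_ratio
      for (j in seq_len(blk$n_trials)) {
        k <- k + 1
        correct <- if (runif(1) < f / (f + 1)) blk$frequent_side else other_side(blk$frequent_side)
        cond <- list(
          participant_id = participant_id, block = blk$block, trial = j,
          reward_left = if (blk$rewarded_side == "L") 10 * blk$reward_ratio else 10,
          reward_right = if (blk$rewarded_side == "R") 10 * blk$reward_ratio else 10,
          reward_ratio = blk$reward_ratio,
          likelihood_ratio = blk$likelihood_ratio,
          correct_side = correct,
          rewarded_side = blk$rewarded_side,
          frequent_side = blk$frequent_side
        )
        if ("near_far_ratio" %in% names(blk)) cond$near_far_ratio <- blk$near_far_ratio
        out <- simulate_trial_impl(profile, cond, config)
        rows[[k]] <- out$trial
        trajs[[k]] <- dplyr::mutate(out$trajectory,
          participant_id = participant_id, block = blk$block, trial = j,
          .before = 1
        )
      }
    }
    reach_session(dplyr::bind_rows(rows), dplyr::bind_rows(trajs), config)
  })
}

#' Simulate a cohort of participants
#'
#' @param profiles list of [participant_profile()]s (one per participant).
#' @param design,config,seed as in [simulate_session()].
#' @return a `reach_session` pooling all participants.
#' @export
simulate_cohort <- function(profiles, design, config, seed) {
  seeds <- derive_seeds(seed, length(profiles))
  ids <- sprintf("P%02d", seq_along(profiles))
  sessions <- purrr::map(seq_along(profiles), function(i) {
    simulate_session(profiles[[i]], design, config, seeds[i], participant_id = ids[i])
  })
  reach_session(
    purrr::list_rbind(purrr::map(sessions, "trials")),
    purrr::list_rbind(purrr::map(sessions, "trajectories")),
    config
  )
}

#' Simulate sure-bet versus gamble choices
#'
#' Choice model: the gamble is chosen with probability
#' `plogis(slope * (EV_gamble - sure_bet - indifference_point))`, so the
#' gamble probability increases with the reward difference and equals 0.5
#' exactly at the profile's indifference point. An infinite slope gives the
#' deterministic step-function limit.
#'
#' @param profile a [participant_profile()].
#' @param offers tibble with columns `sure_bet_cents`, `gamble_hi`,
#'   `gamble_lo` (cents; the gamble pays either outcome with probability 0.5).
#' @param seed integer seed.
#' @return the offers with `reward_diff` (EV of gamble minus sure bet) and
#'   `choice` (1 = gamble, 0 = sure bet).
#' @export
simulate_utility_choices <- function(profile, offers, seed) {
  if (nrow(offers) < 1) abort("empty offers.", class = "reachbias_config_error")
  check_columns(offers, c("sure_bet_cents", "gamble_hi", "gamble_lo"), "offer table")
  with_seed(seed, {
    diff <- (offers$gamble_hi + offers$gamble_lo) / 2 - offers$sure_bet_cents
    z <- diff - profile$indifference_point_cents
    p <- if (is.infinite(profile$psychometric_slope)) {
      ifelse(z > 0, 1, ifelse(z < 0, 0, 0.5))
    } else {
      plogis(profile$psychometric_slope * z)
    }
    dplyr::mutate(tibble::as_tibble(offers),
      reward_diff = diff,
      choice = as.integer(runif(dplyr::n()) < p)
    )
  })
}
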