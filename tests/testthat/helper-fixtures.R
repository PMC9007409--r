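# Fixture builders shared across test files. Everything is generated in code;
# trajectories are tiny (tens of samples) unless a test says otherwise.

# Straight-line trajectory at a fixed angle (deg from midline) with a linear
# speed ramp 0 -> v_max (m/s) over ramp_ms, then constant. dt in ms.
straight_trajectory <- function(angle_deg, v_max = 0.6, ramp_ms = 100,
                                total_ms = 600, dt = 10) {
  t <- seq(0, total_ms, by = dt)
  v <- pmin(v_max * t / ramp_ms, v_max) # m/s
  # integrate speed (trapezoid) into distance in cm (1 m/s = 0.1 cm/ms)
  d <- c(0, cumsum((head(v, -1) + tail(v, -1)) / 2 * 0.1 * dt))
  tibble::tibble(
    t = t,
    x = d * sin(angle_deg * pi / 180),
    y = d * cos(angle_deg * pi / 180)
  )
}

# Minimal valid trial table row.
make_trial_row <- function(participant_id = "P1", block = 1L, trial = 1L,
                           reward_ratio = 1, likelihood_ratio = 1,
                           correct_side = "R", rewarded_side = "R") {
  tibble::tibble(
    participant_id = participant_id, block = block, trial = trial,
    reward_left = 10, reward_right = 10 * reward_ratio,
    reward_ratio = reward_ratio, likelihood_ratio = likelihood_ratio,
    correct_side = correct_side, rewarded_side = rewarded_side,
    frequent_side = ifelse(rewarded_side == "R", "L", "R"),
    t_reveal = NA_real_
  )
}

# Tiny two-trial session with straight-line paths.
make_tiny_session <- function(config = experiment_config(1)) {
  trials <- dplyr::bind_rows(
    make_trial_row(trial = 1L),
    make_trial_row(trial = 2L, correct_side = "L")
  )
  traj <- dplyr::bind_rows(
    dplyr::mutate(straight_trajectory(22.5),
      participant_id = "P1", block = 1L, trial = 1L, .before = 1
    ),
    dplyr::mutate(straight_trajectory(-22.5),
      participant_id = "P1", block = 1L, trial = 2L, .before = 1
    )
  )
  reach_session(trials, traj, config)
}

# Brute-force per-sample commit-time oracle: recompute the angular window
# membership for every sample independently of the package's vectorized path.
oracle_commit_time <- function(traj, config, onset_ms = NULL, half_window = 2) {
  sp <- reachbias::trajectory_speeds(traj, half_window)
  r_win <- config$hit_radius_cm
  best <- NA_real_
  for (i in seq_len(nrow(traj))) {
    if (!is.null(onset_ms) && sp$t[i] < onset_ms) next
    if (is.na(sp$heading_deg[i])) next
    for (ang in config$target_angles_deg) {
      cx <- config$target_distance_cm * sin(ang * pi / 180)
      cy <- config$target_distance_cm * cos(ang * pi / 180)
      dx <- cx - traj$x[i]
      dy <- cy - traj$y[i]
      dist <- sqrt(dx^2 + dy^2)
      if (dist <= r_win) next
      half <- asin(min(r_win / dist, 1)) * 180 / pi
      gap <- ((atan2(dx, dy) * 180 / pi - sp$heading_deg[i] + 180) %% 360) - 180
      if (abs(gap) <= half) {
        return(sp$t[i])
      }
    }
  }
  best
}

# Closed-form least-squares weight for the weighted-sum model, clamped to
# [0, 1]: w* = sum((L - R) (obs - R)) / sum((L - R)^2).
oracle_closed_form_weight <- function(effects, mixed, measure) {
  L <- effects$likelihood["intercept"] + effects$likelihood["slope"] * mixed$likelihood_ratio
  R <- effects$reward["intercept"] + effects$reward["slope"] * mixed$reward_ratio
  obs <- mixed[[measure]]
  w <- sum((L - R) * (obs - R)) / sum((L - R)^2)
  unname(min(max(w, 0), 1))
}

# Grid-search maximum-likelihood oracle for a 2-component Gaussian mixture:
# cyclic per-parameter grid refinement (zooming line search) over
# (mu1, mu2, sd1, sd2, p), started from a data split at zero — entirely
# independent of the EM updates.
oracle_gmm2_loglik <- function(x, sweeps = 14, n_grid = 21) {
  ll_of <- function(par) {
    d <- par[5] * dnorm(x, par[1], par[3]) + (1 - par[5]) * dnorm(x, par[2], par[4])
    sum(log(pmax(d, .Machine$double.xmin)))
  }
  lo <- x[x < 0]
  hi <- x[x >= 0]
  par <- c(
    mean(lo), mean(hi),
    max(sd(lo), 0.5), max(sd(hi), 0.5),
    min(max(length(lo) / length(x), 0.05), 0.95)
  )
  width <- c(10, 10, 4, 4, 0.4)
  lower <- c(-Inf, -Inf, 0.25, 0.25, 0.01)
  upper <- c(Inf, Inf, Inf, Inf, 0.99)
  for (s in seq_len(sweeps)) {
    for (j in 1:5) {
      cand <- seq(par[j] - width[j], par[j] + width[j], length.out = n_grid)
      cand <- pmin(pmax(cand, lower[j]), upper[j])
      lls <- vapply(cand, function(v) {
        p2 <- par
        p2[j] <- v
        ll_of(p2)
      }, numeric(1))
      par[j] <- cand[which.max(lls)]
    }
    width <- width * 0.5
  }
  ll_of(par)
}
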