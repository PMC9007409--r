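# Direct versus intermediate classification and outcome typing.
#
# Experiments 1-2 use a temporal criterion: the reach is direct if the hand's
# instantaneous heading first enters the angular window subtended by either
# target (T_commit) strictly before the reveal time plus a 60 ms perceptual
# delay. Experiment 3 uses geometry: a reach that intercepts the central
# rectangle is intermediate, otherwise direct.

target_xy <- function(angle_deg, distance_cm) {
  c(distance_cm * sin(angle_deg * pi / 180), distance_cm * cos(angle_deg * pi / 180))
}

#' Time of commitment to a target
#'
#' Scans post-onset samples for the first time the instantaneous heading lies
#' inside the angular window subtended, at the current hand position, by a
#' disc of radius `target_radius + cursor_radius` around either target centre
#' (the task scores cursor-target intersection). Samples where the hand is
#' inside that disc (window undefined) or at rest (heading undefined) are
#' skipped.
#'
#' @param trajectory single-trial tibble (`t`, `x`, `y`).
#' @param config a [experiment_config()]; supplies target geometry.
#' @param onset_ms,end_ms search window; defaults to the full trajectory.
#' @param half_window see [trajectory_speeds()].
#' @return commit time in ms, or `NA` if the heading never enters a window.
#' @export
find_commit_time <- function(trajectory, config, onset_ms = NULL, end_ms = NULL,
                             half_window = 2) {
  sp <- trajectory_speeds(trajectory, half_window)
  keep <- rep(TRUE, nrow(sp))
  if (!is.null(onset_ms)) keep <- keep & sp$t >= onset_ms
  if (!is.null(end_ms)) keep <- keep & sp$t <= end_ms
  keep <- keep & !is.na(sp$heading_deg)

  r_win <- config$hit_radius_cm
  targets <- lapply(config$target_angles_deg, target_xy, distance_cm = config$target_distance_cm)

  in_window <- rep(FALSE, nrow(sp))
  for (tg in targets) {
    dx <- tg[1] - trajectory$x
    dy <- tg[2] - trajectory$y
    dist <- sqrt(dx^2 + dy^2)
    ok <- dist > r_win # inside the disc the window is undefined; skip
    half_angle <- ifelse(ok, asin(pmin(r_win / dist, 1)) * 180 / pi, NA_real_)
    gap <- abs(wrap_deg(vec_angle_deg(dx, dy) - sp$heading_deg))
    in_window <- in_window | (ok & !is.na(gap) & gap <= half_angle)
  }
  hits <- which(keep & in_window)
  if (length(hits) == 0) {
    return(NA_real_)
  }
  sp$t[hits[1]]
}

#' Temporal direct/intermediate rule
#'
#' Direct if and only if `t_commit` is strictly before
#' `t_reveal + delay_ms`; a reach that never commits is intermediate. The
#' boundary case `t_commit == t_reveal + delay_ms` is intermediate (strict
#' "before").
#'
#' @param t_commit,t_reveal times in ms (vectorized; `t_commit` may be `NA`).
#' @param delay_ms perceptual delay added to the reveal (60 ms).
#' @return character vector `"direct"` / `"intermediate"`.
#' @export
classify_temporal <- function(t_commit, t_reveal, delay_ms = 60) {
  ifelse(!is.na(t_commit) & t_commit < t_reveal + delay_ms, "direct", "intermediate")
}

#' Geometric direct/intermediate rule (five-target layout)
#'
#' A reach is intermediate if the path crosses the central rectangle before
#' entering either near-target disc; otherwise direct. The rectangle is the
#' band at the near-target depth spanning 46 deg across the midline; crossing
#' is tested per path segment against that depth line.
#'
#' @param trajectory single-trial tibble.
#' @param config an experiment-3 [experiment_config()].
#' @return `"direct"` or `"intermediate"`.
#' @export
classify_geometric <- function(trajectory, config) {
  if (is.null(config$rect_depth_cm)) {
    abort("geometric classification requires the experiment-3 layout.",
      class = "reachbias_config_error"
    )
  }
  x <- trajectory$x
  y <- trajectory$y
  n <- length(x)
  if (n < 2) {
    return("direct")
  }
  y0 <- config$rect_depth_cm

  seg <- seq_len(n - 1)
  crosses <- (y[seg] < y0 & y[seg + 1] >= y0)
  xc <- x[seg] + (y0 - y[seg]) / (y[seg + 1] - y[seg]) * (x[seg + 1] - x[seg])
  rect_hit <- crosses & abs(xc) <= config$rect_half_width_cm
  t_rect <- if (any(rect_hit)) which(rect_hit)[1] else Inf

  near <- lapply(config$target_angles_deg, target_xy, distance_cm = config$target_distance_cm)
  t_near <- Inf
  for (tg in near) {
    d <- sqrt((x - tg[1])^2 + (y - tg[2])^2)
    hit <- which(d <= config$hit_radius_cm)
    if (length(hit)) t_near <- min(t_near, hit[1])
  }
  if (t_rect < t_near) "intermediate" else "direct"
}

#' Type a trial's outcome: hit, choice error, or motor error
#'
#' Endpoint error is the minimum Euclidean distance between the hand path
#' (post-onset samples) and a target centre. A reach whose endpoint error to
#' the incorrect target is smaller than to the correct target is a choice
#' error; otherwise it is a hit if the error to the correct target is at most
#' the hit radius (1.5 cm), else a motor error.
#'
#' @param trajectory single-trial tibble.
#' @param correct_xy,incorrect_xy target centres, `c(x, y)` in cm.
#' @param config a [experiment_config()].
#' @param after_ms only samples at or after this time are considered.
#' @param endpoint `"path_min"` (default; minimum over the path, the natural
#'   reading for a shooting task) or `"terminal"` (final sample only).
#' @return `"hit"`, `"choice_error"` or `"motor_error"`.
#' @export
classify_outcome <- function(trajectory, correct_xy, incorrect_xy, config,
                             after_ms = 0, endpoint = c("path_min", "terminal")) {
  endpoint <- match.arg(endpoint)
  sel <- trajectory$t >= after_ms
  x <- trajectory$x[sel]
  y <- trajectory$y[sel]
  if (endpoint == "terminal") {
    x <- x[length(x)]
    y <- y[length(y)]
  }
  d_cor <- min(sqrt((x - correct_xy[1])^2 + (y - correct_xy[2])^2))
  d_inc <- min(sqrt((x - incorrect_xy[1])^2 + (y - incorrect_xy[2])^2))
  if (d_inc < d_cor) {
    "choice_error"
  } else if (d_cor <= config$hit_radius_cm) {
    "hit"
  } else {
    "motor_error"
  }
}

#' Classify every trial of a session
#'
#' Runs the kinematic summaries and exclusions, then labels each kept trial
#' direct or intermediate (temporal rule for experiments 1-2, geometric rule
#' for experiment 3) and types its outcome. Initial directions are also
#' reported in the aligned convention (positive toward the more-rewarded
#' side; in equal-reward blocks the stored `rewarded_side` label carries the
#' counterbalance orientation, so the frequent side maps to negative).
#'
#' @param session a `reach_session`.
#' @param kinematics optional precomputed [summarize_kinematics()] output.
#' @return tibble with one row per trial: condition columns, kinematic
#'   summaries, `keep`/`drop_reason`, and for kept trials `t_commit`,
#'   `strategy`, `aligned_initial_direction_deg`, `outcome`.
#' @export
classify_trials <- function(session, kinematics = NULL) {
  cfg <- session$config
  if (is.null(kinematics)) kinematics <- summarize_kinematics(session)
  kin <- apply_exclusions(kinematics, cfg)
  trials <- dplyr::left_join(
    session$trials, kin,
    by = c("participant_id", "block", "trial")
  )
  exp3 <- cfg$experiment_id == 3
  traj_by_trial <- session$trajectories |>
    dplyr::group_by(.data$participant_id, .data$block, .data$trial) |>
    dplyr::group_split()
  keys <- session$trajectories |>
    dplyr::distinct(.data$participant_id, .data$block, .data$trial)
  key_id <- trial_key(keys)
  names(traj_by_trial) <- key_id

  out <- trials
  out$t_commit <- NA_real_
  out$strategy <- NA_character_
  out$outcome <- NA_character_

  for (i in seq_len(nrow(out))) {
    if (!isTRUE(out$keep[i])) next
    traj <- traj_by_trial[[trial_key(out[i, ])]]
    if (exp3) {
      out$strategy[i] <- classify_geometric(traj, cfg)
      dist <- if (out$strategy[i] == "intermediate") cfg$far_target_distance_cm else cfg$target_distance_cm
      angs <- if (out$strategy[i] == "intermediate") cfg$far_target_angles_deg else cfg$target_angles_deg
    } else {
      out$t_commit[i] <- find_commit_time(
        traj, cfg,
        onset_ms = out$onset_ms[i], end_ms = out$end_of_motion_ms[i]
      )
      out$strategy[i] <- classify_temporal(
        out$t_commit[i], out$t_reveal[i], cfg$perception_delay_ms
      )
      dist <- cfg$target_distance_cm
      angs <- cfg$target_angles_deg
    }
    cor_ang <- side_sign(out$correct_side[i]) * max(abs(angs))
    out$outcome[i] <- classify_outcome(
      traj,
      target_xy(cor_ang, dist), target_xy(-cor_ang, dist),
      cfg,
      after_ms = out$onset_ms[i]
    )
  }
  out$aligned_initial_direction_deg <-
    out$initial_direction_deg * side_sign(out$rewarded_side)
  out
}

#' Re-sign angles so the more-rewarded side is positive
#'
#' In fully symmetric (1:1 reward) blocks the stored `rewarded_side` label is
#' the counterbalance orientation, which places the frequent side on the
#' negative side (the frequent side is always opposite the label).
#'
#' @param data data frame with an angle column and a `rewarded_side` column.
#' @param angle unquoted name of the angle column (lab frame, rightward
#'   positive).
#' @return `data` with an added `aligned_deg` column.
#' @export
align_angles <- function(data, angle = initial_direction_deg) {
  check_columns(data, "rewarded_side", "trial data")
  if (any(is.na(data$rewarded_side))) {
    abort("`rewarded_side` labels are missing.", class = "reachbias_format_error")
  }
  dplyr::mutate(data, aligned_deg = {{ angle }} * side_sign(.data$rewarded_side))
}
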