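# Experiment geometry and analysis thresholds.
#
# Experiment 1: two ring targets (2 cm diameter) 45 deg apart, 20 cm from the
#   start; blockwise frequency ratios crossed with displayed reward ratios.
# Experiment 2: same geometry; per-trial probability cue instead of blockwise
#   frequency; movement-time limit clocked from the go tone.
# Experiment 3: near targets 90 deg apart at 10 cm, an "intermediate" rectangle
#   spanning 46 deg across the midline at the near-target depth (7.07 cm), far
#   targets 45 deg apart at 15 cm.

#' Build an experiment configuration
#'
#' Bundles the task geometry and analysis thresholds for one of the three
#' go-before-you-know experiment variants. Defaults follow the published task
#' descriptions; any field may be overridden.
#'
#' @param experiment integer 1, 2 or 3; selects geometry, onset threshold and
#'   exclusion rules.
#' @param sampling_rate_hz trajectory sampling rate. Hardware recordings are
#'   1000 Hz; the synthetic generator defaults to 100 Hz for speed, and every
#'   threshold in the pipeline is expressed in rate-independent units.
#' @param ... named overrides for any configuration field (e.g.
#'   `target_radius_cm`, `onset_velocity_ms`, `exclusion`).
#'
#' @return an object of class `reach_config`: a named list with fields
#'   `experiment_id`, `target_angles_deg`, `target_distance_cm`,
#'   `target_radius_cm`, `cursor_radius_cm`, `onset_velocity_ms`,
#'   `reveal_trigger` (`distance_cm`, `velocity_ms`), `perception_delay_ms`,
#'   `initial_direction_latency_ms`, `exclusion` (`max_angle_deg`,
#'   `max_duration_ms`, `clock`), `sampling_rate_hz`, `hit_radius_cm`, and for
#'   experiment 3 the far-target and rectangle geometry.
#'
#' @details The classification hit radius is the target radius plus the cursor
#'   radius (1.5 cm): the task scores cursor-target intersection. Experiment 3
#'   uses a more liberal onset threshold (0.02 m/s) and a wider angular
#'   exclusion (75 deg) because reaches may legitimately skirt the central
#'   rectangle.
#'
#' @examples
#' cfg <- experiment_config(1)
#' cfg$target_angles_deg
#' @export
experiment_config <- function(experiment = 1L, sampling_rate_hz = 100, ...) {
  experiment <- as.integer(experiment)
  if (!experiment %in% 1:3) {
    abort("`experiment` must be 1, 2 or 3.", class = "reachbias_config_error")
  }
  base <- list(
    experiment_id = experiment,
    target_radius_cm = 1.0,
    cursor_radius_cm = 0.5,
    reveal_trigger = list(distance_cm = 4, velocity_ms = 0.1),
    perception_delay_ms = 60,
    initial_direction_latency_ms = 100,
    sampling_rate_hz = sampling_rate_hz
  )
  geom <- switch(experiment,
    # Exp 1: 45 deg apart, 20 cm; exclusion clocked from target appearance.
    list(
      target_angles_deg = c(-22.5, 22.5),
      target_distance_cm = 20,
      onset_velocity_ms = 0.05,
      exclusion = list(max_angle_deg = 45, max_duration_ms = 1000, clock = "target_onset")
    ),
    # Exp 2: same geometry; 650 ms movement-time limit from the go tone.
    list(
      target_angles_deg = c(-22.5, 22.5),
      target_distance_cm = 20,
      onset_velocity_ms = 0.05,
      exclusion = list(max_angle_deg = 45, max_duration_ms = 650, clock = "go_tone")
    ),
    # Exp 3: near pair 90 deg apart at 10 cm, far pair 45 deg apart at 15 cm,
    # rectangle spanning 46 deg across the midline at the near-target depth.
    list(
      target_angles_deg = c(-45, 45),
      target_distance_cm = 10,
      far_target_angles_deg = c(-22.5, 22.5),
      far_target_distance_cm = 15,
      rect_depth_cm = 7.07,
      rect_half_width_cm = 7.07 * tan(23 * pi / 180),
      onset_velocity_ms = 0.02,
      exclusion = list(max_angle_deg = 75, max_duration_ms = 2500, clock = "target_onset")
    )
  )
  cfg <- utils::modifyList(c(base, geom), list(...))
  cfg$hit_radius_cm <- cfg$target_radius_cm + cfg$cursor_radius_cm
  class(cfg) <- "reach_config"
  validate_config(cfg)
}

#' Validate a reach configuration
#'
#' Checks the invariants every downstream stage relies on: a symmetric target
#' layout, strictly positive thresholds and a positive sampling rate.
#'
#' @param config a `reach_config`.
#' @return the config, invisibly usable in a pipe; errors on violation.
#' @export
validate_config <- function(config) {
  a <- sort(config$target_angles_deg)
  if (length(a) != 2 || abs(a[1] + a[2]) > 1e-9) {
    abort("target angles must be symmetric about the midline.",
      class = "reachbias_config_error"
    )
  }
  if (any(abs(a) < 1e-9)) {
    abort("targets may not sit on the midline.", class = "reachbias_config_error")
  }
  positive <- c(
    target_distance = config$target_distance_cm,
    target_radius = config$target_radius_cm,
    onset_velocity = config$onset_velocity_ms,
    sampling_rate = config$sampling_rate_hz,
    reveal_distance = config$reveal_trigger$distance_cm,
    reveal_velocity = config$reveal_trigger$velocity_ms,
    max_angle = config$exclusion$max_angle_deg,
    max_duration = config$exclusion$max_duration_ms
  )
  if (any(!is.finite(positive)) || any(positive <= 0)) {
    bad <- names(positive)[!is.finite(positive) | positive <= 0]
    abort(
      sprintf("configuration thresholds must be positive: %s", paste(bad, collapse = ", ")),
      class = "reachbias_config_error"
    )
  }
  invisible(config)
}

#' @export
print.reach_config <- function(x, ...) {
  cat(sprintf(
    "<reach_config> experiment %d: targets at %s deg, %g cm; onset > %g m/s; %g Hz\n",
    x$experiment_id, paste(x$target_angles_deg, collapse = "/"),
    x$target_distance_cm, x$onset_velocity_ms, x$sampling_rate_hz
  ))
  invisible(x)
}

#' Read / write a configuration as YAML
#'
#' @param path file path.
#' @return `read_config()` returns a validated `reach_config`;
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(
    experiment_config,
    c(
      list(
        experiment = raw$experiment_id,
        sampling_rate_hz = raw$sampling_rate_hz %||% 100
      ),
      raw[setdiff(names(raw), c("experiment_id", "sampling_rate_hz", "hit_radius_cm"))]
    )
  )
  cfg
}

#' @rdname read_config
#' @param config a `reach_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
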