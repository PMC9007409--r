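# Session I/O: comma-delimited trial and trajectory tables, JSON results.
#
# A session couples a per-trial condition table with a long-format trajectory
# table; trials are keyed by (participant_id, block, trial). Timestamps are in
# ms from trial start (0-based); positions in cm with the start at the origin,
# x positive rightward, y positive away from the body.

TRIAL_COLUMNS <- c(
  "participant_id", "block", "trial", "reward_left", "reward_right",
  "likelihood_ratio", "correct_side", "rewarded_side", "frequent_side",
  "t_reveal"
)
TRAJ_COLUMNS <- c("participant_id", "block", "trial", "t", "x", "y")

trial_key <- function(df) {
  paste(df$participant_id, df$block, df$trial, sep = "\r")
}

#' Construct a reach session from trial and trajectory tables
#'
#' @param trials tibble with columns `participant_id`, `block`, `trial`,
#'   `reward_left`, `reward_right` (cents), `likelihood_ratio`,
#'   `correct_side`, `rewarded_side`, `frequent_side` (each `"L"`/`"R"`),
#'   `t_reveal` (ms; `NA` before processing). Extra columns are kept.
#' @param trajectories tibble with columns `participant_id`, `block`, `trial`,
#'   `t` (ms), `x`, `y` (cm).
#' @param config a [experiment_config()] object.
#' @return a `reach_session`: list of `trials`, `trajectories`, `config`.
#' @export
reach_session <- function(trials, trajectories, config) {
  trials <- tibble::as_tibble(trials)
  trajectories <- tibble::as_tibble(trajectories)
  check_columns(trials, TRIAL_COLUMNS, "trial table")
  check_columns(trajectories, TRAJ_COLUMNS, "trajectory table")

  bad_side <- !trials$correct_side %in% c("L", "R")
  if (any(bad_side)) {
    abort("`correct_side` must be 'L' or 'R'.", class = "reachbias_format_error")
  }

  tk <- trial_key(trials)
  xk <- trial_key(trajectories)
  orphan_traj <- setdiff(unique(xk), tk)
  orphan_trial <- setdiff(tk, unique(xk))
  if (length(orphan_traj) || length(orphan_trial)) {
    listing <- c(
      if (length(orphan_traj)) {
        sprintf("trajectories without a trial row: %s", paste(gsub("\r", "/", orphan_traj), collapse = "; "))
      },
      if (length(orphan_trial)) {
        sprintf("trials without trajectory samples: %s", paste(gsub("\r", "/", orphan_trial), collapse = "; "))
      }
    )
    abort(paste(c("trial/trajectory key mismatch:", listing), collapse = "\n"),
      class = "reachbias_key_mismatch"
    )
  }

  mono <- trajectories |>
    dplyr::group_by(.data$participant_id, .data$block, .data$trial) |>
    dplyr::summarise(ok = all(diff(.data$t) > 0), .groups = "drop")
  if (!all(mono$ok)) {
    abort("trajectory timestamps must be strictly increasing within each trial.",
      class = "reachbias_format_error"
    )
  }

  structure(
    list(trials = trials, trajectories = trajectories, config = config),
    class = "reach_session"
  )
}

#' @export
print.reach_session <- function(x, ...) {
  cat(sprintf(
    "<reach_session> %d trials, %d participants, experiment %d, %d trajectory samples\n",
    nrow(x$trials), dplyr::n_distinct(x$trials$participant_id),
    x$config$experiment_id, nrow(x$trajectories)
  ))
  invisible(x)
}

#' Read a session from CSV trial and trajectory files
#'
#' Both files are comma-delimited with a header row. Missing columns raise a
#' format error naming the column; unmatched trial keys raise an error listing
#' the orphans.
#'
#' @param trial_path,traj_path CSV file paths.
#' @param config a [experiment_config()] object.
#' @return a `reach_session`.
#' @export
read_session <- function(trial_path, traj_path, config) {
  for (p in c(trial_path, traj_path)) {
    if (!file.exists(p)) {
      abort(sprintf("file not found: %s", p), class = "reachbias_io_error")
    }
  }
  trials <- utils::read.csv(trial_path, stringsAsFactors = FALSE) |> tibble::as_tibble()
  traj <- utils::read.csv(traj_path, stringsAsFactors = FALSE) |> tibble::as_tibble()
  if ("t_reveal" %in% names(trials)) trials$t_reveal <- as.numeric(trials$t_reveal)
  reach_session(trials, traj, config)
}

#' Write a session to CSV trial and trajectory files
#'
#' The written files round-trip losslessly through [read_session()].
#'
#' @param session a `reach_session`.
#' @inheritParams read_session
#' @return invisibly, the two paths.
#' @export
write_session <- function(session, trial_path, traj_path) {
  utils::write.csv(session$trials, trial_path, row.names = FALSE)
  utils::write.csv(session$trajectories, traj_path, row.names = FALSE)
  invisible(c(trial_path, traj_path))
}

RESULTS_SCHEMA_VERSION <- "1.0"

#' Write analysis results to JSON
#'
#' Serializes a (possibly nested) list of results tables and scalars to a
#' schema-versioned JSON file. Data frames are stored as row records so the
#' file re-reads losslessly; writing the re-read object again is
#' byte-identical.
#'
#' @param results named list; tibbles, vectors and scalars allowed at any
#'   depth. An empty list writes a valid file with empty sections.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_results <- function(results, path) {
  payload <- list(schema_version = RESULTS_SCHEMA_VERSION, results = results)
  ok <- tryCatch(
    {
      suppressWarnings(jsonlite::write_json(payload, path,
        dataframe = "rows", auto_unbox = TRUE, digits = NA, null = "null", na = "null"
      ))
      TRUE
    },
    error = function(e) e
  )
  if (!isTRUE(ok)) {
    abort(sprintf("cannot write results to '%s': %s", path, conditionMessage(ok)),
      class = "reachbias_io_error"
    )
  }
  invisible(path)
}

#' Import adapter for externally deposited datasets (stub)
#'
#' The file layout of externally deposited recordings is not part of this
#' package's contract; converting such a deposit into the trial and
#' trajectory CSVs read by [read_session()] is left to a future adapter.
#'
#' @param path path to a deposited dataset.
#' @return never returns; raises a `reachbias_not_implemented` error.
#' @export
read_deposit <- function(path) {
  abort(
    "no import adapter is implemented for external deposits; convert to the trial/trajectory CSV layout and use read_session().",
    class = "reachbias_not_implemented"
  )
}

#' @rdname write_results
#' @return `read_results()` returns the `results` list.
#' @export
read_results <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(payload$schema_version)) {
    abort("not a reachbias results file (missing schema_version).",
      class = "reachbias_format_error"
    )
  }
  payload$results
}
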