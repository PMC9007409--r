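# Internal helpers shared across modules.

# Angles live in degrees, measured from the midline (+y), positive rightward
# in the lab frame. Analysis steps re-sign them so the more-rewarded side is
# positive ("aligned" convention).

#' Angle of a planar vector from the midline
#'
#' @param dx,dy vector components (x rightward, y away from the body).
#' @return angle in degrees in (-180, 180], 0 along +y, positive toward +x.
#' @noRd
vec_angle_deg <- function(dx, dy) {
  ang <- atan2(dx, dy) * 180 / pi
  # resolve the -180 boundary toward positive
  ifelse(ang <= -180, ang + 360, ang)
}

#' Wrap an angle difference into (-180, 180]
#' @noRd
wrap_deg <- function(a) {
  a <- (a + 180) %% 360 - 180
  ifelse(a <= -180, a + 360, a)
}

#' Draw a reproducible sub-seed stream
#'
#' Derives `n` independent 31-bit integer seeds from one parent seed without
#' disturbing the caller's RNG state.
#' @noRd
derive_seeds <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  sample.int(.Machine$integer.max, n)
}

#' Evaluate an expression under a fixed seed, restoring RNG state afterwards
#' @noRd
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Stop with a named format error if columns are missing
#' @noRd
check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(
      sprintf(
        "%s is missing required column%s: %s",
        what, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
      ),
      class = "reachbias_format_error"
    )
  }
  invisible(df)
}

#' Structured per-stage log message (suppressible via option)
#' @noRd
log_stage <- function(stage, msg, ...) {
  if (isTRUE(getOption("reachbias.quiet", TRUE))) return(invisible(NULL))
  message(sprintf("[%s] %s", stage, sprintf(msg, ...)))
}
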