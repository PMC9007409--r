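# Relative weighting of success likelihood versus reward.
#
# Pure-axis conditions (one ratio held at 1:1) give two linear regressions of
# bias on the raw ratio; the weight w_f in [0, 1] is the mixing coefficient of
# the two regression lines that best predicts the biases observed when both
# ratios differ from 1. One weight is estimated per bootstrap iteration (or
# per participant), yielding a weight distribution per reach strategy.

#' Fit the independent reward and likelihood axis regressions
#'
#' Ordinary least squares of the bias measure on the raw ratio, separately
#' for the reward axis (conditions with likelihood 1:1) and the likelihood
#' axis (conditions with reward 1:1). In the aligned convention the reward
#' slope is expected positive and the likelihood slope negative (not
#' enforced).
#'
#' @param bias_table one iteration's (or participant's) condition table with
#'   columns `reward_ratio`, `likelihood_ratio` and the measure column.
#' @param measure `"d_choice"` or `"i_bias"`.
#' @param predictor `"ratio"` (default; the raw ratio, matching the scale on
#'   which axis slopes are conventionally reported) or `"log_ratio"`.
#' @return an `axis_effects` object: per-axis intercept and slope plus the
#'   measure name and predictor transform.
#' @export
fit_axis_effects <- function(bias_table, measure = c("d_choice", "i_bias"),
                             predictor = c("ratio", "log_ratio")) {
  measure <- match.arg(measure)
  predictor <- match.arg(predictor)
  check_columns(bias_table, c("reward_ratio", "likelihood_ratio", measure), "bias table")
  trans <- if (predictor == "log_ratio") log else identity
  rew <- dplyr::filter(bias_table, .data$likelihood_ratio == 1)
  lik <- dplyr::filter(bias_table, .data$reward_ratio == 1)
  fit_line <- function(df, ratio_col, axis) {
    df <- df[!is.na(df[[measure]]), ]
    x <- trans(df[[ratio_col]])
    if (dplyr::n_distinct(x) < 2) {
      abort(sprintf("%s axis needs at least 2 distinct ratios.", axis),
        class = "reachbias_insufficient_data"
      )
    }
    coef(lm(df[[measure]] ~ x))
  }
  rc <- fit_line(rew, "reward_ratio", "reward")
  lc <- fit_line(lik, "likelihood_ratio", "likelihood")
  structure(
    list(
      measure = measure, predictor = predictor,
      reward = c(intercept = unname(rc[1]), slope = unname(rc[2])),
      likelihood = c(intercept = unname(lc[1]), slope = unname(lc[2]))
    ),
    class = "axis_effects"
  )
}

#' @export
print.axis_effects <- function(x, ...) {
  cat(sprintf(
    "<axis_effects> %s: reward = %.4f %+.4f r, likelihood = %.4f %+.4f f\n",
    x$measure, x$reward["intercept"], x$reward["slope"],
    x$likelihood["intercept"], x$likelihood["slope"]
  ))
  invisible(x)
}

#' @export
tidy.axis_effects <- function(x, ...) {
  tibble::tibble(
    axis = c("reward", "likelihood"),
    intercept = c(x$reward["intercept"], x$likelihood["intercept"]),
    slope = c(x$reward["slope"], x$likelihood["slope"]),
    measure = x$measure
  )
}

axis_lines <- function(effects, conditions) {
  trans <- if (identical(effects$predictor, "log_ratio")) log else identity
  list(
    likelihood = effects$likelihood["intercept"] +
      effects$likelihood["slope"] * trans(conditions$likelihood_ratio),
    reward = effects$reward["intercept"] +
      effects$reward["slope"] * trans(conditions$reward_ratio)
  )
}

#' Predict bias under a given likelihood weight
#'
#' `w_f * likelihood_line(f) + (1 - w_f) * reward_line(r)`; `w_f = 0.5` is
#' the equal-weighting prediction.
#'
#' @param effects an [fit_axis_effects()] result.
#' @param w_f likelihood (frequency) weight in `[0, 1]`.
#' @param conditions data frame with `reward_ratio` and `likelihood_ratio`.
#' @return numeric vector of predicted biases.
#' @export
predict_bias <- function(effects, w_f, conditions) {
  ln <- axis_lines(effects, conditions)
  unname(w_f * ln$likelihood + (1 - w_f) * ln$reward)
}

#' Estimate the likelihood weight for one bias table
#'
#' Grid search over `w_f` in `[0, 1]` (step 0.001, ties resolved to the
#' smallest value) minimizing the summed squared prediction error over the
#' mixed conditions (both ratios different from 1:1), each condition entering
#' once, unweighted.
#'
#' @param effects an [fit_axis_effects()] result.
#' @param mixed_biases data frame of mixed conditions with `reward_ratio`,
#'   `likelihood_ratio` and the measure column named in `effects$measure`.
#' @param grid_step grid resolution.
#' @return a `weight_estimate`: `w_f`, `w_r = 1 - w_f`, `sse`, `measure`,
#'   `n_conditions`.
#' @export
estimate_weight <- function(effects, mixed_biases, grid_step = 0.001) {
  measure <- effects$measure
  mixed <- dplyr::filter(
    mixed_biases, .data$reward_ratio != 1, .data$likelihood_ratio != 1,
    !is.na(.data[[measure]])
  )
  if (nrow(mixed) == 0) {
    abort("no mixed conditions (both ratios != 1) available.",
      class = "reachbias_insufficient_data"
    )
  }
  obs <- mixed[[measure]]
  ln <- axis_lines(effects, mixed)
  w <- seq(0, 1, grid_step)
  # sse(w) = sum((w * L + (1 - w) * R - obs)^2), vectorized over the grid
  dL <- ln$likelihood - ln$reward
  resid0 <- ln$reward - obs
  sse <- colSums((outer(dL, w) + resid0)^2)
  best <- which.min(sse) # first minimum -> smallest w on ties
  structure(
    list(
      w_f = w[best], w_r = 1 - w[best], sse = sse[best],
      measure = measure, n_conditions = nrow(mixed)
    ),
    class = "weight_estimate"
  )
}

#' @export
print.weight_estimate <- function(x, ...) {
  cat(sprintf(
    "<weight_estimate> %s: w_f = %.3f (w_r = %.3f), sse = %.3g over %d mixed conditions\n",
    x$measure, x$w_f, x$w_r, x$sse, x$n_conditions
  ))
  invisible(x)
}

#' Per-iteration weight estimates from a bias table
#'
#' Applies [fit_axis_effects()] and [estimate_weight()] within each bootstrap
#' iteration (or participant) for one measure.
#'
#' @param bias_table tibble with a grouping column (`iteration` or
#'   `participant_id`), `reward_ratio`, `likelihood_ratio`, and the measure.
#' @param measure `"d_choice"` or `"i_bias"`.
#' @param by name of the grouping column; guessed from the table if absent.
#' @return tibble with the grouping column, `w_f`, `sse`, `ok` (estimation
#'   succeeded), `measure`.
#' @export
estimate_weights <- function(bias_table, measure = c("d_choice", "i_bias"),
                             by = NULL) {
  measure <- match.arg(measure)
  if (inherits(bias_table, "bias_bootstrap")) bias_table <- bias_table$draws
  by <- by %||% intersect(c("iteration", "participant_id"), names(bias_table))[1]
  if (is.na(by)) abort("no `iteration` or `participant_id` column found.")
  bias_table |>
    dplyr::group_by(.data[[by]]) |>
    dplyr::group_modify(function(df, key) {
      res <- tryCatch(
        {
          eff <- fit_axis_effects(df, measure)
          est <- estimate_weight(eff, df)
          tibble::tibble(w_f = est$w_f, sse = est$sse, ok = TRUE)
        },
        reachbias_insufficient_data = function(e) {
          tibble::tibble(w_f = NA_real_, sse = NA_real_, ok = FALSE)
        }
      )
      res
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(measure = measure)
}

#' Compare the direct and intermediate weight distributions
#'
#' One-sample t tests of each distribution against 0.5 (equal weighting), a
#' paired t test and a two-sample Kolmogorov-Smirnov test between them, plus
#' mean and SD summaries. The paired test requires equal lengths with shared
#' keys. Zero-variance inputs are flagged instead of producing an infinite
#' statistic.
#'
#' @param direct_w,intermediate_w numeric weight distributions (e.g. the
#'   `w_f` column of [estimate_weights()] output), index-aligned for the
#'   paired test.
#' @param mu reference weight for the one-sample tests.
#' @return a `weight_comparison` list; see [tidy.weight_comparison()].
#' @export
compare_weights <- function(direct_w, intermediate_w, mu = 0.5) {
  direct_w <- direct_w[!is.na(direct_w)]
  intermediate_w <- intermediate_w[!is.na(intermediate_w)]
  if (length(direct_w) == 0 || length(intermediate_w) == 0) {
    abort("both weight distributions must be nonempty.", class = "reachbias_insufficient_data")
  }
  if (length(direct_w) != length(intermediate_w)) {
    abort("paired comparison requires equal-length distributions.",
      class = "reachbias_insufficient_data"
    )
  }
  one_sample <- function(x) {
    if (sd(x) == 0) {
      list(statistic = NA_real_, df = length(x) - 1, p.value = NA_real_, degenerate = TRUE)
    } else {
      tt <- t.test(x, mu = mu)
      list(
        statistic = unname(tt$statistic), df = unname(tt$parameter),
        p.value = tt$p.value, degenerate = FALSE
      )
    }
  }
  d <- direct_w - intermediate_w
  paired <- if (sd(d) == 0) {
    list(
      statistic = if (all(d == 0)) 0 else NA_real_,
      df = length(d) - 1, p.value = if (all(d == 0)) 1 else NA_real_,
      degenerate = TRUE
    )
  } else {
    tt <- t.test(direct_w, intermediate_w, paired = TRUE)
    list(
      statistic = unname(tt$statistic), df = unname(tt$parameter),
      p.value = tt$p.value, degenerate = FALSE
    )
  }
  ks <- suppressWarnings(ks.test(direct_w, intermediate_w))
  structure(
    list(
      direct = c(mean = mean(direct_w), sd = sd(direct_w), n = length(direct_w)),
      intermediate = c(
        mean = mean(intermediate_w), sd = sd(intermediate_w),
        n = length(intermediate_w)
      ),
      diff = c(mean = mean(d), sd = sd(d)),
      t_direct_vs_mu = one_sample(direct_w),
      t_intermediate_vs_mu = one_sample(intermediate_w),
      t_paired = paired,
      ks = list(statistic = unname(ks$statistic), p.value = ks$p.value),
      mu = mu
    ),
    class = "weight_comparison"
  )
}

#' @export
print.weight_comparison <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<weight_comparison>\n",
      "  direct:       w_f = %.3f +/- %.3f (n = %d)\n",
      "  intermediate: w_f = %.3f +/- %.3f (n = %d)\n",
      "  paired t = %.2f (df = %d, p = %.3g); KS D = %.3f (p = %.3g)\n"
    ),
    x$direct["mean"], x$direct["sd"], x$direct["n"],
    x$intermediate["mean"], x$intermediate["sd"], x$intermediate["n"],
    x$t_paired$statistic, x$t_paired$df, x$t_paired$p.value,
    x$ks$statistic, x$ks$p.value
  ))
  invisible(x)
}

#' Tidy a weight comparison
#'
#' @param x a `weight_comparison`.
#' @param ... unused.
#' @return tibble with one row per test (`direct_vs_mu`,
#'   `intermediate_vs_mu`, `paired`, `ks`).
#' @export
tidy.weight_comparison <- function(x, ...) {
  tibble::tibble(
    test = c("direct_vs_mu", "intermediate_vs_mu", "paired", "ks"),
    statistic = c(
      x$t_direct_vs_mu$statistic, x$t_intermediate_vs_mu$statistic,
      x$t_paired$statistic, x$ks$statistic
    ),
    df = c(x$t_direct_vs_mu$df, x$t_intermediate_vs_mu$df, x$t_paired$df, NA),
    p.value = c(
      x$t_direct_vs_mu$p.value, x$t_intermediate_vs_mu$p.value,
      x$t_paired$p.value, x$ks$p.value
    )
  )
}

#' @export
glance.weight_comparison <- function(x, ...) {
  tibble::tibble(
    mean_direct = unname(x$direct["mean"]), sd_direct = unname(x$direct["sd"]),
    mean_intermediate = unname(x$intermediate["mean"]),
    sd_intermediate = unname(x$intermediate["sd"]),
    mean_diff = unname(x$diff["mean"]), sd_diff = unname(x$diff["sd"])
  )
}
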