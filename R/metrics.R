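# Individual-difference metrics (explicit-choice experiment) and the
# error-effect linear models.

#' Per-participant strategy and error metrics
#'
#' For each participant: the fraction of intermediate reaches per condition
#' averaged over conditions; the near-to-far reward sensitivity — the OLS
#' slope of the per-condition difference (intermediate minus direct
#' proportion) on the near-to-far reward ratio; and choice / motor error
#' fractions separately per strategy. A participant seen at a single
#' near-to-far ratio gets `NA` sensitivity and is flagged.
#'
#' @param classified output of [classify_trials()] for an experiment-3
#'   session (needs a `near_far_ratio` column).
#' @return tibble, one row per participant: `prop_intermediate`,
#'   `near_far_sensitivity`, `sensitivity_defined`, `choice_err_direct`,
#'   `choice_err_intermediate`, `motor_err_direct`,
#'   `motor_err_intermediate`, `choice_err_diff`, `motor_err_diff`
#'   (intermediate minus direct).
#' @export
individual_metrics <- function(classified) {
  check_columns(classified, c("near_far_ratio", "strategy", "outcome", "keep"), "classified trials")
  kept <- dplyr::filter(classified, .data$keep)

  per_cond <- kept |>
    dplyr::group_by(
      .data$participant_id, .data$reward_ratio, .data$likelihood_ratio,
      .data$near_far_ratio
    ) |>
    dplyr::summarise(p_int = mean(.data$strategy == "intermediate"), .groups = "drop")

  sens <- per_cond |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      prop_intermediate = mean(.data$p_int),
      sensitivity_defined = dplyr::n_distinct(.data$near_far_ratio) >= 2,
      near_far_sensitivity = if (dplyr::n_distinct(.data$near_far_ratio) >= 2) {
        unname(coef(lm((2 * .data$p_int - 1) ~ .data$near_far_ratio))[2])
      } else {
        NA_real_
      },
      .groups = "drop"
    )

  err_frac <- function(outcome, which) mean(outcome == which)
  errs <- kept |>
    dplyr::group_by(.data$participant_id, .data$strategy) |>
    dplyr::summarise(
      choice_err = err_frac(.data$outcome, "choice_error"),
      motor_err = err_frac(.data$outcome, "motor_error"),
      .groups = "drop"
    ) |>
    tidyr::pivot_wider(
      names_from = "strategy", values_from = c("choice_err", "motor_err")
    )
  for (col in c(
    "choice_err_direct", "choice_err_intermediate",
    "motor_err_direct", "motor_err_intermediate"
  )) {
    if (!col %in% names(errs)) errs[[col]] <- NA_real_
  }

  dplyr::left_join(sens, errs, by = "participant_id") |>
    dplyr::mutate(
      choice_err_diff = .data$choice_err_intermediate - .data$choice_err_direct,
      motor_err_diff = .data$motor_err_intermediate - .data$motor_err_direct
    )
}

#' Correlate behavioral metrics with risk attitude
#'
#' Pearson and Spearman correlations of the intermediate-reach proportion and
#' the near-to-far sensitivity with the risk indifference point, computed
#' both with the full cohort and with flagged risk outliers removed.
#'
#' @param metrics output of [individual_metrics()] joined with a
#'   `indifference_point_cents` column and a logical `risk_outlier` column
#'   (see [flag_risk_outliers()]; absent columns are treated as no
#'   outliers).
#' @return tibble: `metric`, `method`, `outliers_excluded`, `estimate`,
#'   `p.value`, `n`.
#' @export
correlate_risk_behavior <- function(metrics) {
  check_columns(metrics, "indifference_point_cents", "metrics")
  if (!"risk_outlier" %in% names(metrics)) metrics$risk_outlier <- FALSE
  run <- function(df, metric, method, excluded) {
    x <- df[[metric]]
    y <- df$indifference_point_cents
    keep <- complete.cases(x, y)
    x <- x[keep]
    y <- y[keep]
    if (length(x) < 4) {
      abort("need at least 4 participants for correlations.",
        class = "reachbias_insufficient_data"
      )
    }
    if (sd(x) == 0 || sd(y) == 0) {
      abort(sprintf("zero variance in %s.", if (sd(x) == 0) metric else "risk attitude"),
        class = "reachbias_degenerate_fit"
      )
    }
    ct <- suppressWarnings(cor.test(x, y, method = method))
    tibble::tibble(
      metric = metric, method = method, outliers_excluded = excluded,
      estimate = unname(ct$estimate), p.value = ct$p.value, n = length(x)
    )
  }
  sets <- list(all = metrics, trimmed = dplyr::filter(metrics, !.data$risk_outlier))
  out <- list()
  for (nm in names(sets)) {
    for (metric in c("prop_intermediate", "near_far_sensitivity")) {
      for (method in c("pearson", "spearman")) {
        out[[length(out) + 1]] <- run(sets[[nm]], metric, method, nm == "trimmed")
      }
    }
  }
  dplyr::bind_rows(out)
}

#' Error-effect linear models
#'
#' Fits (i) the intermediate-reach proportion on the choice-error difference,
#' the motor-error difference (each intermediate minus direct), risk
#' attitude, and the error-by-risk interactions; and (ii) each strategy's
#' frequency weight on the two error differences and their interaction.
#' Coefficients, standard errors, t statistics and p values are returned
#' tidily. A rank-deficient design raises an error naming the collinear
#' terms.
#'
#' @param metrics output of [individual_metrics()] with
#'   `indifference_point_cents` and, for the weight models, `w_f_direct` /
#'   `w_f_intermediate` columns.
#' @return tibble: `model`, `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`, `df.residual`.
#' @export
error_effect_models <- function(metrics) {
  fit_one <- function(formula, data, label) {
    mf <- stats::model.frame(formula, data = data, na.action = stats::na.omit)
    mm <- stats::model.matrix(formula, mf)
    qr_ <- qr(mm)
    if (qr_$rank < ncol(mm)) {
      bad <- colnames(mm)[qr_$pivot[(qr_$rank + 1):ncol(mm)]]
      abort(
        sprintf("rank-deficient design in %s: collinear term(s) %s", label, paste(bad, collapse = ", ")),
        class = "reachbias_collinear"
      )
    }
    fit <- lm(formula, data = data)
    cf <- summary(fit)$coefficients
    tibble::tibble(
      model = label, term = rownames(cf),
      estimate = unname(cf[, 1]), std.error = unname(cf[, 2]),
      statistic = unname(cf[, 3]), p.value = unname(cf[, 4]),
      df.residual = fit$df.residual
    )
  }
  out <- list(fit_one(
    prop_intermediate ~ choice_err_diff * indifference_point_cents +
      motor_err_diff * indifference_point_cents,
    metrics, "prop_intermediate"
  ))
  for (wcol in c("w_f_direct", "w_f_intermediate")) {
    if (wcol %in% names(metrics)) {
      f <- stats::reformulate("choice_err_diff * motor_err_diff", response = wcol)
      out[[length(out) + 1]] <- fit_one(f, metrics, wcol)
    }
  }
  dplyr::bind_rows(out)
}
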