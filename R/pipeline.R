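# End-to-end orchestration: kinematics -> classification -> bias fitting ->
# weight estimation -> subjective value (plus utility and individual metrics
# for the explicit-choice experiment).

#' Run the full analysis pipeline on a session
#'
#' For the pooled-group experiments (1 and 2): kinematic summaries and
#' exclusions, temporal classification, participant-level bootstrap of the
#' per-condition Gaussian biases, per-iteration weight estimation for both
#' strategies, the paired weight comparison, and the subjective-value
#' exponent fits. For the explicit-choice experiment (3): geometric
#' classification, per-participant count-based biases and weights, the
#' across-participant weight comparison, individual-difference metrics, and
#' (when utility choices are supplied) risk profiles, risk-behavior
#' correlations and the error-effect models.
#'
#' @param session a `reach_session` (see [read_session()] /
#'   [simulate_session()]).
#' @param n_iter bootstrap iterations (experiments 1-2).
#' @param frac participant subsample fraction per iteration.
#' @param seed integer seed for the bootstrap.
#' @param min_trials minimum pooled trials per Gaussian fit.
#' @param utility_choices optional tibble of utility-assay choices with
#'   `participant_id`, `reward_diff`, `choice` (experiment 3).
#' @return a `reach_report`: a named list of result tibbles plus metadata;
#'   see [tidy.reach_report()] and [write_results()].
#' @export
run_pipeline <- function(session, n_iter = 1000, frac = 0.75, seed = 1,
                         min_trials = 10, utility_choices = NULL) {
  if (nrow(session$trials) == 0) {
    abort("session has no trials.", class = "reachbias_pipeline_error")
  }
  cfg <- session$config
  log_stage("classify", "classifying %d trials", nrow(session$trials))
  classified <- classify_trials(session)

  exclusions <- classified |>
    dplyr::count(.data$drop_reason) |>
    dplyr::mutate(drop_reason = ifelse(is.na(.data$drop_reason), "kept", .data$drop_reason))

  report <- list(
    experiment_id = cfg$experiment_id,
    seed = seed,
    n_trials_in = nrow(classified),
    n_trials_kept = sum(classified$keep),
    exclusions = exclusions,
    classified = classified
  )

  if (cfg$experiment_id %in% 1:2) {
    log_stage("bootstrap", "running %d bootstrap iterations", n_iter)
    boots <- bootstrap_biases(classified, cfg,
      n_iter = n_iter, frac = frac,
      seed = seed, min_trials = min_trials
    )
    wd <- estimate_weights(boots, "d_choice")
    wi <- estimate_weights(boots, "i_bias")
    shared <- intersect(wd$iteration[wd$ok], wi$iteration[wi$ok])
    cmp <- compare_weights(
      wd$w_f[match(shared, wd$iteration)],
      wi$w_f[match(shared, wi$iteration)]
    )
    sep <- abs(diff(range(cfg$target_angles_deg)))
    report <- c(report, list(
      bias_bootstrap = boots,
      weights_direct = wd,
      weights_intermediate = wi,
      weight_comparison = cmp,
      alpha_direct = fit_alpha(boots, "d_choice", separation_deg = sep),
      alpha_intermediate = fit_alpha(boots, "i_bias", separation_deg = sep)
    ))
  } else {
    biases <- participant_biases(classified)
    wd <- estimate_weights(biases, "d_choice")
    wi <- estimate_weights(biases, "i_bias")
    shared <- intersect(wd$participant_id[wd$ok], wi$participant_id[wi$ok])
    cmp <- if (length(shared) >= 2) {
      compare_weights(
        wd$w_f[match(shared, wd$participant_id)],
        wi$w_f[match(shared, wi$participant_id)]
      )
    } else {
      NULL
    }
    metrics <- individual_metrics(classified) |>
      dplyr::left_join(
        dplyr::select(wd, "participant_id", w_f_direct = "w_f"),
        by = "participant_id"
      ) |>
      dplyr::left_join(
        dplyr::select(wi, "participant_id", w_f_intermediate = "w_f"),
        by = "participant_id"
      )
    report <- c(report, list(
      participant_biases = biases,
      weights_direct = wd,
      weights_intermediate = wi,
      weight_comparison = cmp,
      individual_metrics = metrics
    ))
    if (!is.null(utility_choices)) {
      profiles <- utility_choices |>
        dplyr::group_by(.data$participant_id) |>
        dplyr::group_modify(function(df, key) tidy(fit_indifference(df))) |>
        dplyr::ungroup() |>
        flag_risk_outliers()
      metrics <- dplyr::left_join(metrics, profiles, by = "participant_id")
      report$risk_profiles <- profiles
      report$individual_metrics <- metrics
      report$risk_correlations <- correlate_risk_behavior(metrics)
      report$error_models <- tryCatch(
        error_effect_models(metrics),
        error = function(e) NULL
      )
    }
  }
  structure(report, class = "reach_report")
}

#' @export
print.reach_report <- function(x, ...) {
  cat(sprintf(
    "<reach_report> experiment %d: %d/%d trials kept\n",
    x$experiment_id, x$n_trials_kept, x$n_trials_in
  ))
  if (!is.null(x$weight_comparison)) print(x$weight_comparison)
  invisible(x)
}

#' Tidy summaries of a pipeline report
#'
#' @param x a `reach_report`.
#' @param ... unused.
#' @return a tibble of the headline estimates: mean and SD of the frequency
#'   weight per strategy, plus the subjective-value exponents where fitted.
#' @export
tidy.reach_report <- function(x, ...) {
  rows <- list()
  for (strat in c("direct", "intermediate")) {
    w <- x[[paste0("weights_", strat)]]
    a <- x[[paste0("alpha_", strat)]]
    rows[[strat]] <- tibble::tibble(
      strategy = strat,
      w_f_mean = mean(w$w_f[w$ok], na.rm = TRUE),
      w_f_sd = sd(w$w_f[w$ok], na.rm = TRUE),
      n = sum(w$ok),
      alpha_mean = if (!is.null(a)) mean(a$alpha[a$ok], na.rm = TRUE) else NA_real_
    )
  }
  dplyr::bind_rows(rows)
}

#' @export
glance.reach_report <- function(x, ...) {
  tibble::tibble(
    experiment_id = x$experiment_id,
    n_trials_in = x$n_trials_in,
    n_trials_kept = x$n_trials_kept,
    n_bootstrap_valid = if (!is.null(x$bias_bootstrap)) x$bias_bootstrap$n_valid else NA_integer_,
    seed = x$seed
  )
}

#' Serialize a pipeline report to JSON
#'
#' Flattens the report's tibbles and test objects into the schema-versioned
#' JSON layout of [write_results()].
#'
#' @param report a `reach_report`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_report <- function(report, path) {
  ser <- list(
    experiment_id = report$experiment_id,
    seed = report$seed,
    n_trials_in = report$n_trials_in,
    n_trials_kept = report$n_trials_kept,
    exclusions = report$exclusions,
    weight_summary = tidy(report),
    weights_direct = report$weights_direct,
    weights_intermediate = report$weights_intermediate
  )
  if (!is.null(report$weight_comparison)) {
    ser$weight_comparison <- tidy(report$weight_comparison)
  }
  if (!is.null(report$bias_bootstrap)) {
    ser$bootstrap <- glance(report$bias_bootstrap)
    ser$bias_draws <- report$bias_bootstrap$draws
  }
  if (!is.null(report$individual_metrics)) ser$individual_metrics <- report$individual_metrics
  if (!is.null(report$risk_correlations)) ser$risk_correlations <- report$risk_correlations
  if (!is.null(report$error_models)) ser$error_models <- report$error_models
  write_results(ser, path)
}
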