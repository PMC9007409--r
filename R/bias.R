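# Per-condition bias estimation: bimodal / unimodal Gaussian fits to aligned
# initial reach directions, with a participant-level bootstrap.
#
# Direct reaches form a bimodal distribution over the two target directions;
# the mixing proportion of the rewarded-side component is the choice bias
# D_choice. Intermediate reaches form a unimodal distribution whose mean is
# the initial-direction bias I_bias.

#' Two-component Gaussian mixture fit to direct-reach directions
#'
#' Expectation-maximization for a 1-D two-component Gaussian mixture.
#' Initialization places the component means at the two aligned target
#' directions with equal proportions and 10 deg SDs; if that fit is invalid,
#' up to `restarts` jittered restarts are tried and the best valid
#' log-likelihood kept. A fit is invalid when the components collapse
#' (means closer than 5 deg) or a mixing proportion falls below 0.02.
#'
#' @param angles aligned initial directions (degrees) of direct reaches.
#' @param target_angles_deg the two aligned target directions used to seed
#'   the means.
#' @param min_n minimum number of angles (insufficient data errors mirror
#'   the bootstrap's dropped-iteration rule).
#' @param tol convergence tolerance on the log-likelihood.
#' @param max_iter maximum EM iterations.
#' @param restarts maximum jittered restarts after an invalid first fit.
#' @return a `bimodal_fit`: means, SDs and proportions (ordered negative
#'   side first), `d_choice` (rewarded-side proportion), `mode_ratio`
#'   (rewarded over frequent-side proportion), `loglik`, `valid`, `n`.
#' @export
fit_direct <- function(angles, target_angles_deg = c(-22.5, 22.5), min_n = 10,
                       tol = 1e-6, max_iter = 500, restarts = 19) {
  angles <- angles[!is.na(angles)]
  if (length(angles) < min_n) {
    abort(sprintf("need at least %d direct angles (got %d).", min_n, length(angles)),
      class = "reachbias_insufficient_data"
    )
  }
  init <- list(mu = sort(target_angles_deg), sd = c(10, 10), prop = c(0.5, 0.5))
  fit <- em_gmm2(angles, init, tol, max_iter)
  tries <- 0
  best <- fit
  while (!fit$valid && tries < restarts) {
    tries <- tries + 1
    jit <- list(
      mu = sort(target_angles_deg + rnorm(2, 0, 5)),
      sd = pmax(rnorm(2, 10, 3), 2),
      prop = c(0.5, 0.5)
    )
    fit <- em_gmm2(angles, jit, tol, max_iter)
    if (fit$valid && (!best$valid || fit$loglik > best$loglik)) best <- fit
  }
  if (fit$valid && (!best$valid || fit$loglik > best$loglik)) best <- fit
  fit <- best

  pos <- which.max(fit$mu)
  structure(
    list(
      means = fit$mu, sds = fit$sd, props = fit$prop,
      d_choice = fit$prop[pos],
      mode_ratio = fit$prop[pos] / fit$prop[3 - pos],
      loglik = fit$loglik, n = length(angles), valid = fit$valid,
      iterations = fit$iter
    ),
    class = "bimodal_fit"
  )
}

# Tight 1-D 2-component EM; returns parameters ordered by mean.
em_gmm2 <- function(x, init, tol = 1e-6, max_iter = 500, sd_floor = 0.25) {
  mu <- init$mu
  sd <- pmax(init$sd, sd_floor)
  prop <- init$prop
  n <- length(x)
  ll_old <- -Inf
  iter <- 0
  repeat {
    iter <- iter + 1
    d1 <- prop[1] * dnorm(x, mu[1], sd[1])
    d2 <- prop[2] * dnorm(x, mu[2], sd[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    ll <- sum(log(tot))
    r <- d1 / tot
    if (abs(ll - ll_old) < tol || iter >= max_iter) break
    ll_old <- ll
    n1 <- sum(r)
    n2 <- n - n1
    if (n1 < 1e-8 || n2 < 1e-8) break
    mu <- c(sum(r * x) / n1, sum((1 - r) * x) / n2)
    sd <- pmax(
      c(
        sqrt(sum(r * (x - mu[1])^2) / n1),
        sqrt(sum((1 - r) * (x - mu[2])^2) / n2)
      ),
      sd_floor
    )
    prop <- c(n1, n2) / n
  }
  ord <- order(mu)
  mu <- mu[ord]
  sd <- sd[ord]
  prop <- prop[ord]
  valid <- is.finite(ll) && abs(diff(mu)) >= 5 && min(prop) >= 0.02
  list(mu = mu, sd = sd, prop = prop, loglik = ll, iter = iter, valid = valid)
}

#' Single-Gaussian fit to intermediate-reach directions
#'
#' Maximum-likelihood Gaussian: the mean is the intermediate initial-direction
#' bias I_bias; the SD uses the unbiased estimator.
#'
#' @param angles aligned initial directions (degrees) of intermediate reaches.
#' @param min_n minimum number of angles.
#' @return a `unimodal_fit`: `i_bias` (mean, degrees), `sd`, `n`, `valid`.
#' @export
fit_intermediate <- function(angles, min_n = 10) {
  angles <- angles[!is.na(angles)]
  if (length(angles) < min_n) {
    abort(sprintf("need at least %d intermediate angles (got %d).", min_n, length(angles)),
      class = "reachbias_insufficient_data"
    )
  }
  s <- sd(angles)
  structure(
    list(i_bias = mean(angles), sd = s, n = length(angles), valid = is.finite(s) && s > 0),
    class = "unimodal_fit"
  )
}

#' @export
print.bimodal_fit <- function(x, ...) {
  cat(sprintf(
    "<bimodal_fit> means %.2f/%.2f deg, sds %.2f/%.2f, props %.3f/%.3f, D_choice = %.3f (n = %d%s)\n",
    x$means[1], x$means[2], x$sds[1], x$sds[2], x$props[1], x$props[2],
    x$d_choice, x$n, if (x$valid) "" else ", INVALID"
  ))
  invisible(x)
}

#' @export
print.unimodal_fit <- function(x, ...) {
  cat(sprintf("<unimodal_fit> I_bias = %.3f deg, sd = %.3f (n = %d)\n", x$i_bias, x$sd, x$n))
  invisible(x)
}

#' @export
tidy.bimodal_fit <- function(x, ...) {
  tibble::tibble(
    component = c("frequent_side", "rewarded_side"),
    mean = x$means, sd = x$sds, proportion = x$props
  )
}

#' @export
glance.bimodal_fit <- function(x, ...) {
  tibble::tibble(
    d_choice = x$d_choice, mode_ratio = x$mode_ratio,
    loglik = x$loglik, n = x$n, valid = x$valid
  )
}

#' @export
tidy.unimodal_fit <- function(x, ...) {
  tibble::tibble(i_bias = x$i_bias, sd = x$sd, n = x$n)
}

#' Participant-level bootstrap of per-condition biases
#'
#' Per iteration, a random 75% subset of participants is drawn (without
#' replacement by default; a literal reading of resampling a "subset"), their
#' aligned initial directions are pooled per condition, and the bimodal and
#' unimodal Gaussians are fit. Iterations in which any condition has too few
#' trials or an invalid mixture fit are dropped and counted.
#'
#' @param classified output of [classify_trials()] (kept trials are selected
#'   internally).
#' @param config a [experiment_config()].
#' @param n_iter bootstrap iterations requested.
#' @param frac fraction of participants per iteration.
#' @param seed integer seed; fixed seed gives identical draws and fits.
#' @param replace sample participants with replacement instead.
#' @param min_trials minimum pooled trials per fit.
#' @return a `bias_bootstrap`: `draws` tibble (`iteration`, `reward_ratio`,
#'   `likelihood_ratio`, `d_choice`, `mode_ratio`, `i_bias`, counts),
#'   `n_requested`, `n_valid`, and the participant subsample per iteration.
#' @export
bootstrap_biases <- function(classified, config, n_iter = 1000, frac = 0.75,
                             seed = 1, replace = FALSE, min_trials = 10) {
  data <- dplyr::filter(classified, .data$keep)
  participants <- sort(unique(data$participant_id))
  p_total <- length(participants)
  if (p_total < 4) {
    abort("bootstrap requires at least 4 participants.", class = "reachbias_insufficient_data")
  }
  n_sub <- ceiling(frac * p_total)
  aligned_targets <- sort(c(-1, 1) * max(abs(config$target_angles_deg)))

  # pre-split angles by participant x condition x strategy
  pool <- data |>
    dplyr::mutate(angle = .data$aligned_initial_direction_deg) |>
    dplyr::group_by(
      .data$participant_id, .data$reward_ratio, .data$likelihood_ratio, .data$strategy
    ) |>
    dplyr::summarise(angles = list(.data$angle), .groups = "drop")
  conditions <- dplyr::distinct(data, .data$reward_ratio, .data$likelihood_ratio) |>
    dplyr::arrange(.data$reward_ratio, .data$likelihood_ratio)

  cell <- function(pid, r, f, strat) {
    hit <- pool$participant_id %in% pid & pool$reward_ratio == r &
      pool$likelihood_ratio == f & pool$strategy == strat
    unlist(pool$angles[hit], use.names = FALSE)
  }

  with_seed(seed, {
    draws <- vector("list", n_iter)
    subsamples <- vector("list", n_iter)
    n_invalid <- 0
    for (it in seq_len(n_iter)) {
      sub <- sample(participants, n_sub, replace = replace)
      subsamples[[it]] <- sub
      rows <- vector("list", nrow(conditions))
      ok <- TRUE
      for (ci in seq_len(nrow(conditions))) {
        r <- conditions$reward_ratio[ci]
        f <- conditions$likelihood_ratio[ci]
        ang_d <- cell(sub, r, f, "direct")
        ang_i <- cell(sub, r, f, "intermediate")
        fit_d <- tryCatch(
          fit_direct(ang_d, aligned_targets, min_n = min_trials),
          reachbias_insufficient_data = function(e) NULL
        )
        fit_i <- tryCatch(
          fit_intermediate(ang_i, min_n = min_trials),
          reachbias_insufficient_data = function(e) NULL
        )
        if (is.null(fit_d) || is.null(fit_i) || !fit_d$valid || !fit_i$valid) {
          ok <- FALSE
          break
        }
        rows[[ci]] <- tibble::tibble(
          iteration = it, reward_ratio = r, likelihood_ratio = f,
          d_choice = fit_d$d_choice, mode_ratio = fit_d$mode_ratio,
          i_bias = fit_i$i_bias,
          n_direct = length(ang_d), n_intermediate = length(ang_i)
        )
      }
      if (ok) {
        draws[[it]] <- dplyr::bind_rows(rows)
      } else {
        n_invalid <- n_invalid + 1
      }
    }
    draws <- dplyr::bind_rows(draws)
    if (nrow(draws) == 0) {
      abort("all bootstrap iterations were invalid.", class = "reachbias_pipeline_error")
    }
    structure(
      list(
        draws = draws,
        n_requested = n_iter, n_valid = n_iter - n_invalid,
        frac = frac, replace = replace,
        subsamples = subsamples
      ),
      class = "bias_bootstrap"
    )
  })
}

#' @export
print.bias_bootstrap <- function(x, ...) {
  cat(sprintf(
    "<bias_bootstrap> %d/%d valid iterations, %d conditions\n",
    x$n_valid, x$n_requested,
    nrow(dplyr::distinct(x$draws, .data$reward_ratio, .data$likelihood_ratio))
  ))
  invisible(x)
}

#' @export
tidy.bias_bootstrap <- function(x, ...) x$draws

#' @export
glance.bias_bootstrap <- function(x, ...) {
  tibble::tibble(
    n_requested = x$n_requested, n_valid = x$n_valid,
    frac = x$frac, replace = x$replace
  )
}

#' Per-participant biases for the five-target experiment
#'
#' The explicit-choice layout needs no mixture fitting: per participant and
#' condition, D_choice is the proportion of direct reaches aimed at the
#' more-rewarded side (aligned direction positive) and I_bias is the mean
#' aligned intermediate direction. Conditions pool over the near/far reward
#' factor, which does not enter the bias definitions.
#'
#' @param classified output of [classify_trials()] for an experiment-3
#'   session.
#' @param min_trials minimum reaches per cell; cells below it return `NA`.
#' @return tibble `participant_id`, `reward_ratio`, `likelihood_ratio`,
#'   `d_choice`, `i_bias`, counts.
#' @export
participant_biases <- function(classified, min_trials = 3) {
  dplyr::filter(classified, .data$keep) |>
    dplyr::group_by(.data$participant_id, .data$reward_ratio, .data$likelihood_ratio) |>
    dplyr::summarise(
      n_direct = sum(.data$strategy == "direct"),
      n_intermediate = sum(.data$strategy == "intermediate"),
      d_choice = ifelse(n_direct >= min_trials,
        mean(.data$aligned_initial_direction_deg[.data$strategy == "direct"] > 0),
        NA_real_
      ),
      i_bias = ifelse(n_intermediate >= min_trials,
        mean(.data$aligned_initial_direction_deg[.data$strategy == "intermediate"]),
        NA_real_
      ),
      .groups = "drop"
    )
}
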