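test_that("angle alignment re-signs toward the rewarded side", {
  df <- tibble::tibble(
    initial_direction_deg = c(-10, 10, -5, 5, 0, 22.5),
    rewarded_side = c("L", "R", "R", "L", "L", "R")
  )
  out <- align_angles(df)
  expect_equal(out$aligned_deg, c(10, 10, -5, -5, 0, 22.5))
  expect_error(align_angles(dplyr::select(df, -"rewarded_side")),
    class = "reachbias_format_error"
  )
  expect_error(
    align_angles(dplyr::mutate(df, rewarded_side = NA)),
    class = "reachbias_format_error"
  )
})

test_that("the bimodal fit recovers generative mixtures", {
  set.seed(11)
  draw_mix <- function(n, p_pos, mu = 22.5, sd = 5) {
    pos <- rbinom(n, 1, p_pos)
    rnorm(n, ifelse(pos == 1, mu, -mu), sd)
  }
  sym <- fit_direct(draw_mix(2000, 0.5))
  expect_true(sym$valid)
  expect_equal(sym$d_choice, 0.5, tolerance = 0.03)
  skew <- fit_direct(draw_mix(2000, 0.7))
  expect_equal(skew$d_choice, 0.7, tolerance = 0.03)
  expect_equal(skew$means, c(-22.5, 22.5), tolerance = 0.5)
  expect_error(fit_direct(rnorm(5)), class = "reachbias_insufficient_data")
})

test_that("EM log-likelihood matches a grid-search oracle on small samples", {
  set.seed(3)
  for (rep in 1:3) {
    x <- c(rnorm(30, 22.5, 4), rnorm(20, -22.5, 4))
    fit <- fit_direct(x)
    grid_ll <- oracle_gmm2_loglik(x)
    expect_equal(fit$loglik, grid_ll, tolerance = 1e-3)
  }
})

test_that("EM matches an independent mixture implementation", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  set.seed(12)
  x <- c(rnorm(300, 22.5, 5), rnorm(200, -22.5, 5))
  fit <- fit_direct(x)
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(fit$means), sort(as.numeric(mc$parameters$mean)), tolerance = 0.2)
  expect_equal(fit$loglik, mc$loglik, tolerance = 0.01)
})

test_that("the unimodal fit estimates the intermediate bias", {
  set.seed(13)
  centred <- fit_intermediate(rnorm(2000, 0, 8))
  expect_equal(centred$i_bias, 0, tolerance = 0.5)
  shifted <- fit_intermediate(rnorm(2000, 4, 8))
  expect_equal(shifted$i_bias, 4, tolerance = 0.5)
  expect_error(fit_intermediate(rnorm(3)), class = "reachbias_insufficient_data")
})

test_that("mirror symmetry maps D_choice to 1 - D_choice and flips I_bias", {
  set.seed(14)
  x <- c(rnorm(400, 22.5, 5), rnorm(100, -22.5, 5))
  a <- fit_direct(x)
  b <- fit_direct(-x)
  expect_equal(a$d_choice, 1 - b$d_choice, tolerance = 1e-6)
  xi <- rnorm(300, 3, 6)
  expect_equal(fit_intermediate(xi)$i_bias, -fit_intermediate(-xi)$i_bias)
})

# shared bias-level cohort builder: draws classified-trial angle tables
# directly from known per-condition biases, skipping the kinematic layer
make_bias_cohort <- function(n_participants = 8, n_per_cell = 60,
                             profile = participant_profile(), seed = 99) {
  set.seed(seed)
  design <- session_design(1, n_trials = n_per_cell)
  rows <- list()
  for (p in seq_len(n_participants)) {
    for (b in seq_len(nrow(design))) {
      blk <- design[b, ]
      bias <- condition_bias(profile, blk$reward_ratio, blk$likelihood_ratio)
      n_dir <- rbinom(1, blk$n_trials, 1 - profile$p_intermediate)
      n_int <- blk$n_trials - n_dir
      pos <- rbinom(n_dir, 1, bias$d_choice_prob)
      rows[[length(rows) + 1]] <- tibble::tibble(
        participant_id = sprintf("P%02d", p),
        reward_ratio = blk$reward_ratio,
        likelihood_ratio = blk$likelihood_ratio,
        strategy = c(rep("direct", n_dir), rep("intermediate", n_int)),
        aligned_initial_direction_deg = c(
          rnorm(n_dir, ifelse(pos == 1, 22.5, -22.5), profile$motor_sd_deg),
          rnorm(n_int, bias$i_bias_deg, profile$motor_sd_deg)
        ),
        keep = TRUE
      )
    }
  }
  dplyr::bind_rows(rows)
}

test_that("the participant bootstrap is deterministic and recovers known biases", {
  cfg <- experiment_config(1)
  prof <- participant_profile()
  cohort <- make_bias_cohort(8, 60, prof)
  b1 <- bootstrap_biases(cohort, cfg, n_iter = 10, seed = 5)
  b2 <- bootstrap_biases(cohort, cfg, n_iter = 10, seed = 5)
  expect_equal(b1$draws, b2$draws)
  expect_equal(b1$n_valid, 10)

  b <- bootstrap_biases(cohort, cfg, n_iter = 30, seed = 6)
  means <- b$draws |>
    dplyr::group_by(reward_ratio, likelihood_ratio) |>
    dplyr::summarise(
      d = mean(d_choice), i = mean(i_bias), .groups = "drop"
    )
  truth <- condition_bias(prof, means$reward_ratio, means$likelihood_ratio)
  # iteration-mean biases track the generative truth across conditions
  # (average error bounded by the cohort's binomial sampling noise)
  expect_lt(mean(abs(means$d - truth$d_choice_prob)), 0.03)
  expect_lt(mean(abs(means$i - truth$i_bias_deg)), 0.3)
  # I_bias stays within the half-separation bound on generated data
  expect_true(all(abs(b$draws$i_bias) < 22.5))

  small <- dplyr::filter(cohort, participant_id %in% c("P01", "P02", "P03"))
  expect_error(bootstrap_biases(small, cfg, n_iter = 5, seed = 1),
    class = "reachbias_insufficient_data"
  )
})
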