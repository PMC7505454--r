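#' Null coverage of the aggregated-validity confidence intervals
#'
#' Monte-Carlo calibration of [predictive_validity()]: generates replicate
#' studies with zero cross-format consistency (`rho = 0`), computes the
#' rate-indicator validity rows for each, and records whether each
#' aggregated 95% confidence interval contains 0. With a calibrated
#' procedure about 95% of intervals should.
#'
#' The fast rate-indicator path (no mixed-model fits inside the loop) keeps
#' a 200-replicate run in the minutes range on one CPU.
#'
#' @param config generator configuration; its `rho` is forced to 0.
#' @param n_reps number of replicate studies.
#' @param min_n minimum complete pairs per team.
#' @return tibble `rep`, `indicator`, `r`, `ci_low`, `ci_high`,
#'   `covers_zero`.
#' @export
null_validity_coverage <- function(config = generator_config(),
                                   n_reps = 200, min_n = 4) {
  config$rho <- 0
  config <- validate_generator_config(unclass(config))
  out <- replicate_studies(config, n_reps, function(study, i) {
    v <- rate_validity(study, min_n)
    v$rep <- i
    v
  })
  if (length(out$errors) > 0) {
    warning("null_validity_coverage(): ", length(out$errors),
            " replicate(s) failed", call. = FALSE)
  }
  res <- dplyr::bind_rows(out$results)
  res$covers_zero <- res$ci_low <= 0 & res$ci_high >= 0
  res
}

#' Rate-indicator validity rows for one study
#'
#' The fast subset of the validity analysis: per-bout rates for the four
#' count indicators in both formats, correlated player-wise within teams
#' and DL-aggregated. No mixed-model fits are involved, which makes this
#' the workhorse of the replicate experiments.
#'
#' @param study an `ssg_study` (events, roster, games).
#' @param min_n minimum complete pairs per team.
#' @return tibble `indicator`, `r`, `ci_low`, `ci_high`, `n`.
#' @export
rate_validity <- function(study, min_n = 4) {
  roster <- study$roster
  roster <- roster[roster$minutes_ssg > 0 & roster$minutes_m11 > 0, ,
                   drop = FALSE]
  ssg <- events_per_bout(study$events, roster, "SSG") |>
    dplyr::select("player_id", "indicator", score = "rate")
  m11 <- events_per_bout(study$events, roster, "M11") |>
    dplyr::select("player_id", "indicator", score = "rate")
  suppressWarnings(predictive_validity(ssg, m11, roster, min_n = min_n)) |>
    dplyr::select(indicator = "predictor", "r", "ci_low", "ci_high", "n")
}

#' Recovery of the generator's target cross-format validity
#'
#' Under a high-consistency, low-noise configuration (large event rates so
#' Poisson noise is negligible relative to the latent ability spread), the
#' aggregated rate-indicator validity coefficient should recover the
#' generator's target: for a Gaussian ability copula with correlation
#' `rho`, the population Spearman correlation is (6/pi) asin(rho/2).
#'
#' @param config generator configuration; defaults to the low-noise
#'   setting `rho = 0.9`, `rate_scale = 25`, `rate_effect_sd = 1`,
#'   `team_strength_sd = 0` (game-to-game strength wobble is a noise source
#'   for player-level validity, so the low-noise condition switches it
#'   off).
#' @param n_reps number of replicate studies.
#' @param min_n minimum complete pairs per team.
#' @return list with `target` (population Spearman), `mean_r` (mean
#'   aggregated coefficient over replicates and rate indicators) and
#'   `per_indicator` (tibble of per-indicator means).
#' @export
validity_recovery <- function(config = generator_config(rho = 0.9,
                                                        rate_scale = 25,
                                                        rate_effect_sd = 1,
                                                        team_strength_sd = 0),
                              n_reps = 30, min_n = 4) {
  out <- replicate_studies(config, n_reps, function(study, i) {
    v <- rate_validity(study, min_n)
    v$rep <- i
    v
  })
  if (length(out$errors) > 0) {
    warning("validity_recovery(): ", length(out$errors),
            " replicate(s) failed", call. = FALSE)
  }
  res <- dplyr::bind_rows(out$results)
  per_ind <- res |>
    dplyr::group_by(.data$indicator) |>
    dplyr::summarise(mean_r = mean(.data$r), .groups = "drop")
  list(target = spearman_from_pearson(config$rho),
       mean_r = mean(res$r), per_indicator = per_ind)
}

#' Population Spearman correlation of a bivariate Gaussian
#'
#' For a bivariate normal with Pearson correlation `rho`, the population
#' Spearman rank correlation is (6/pi) asin(rho/2).
#'
#' @param rho Pearson correlation.
#' @return population Spearman coefficient.
#' @export
spearman_from_pearson <- function(rho) (6 / pi) * asin(rho / 2)

#' Parameter recovery for the random-intercept logistic model
#'
#' Simulates one binary indicator at a chosen design
#' ([simulate_binary_indicator()]), fits the model, and reports the
#' recovered random-intercept SD and the Spearman correlation between the
#' empirical-Bayes player modes and the true latent effects.
#'
#' @param n_players,n_trials design size.
#' @param beta0,team_effects,sigma_u generating parameters.
#' @param seed RNG seed.
#' @param n_agq quadrature setting for the fit.
#' @return list `sigma_u_true`, `sigma_u_hat`, `rank_cor`, `fit`.
#' @export
success_model_recovery <- function(n_players = 60, n_trials = 50,
                                   beta0 = 0,
                                   team_effects = c(U15 = 0, U17 = 0.3,
                                                    U19 = -0.3, U23 = 0.5),
                                   sigma_u = 1, seed = 1, n_agq = 1) {
  sim <- simulate_binary_indicator(
    n_players, teams = names(team_effects), beta0 = beta0,
    team_effects = team_effects, sigma_u = sigma_u, n_trials = n_trials,
    seed = seed
  )
  fit <- fit_success_model(sim$events, sim$roster, n_agq = n_agq)
  list(
    sigma_u_true = sigma_u,
    sigma_u_hat = fit$sigma_u,
    rank_cor = stats::cor(fit$u[names(sim$u_true)], sim$u_true,
                          method = "spearman"),
    fit = fit
  )
}
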