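#' Configuration for the synthetic study generator
#'
#' Builds the full parameter set for [generate_study()]. Defaults emulate
#' the design of the original study: four age-category teams (17, 15, 16,
#' 15 players), six-minute SSGs with sides re-drawn every game, six
#' 45-minute 11-vs-11 halves per team with only the academy side coded,
#' and per-player per-bout event rates calibrated so that the expected
#' per-format totals echo the published frequency structure (including the
#' suppression of aerial duels in SSGs).
#'
#' Latent structure: each player carries an offensive and a defensive
#' ability per format, linked across formats by a Gaussian copula with
#' correlation `rho` (the single knob controlling true cross-format
#' consistency). Count-indicator rates are modulated by
#' `exp(rate_effect_sd x ability)`; binary-outcome success probabilities by
#' `plogis(beta0 + team_effect + sigma_u x ability)`. Each game side draws
#' an offensive and defensive strength (SD `team_strength_sd`); a side's
#' offensive rates (shots included, which makes shots on target share a
#' common factor with the other offensive indicators) scale with its own
#' offensive strength and are suppressed by `defense_suppression` times the
#' opposing side's defensive strength. All log-normal modulators are
#' mean-corrected, so expected event totals per indicator recover the
#' configured rates.
#'
#' @param seed integer master seed.
#' @param ... overrides for any default component (matched by name).
#' @return list of class `ssg_generator_config`.
#' @export
generator_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    teams = tibble::tibble(
      team = c("U15", "U17", "U19", "U23"),
      n_players = c(17L, 15L, 16L, 15L),
      n_ssg = c(19L, 12L, 20L, 16L),
      n_m11_halves = 6L
    ),
    ssg_duration = 6,
    half_duration = 45,
    ssg_side_size = 7L,
    m11_side_size = 11L,
    rates = default_event_rates(),
    rate_scale = 1,
    rate_effect_sd = 0.4,
    team_strength_sd = 0.3,
    defense_suppression = 0.5,
    rho = 0.6,
    sigma_u = 0.5,
    beta0 = c(pass_forward = 0.85, dribble = 0, take_on = 0, tackle = 0,
              staying_in_front = 0, offensive_aerial_duel = 0,
              defensive_aerial_duel = 0),
    team_effects = c(U15 = 0, U17 = 0.1, U19 = 0.2, U23 = 0.3),
    test_model = tibble::tribble(
      ~test,          ~mean, ~sd,  ~off_loading, ~def_loading,
      "sprint_10m",    1.80, 0.08, -0.20,         0.00,
      "sprint_30m",    4.30, 0.20, -0.20,         0.00,
      "isrt_tracks",  75.0, 12.0,   0.15,        -0.10,
      "agility_mean",  6.00, 0.30, -0.10,         0.10
    ),
    missing_sprint_agility = 0.10,
    missing_isrt = 0.02
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0) {
    stop("generator_config(): unknown option(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg[names(overrides)] <- overrides
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  stopifnot(
    is.numeric(cfg$seed), length(cfg$seed) == 1,
    all(c("team", "n_players", "n_ssg", "n_m11_halves") %in% names(cfg$teams)),
    cfg$rho >= -1, cfg$rho <= 1,
    cfg$sigma_u >= 0, cfg$rate_effect_sd >= 0, cfg$team_strength_sd >= 0,
    all(cfg$rates$rate >= 0), cfg$rate_scale > 0
  )
  load2 <- cfg$test_model$off_loading^2 + cfg$test_model$def_loading^2
  if (any(load2 > 1)) {
    stop("generator_config(): test loadings imply a correlation matrix ",
         "that is not positive semi-definite", call. = FALSE)
  }
  class(cfg) <- c("ssg_generator_config", class(cfg))
  cfg
}

#' Default per-player per-bout event rates
#'
#' Expected events per player per six-minute bout, per raw indicator and
#' format, calibrated from the published per-format totals divided by the
#' nominal coded exposure of the original design (82 SSGs x 14
#' player-bouts; 4 teams x 6 halves x 45 min x 11 players).
#'
#' @return tibble `indicator`, `format`, `rate`.
#' @export
default_event_rates <- function() {
  counts <- readr::read_csv(
    system.file("extdata", "published_event_counts.csv",
                package = "ssgvalidity", mustWork = TRUE),
    show_col_types = FALSE
  )
  ssg_bouts <- 82 * 14          # SSGs x players on the pitch (one bout each)
  m11_bouts <- 4 * 6 * 45 * 11 / 6
  dplyr::bind_rows(
    tibble::tibble(indicator = counts$indicator, format = "SSG",
                   rate = counts$observed_ssg / ssg_bouts),
    tibble::tibble(indicator = counts$indicator, format = "M11",
                   rate = counts$observed_m11 / m11_bouts)
  )
}

# bivariate standard normals with correlation rho
draw_latent_pair <- function(n, rho) {
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  cbind(z1, z2)
}

#' Generate a complete synthetic study
#'
#' Draws a full event-coded study (events, roster, games) from the
#' generative model described in [generator_config()], together with the
#' ground truth of every latent quantity. Regeneration from the same
#' configuration (same seed) is bit-identical.
#'
#' @param config `ssg_generator_config` (default [generator_config()]).
#' @return list of class `ssg_study` with `events`, `roster`, `games` and
#'   `truth` (list: player latents, game-side strengths, configuration
#'   scalars).
#' @export
generate_study <- function(config = generator_config()) {
  stopifnot(inherits(config, "ssg_generator_config"))
  set.seed(config$seed, kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  tax <- indicator_taxonomy(include_merged = FALSE)
  side_of <- stats::setNames(tax$side, tax$indicator)
  otype <- stats::setNames(tax$outcome_type, tax$indicator)

  ## players and latent abilities -------------------------------------------
  roster0 <- config$teams |>
    dplyr::rowwise() |>
    dplyr::mutate(player_id = list(sprintf("%s_%02d", .data$team,
                                           seq_len(.data$n_players)))) |>
    dplyr::ungroup() |>
    tidyr::unnest("player_id") |>
    dplyr::select("player_id", "team")
  n_players <- nrow(roster0)
  off <- draw_latent_pair(n_players, config$rho)
  def <- draw_latent_pair(n_players, config$rho)
  latents <- tibble::tibble(
    player_id = roster0$player_id, team = roster0$team,
    off_ssg = off[, 1], off_m11 = off[, 2],
    def_ssg = def[, 1], def_m11 = def[, 2]
  )

  ## schedule: who plays on which side of which game ------------------------
  participation <- list()
  game_rows <- list()
  for (ti in seq_len(nrow(config$teams))) {
    tm <- config$teams$team[[ti]]
    players <- roster0$player_id[roster0$team == tm]
    # SSGs: sides re-drawn every game
    for (g in seq_len(config$teams$n_ssg[[ti]])) {
      gid <- sprintf("%s_SSG_%02d", tm, g)
      k <- min(2L * config$ssg_side_size, length(players))
      chosen <- sample(players, k)
      half <- ceiling(k / 2)
      sides <- c(rep(paste0(gid, ".1"), half), rep(paste0(gid, ".2"), k - half))
      participation[[gid]] <- tibble::tibble(
        game_id = gid, format = "SSG", team = tm, side_team_id = sides,
        player_id = chosen, bouts = config$ssg_duration / 6
      )
      game_rows[[gid]] <- tibble::tibble(
        game_id = gid, format = "SSG", team = tm,
        side_team_id = paste0(gid, c(".1", ".2")), coded = TRUE
      )
    }
    # 11-vs-11 halves: academy side coded, opponent side proxy-only
    for (h in seq_len(config$teams$n_m11_halves[[ti]])) {
      gid <- sprintf("%s_M11_%d", tm, h)
      chosen <- sample(players, min(config$m11_side_size, length(players)))
      participation[[gid]] <- tibble::tibble(
        game_id = gid, format = "M11", team = tm,
        side_team_id = paste0(gid, ".home"),
        player_id = chosen, bouts = config$half_duration / 6
      )
      game_rows[[gid]] <- tibble::tibble(
        game_id = gid, format = "M11", team = tm,
        side_team_id = paste0(gid, c(".home", ".opp")),
        coded = c(TRUE, FALSE)
      )
    }
  }
  participation <- dplyr::bind_rows(participation)
  game_sides <- dplyr::bind_rows(game_rows)

  ## per-side strengths ------------------------------------------------------
  sg <- config$team_strength_sd
  game_sides$g_off <- stats::rnorm(nrow(game_sides), 0, sg)
  game_sides$g_def <- stats::rnorm(nrow(game_sides), 0, sg)
  opp <- game_sides |>
    dplyr::group_by(.data$game_id) |>
    dplyr::mutate(g_def_opp = rev(.data$g_def)) |>
    dplyr::ungroup()

  ## expected counts and event draws ----------------------------------------
  sr <- config$rate_effect_sd
  kap <- config$defense_suppression
  cells <- tidyr::expand_grid(participation, indicator = tax$indicator) |>
    dplyr::left_join(config$rates, by = c("indicator", "format")) |>
    dplyr::left_join(
      dplyr::select(opp, "game_id", "side_team_id", "g_off", "g_def",
                    "g_def_opp"),
      by = c("game_id", "side_team_id")
    ) |>
    dplyr::left_join(latents, by = c("player_id", "team"))
  is_off <- side_of[cells$indicator] == "offense"
  ability <- ifelse(is_off,
                    ifelse(cells$format == "SSG", cells$off_ssg,
                           cells$off_m11),
                    ifelse(cells$format == "SSG", cells$def_ssg,
                           cells$def_m11))
  # lognormal mean corrections keep E[count] = rate x bouts x rate_scale
  log_mod <- sr * ability - sr^2 / 2 +
    ifelse(is_off,
           cells$g_off - kap * cells$g_def_opp - (1 + kap^2) * sg^2 / 2,
           cells$g_def - sg^2 / 2)
  mu <- cells$rate * config$rate_scale * cells$bouts * exp(log_mod)
  cells$n_events <- stats::rpois(nrow(cells), mu)

  ev_cells <- cells[cells$n_events > 0, , drop = FALSE]
  idx <- rep(seq_len(nrow(ev_cells)), ev_cells$n_events)
  events <- tibble::tibble(
    game_id = ev_cells$game_id[idx],
    format = ev_cells$format[idx],
    team = ev_cells$team[idx],
    side_team_id = ev_cells$side_team_id[idx],
    player_id = ev_cells$player_id[idx],
    indicator = ev_cells$indicator[idx]
  )
  is_binary <- otype[events$indicator] == "binary"
  ability_ev <- ifelse(side_of[events$indicator] == "offense",
                       ifelse(events$format == "SSG",
                              ev_cells$off_ssg[idx], ev_cells$off_m11[idx]),
                       ifelse(events$format == "SSG",
                              ev_cells$def_ssg[idx], ev_cells$def_m11[idx]))
  p_succ <- stats::plogis(
    config$beta0[events$indicator] +
      config$team_effects[events$team] +
      config$sigma_u * ability_ev
  )
  events$outcome <- NA_character_
  if (any(is_binary)) {
    draws <- stats::rbinom(sum(is_binary), 1, p_succ[is_binary])
    events$outcome[is_binary] <- ifelse(draws == 1, "success", "failure")
  }

  ## games table: shots on target per side -----------------------------------
  shot_counts <- events |>
    dplyr::filter(.data$indicator == "shot_on_target") |>
    dplyr::count(.data$game_id, .data$side_team_id, name = "shots")
  games <- opp |>
    dplyr::left_join(shot_counts, by = c("game_id", "side_team_id")) |>
    dplyr::mutate(shots = dplyr::coalesce(.data$shots, 0L))
  # uncoded opponent sides: draw a side-level shot total from the same law
  unc <- which(!games$coded)
  if (length(unc) > 0) {
    lam_shot <- config$rates$rate[config$rates$indicator == "shot_on_target" &
                                    config$rates$format == "M11"]
    mu_opp <- lam_shot * config$rate_scale * (config$half_duration / 6) *
      config$m11_side_size *
      exp(games$g_off[unc] - kap * games$g_def_opp[unc] -
            (1 + kap^2) * sg^2 / 2)
    games$shots[unc] <- stats::rpois(length(unc), mu_opp)
  }
  games <- games |>
    dplyr::transmute(.data$game_id, .data$format, .data$team,
                     .data$side_team_id,
                     shots_on_target = as.integer(.data$shots), .data$coded)

  ## roster: exposure, SSG counts, test scores --------------------------------
  played <- participation |>
    dplyr::group_by(.data$player_id, .data$format) |>
    dplyr::summarise(n_games = dplyr::n(), minutes = sum(.data$bouts) * 6,
                     .groups = "drop") |>
    tidyr::pivot_wider(names_from = "format",
                       values_from = c("n_games", "minutes"),
                       values_fill = 0)
  roster <- roster0 |>
    dplyr::left_join(played, by = "player_id") |>
    dplyr::mutate(
      minutes_ssg = dplyr::coalesce(.data$minutes_SSG, 0),
      minutes_m11 = dplyr::coalesce(.data$minutes_M11, 0),
      n_ssg_played = as.integer(dplyr::coalesce(.data$n_games_SSG, 0))
    )

  tm_model <- config$test_model
  test_vals <- matrix(NA_real_, n_players, nrow(tm_model),
                      dimnames = list(NULL, tm_model$test))
  for (j in seq_len(nrow(tm_model))) {
    lo <- tm_model$off_loading[[j]]; ld <- tm_model$def_loading[[j]]
    zt <- lo * latents$off_m11 + ld * latents$def_m11 +
      sqrt(max(0, 1 - lo^2 - ld^2)) * stats::rnorm(n_players)
    test_vals[, j] <- tm_model$mean[[j]] + tm_model$sd[[j]] * zt
  }
  roster$sprint_10m <- test_vals[, "sprint_10m"]
  roster$sprint_30m <- test_vals[, "sprint_30m"]
  roster$isrt_tracks <- round(test_vals[, "isrt_tracks"])
  agility <- test_vals[, "agility_mean"]
  d <- stats::rnorm(n_players, 0, 0.05)
  roster$agility_left <- agility + d
  roster$agility_right <- agility - d

  miss_sa <- stats::runif(n_players) < config$missing_sprint_agility
  miss_is <- stats::runif(n_players) < config$missing_isrt
  roster$sprint_10m[miss_sa] <- NA_real_
  roster$sprint_30m[miss_sa] <- NA_real_
  roster$agility_left[miss_sa] <- NA_real_
  roster$agility_right[miss_sa] <- NA_real_
  roster$isrt_tracks[miss_is] <- NA_real_
  roster <- roster |>
    dplyr::select("player_id", "team", "minutes_ssg", "minutes_m11",
                  "n_ssg_played", "sprint_10m", "sprint_30m", "isrt_tracks",
                  "agility_left", "agility_right")
  roster$agility_mean <- rowMeans(roster[, c("agility_left", "agility_right")])

  truth <- list(
    seed = config$seed,
    rho = config$rho,
    sigma_u = config$sigma_u,
    rate_effect_sd = config$rate_effect_sd,
    team_strength_sd = config$team_strength_sd,
    defense_suppression = config$defense_suppression,
    rate_scale = config$rate_scale,
    beta0 = as.list(config$beta0),
    team_effects = as.list(config$team_effects),
    players = as.data.frame(latents),
    game_strengths = as.data.frame(
      dplyr::select(opp, "game_id", "side_team_id", "g_off", "g_def")
    )
  )
  structure(list(events = events, roster = roster, games = games,
                 truth = truth),
            class = "ssg_study")
}

#' @export
print.ssg_study <- function(x, ...) {
  cat(sprintf("Synthetic study: %d players, %d games, %d events\n",
              nrow(x$roster), length(unique(x$games$game_id)),
              nrow(x$events)))
  invisible(x)
}

#' Run an analysis over replicated synthetic studies
#'
#' Generates `n_reps` studies with seeds derived deterministically from the
#' master seed and applies `fn(study, rep)` to each. A failure in one
#' replicate is recorded and the others continue.
#'
#' @param config base `ssg_generator_config`.
#' @param n_reps number of replicates (>= 1).
#' @param fn callback taking `(study, rep_index)`.
#' @return list with `results` (per-replicate callback values; `NULL` for
#'   failed replicates), `errors` (named character), `seeds`.
#' @export
replicate_studies <- function(config, n_reps, fn) {
  stopifnot(n_reps >= 1)
  seeds <- (config$seed + seq_len(n_reps) * 100003L) %% 2147483629L
  results <- vector("list", n_reps)
  errors <- character()
  for (i in seq_len(n_reps)) {
    cfg_i <- config
    cfg_i$seed <- as.integer(seeds[[i]])
    results[[i]] <- tryCatch(fn(generate_study(cfg_i), i),
                             error = function(e) {
                               errors[[as.character(i)]] <<-
                                 conditionMessage(e)
                               NULL
                             })
  }
  list(results = results, errors = errors, seeds = seeds)
}

#' Simulate trials for a single binary indicator with known abilities
#'
#' A minimal generator for parameter-recovery experiments on the
#' random-intercept logistic model: players are assigned to teams
#' round-robin, each player's latent effect u_i is drawn from
#' N(0, sigma_u^2), and each of `n_trials` attempts succeeds with
#' probability plogis(beta0 + team_effect + u_i).
#'
#' @param n_players number of players.
#' @param teams character vector of team labels (players assigned
#'   round-robin).
#' @param beta0 fixed intercept (logit).
#' @param team_effects named logit offsets per team (reference 0 included).
#' @param sigma_u player random-intercept SD.
#' @param n_trials trials per player (scalar or per-player vector).
#' @param seed RNG seed.
#' @param indicator,format labels stamped on the events.
#' @return list `events` (event tibble), `roster`, `u_true` (named).
#' @export
simulate_binary_indicator <- function(n_players, teams = "U15",
                                      beta0 = 0,
                                      team_effects = stats::setNames(
                                        rep(0, length(teams)), teams),
                                      sigma_u = 1, n_trials = 50,
                                      seed = 1,
                                      indicator = "pass_forward",
                                      format = "SSG") {
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  player_id <- sprintf("p%03d", seq_len(n_players))
  team <- rep(teams, length.out = n_players)
  u <- stats::rnorm(n_players, 0, sigma_u)
  n_trials <- rep(n_trials, length.out = n_players)
  p <- stats::plogis(beta0 + unname(team_effects[team]) + u)
  succ <- stats::rbinom(n_players, n_trials, p)
  idx <- rep(seq_len(n_players), n_trials)
  out <- unlist(lapply(seq_len(n_players), function(i) {
    c(rep("success", succ[[i]]), rep("failure", n_trials[[i]] - succ[[i]]))
  }))
  list(
    events = tibble::tibble(
      game_id = "sim", format = format, team = team[idx],
      side_team_id = "sim.1", player_id = player_id[idx],
      indicator = indicator, outcome = out
    ),
    roster = tibble::tibble(player_id = player_id, team = team),
    u_true = stats::setNames(u, player_id)
  )
}
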