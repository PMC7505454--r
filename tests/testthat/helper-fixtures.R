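# shared fixture builders and independent oracles

# minimal valid event tibble; defaults give one SSG pass_forward success
make_events <- function(player_id = "p1", indicator = "pass_forward",
                        outcome = "success", game_id = "g1",
                        format = "SSG", team = "U15",
                        side_team_id = paste0(game_id, ".1")) {
  tibble::tibble(game_id = game_id, format = format, team = team,
                 side_team_id = side_team_id, player_id = player_id,
                 indicator = indicator, outcome = outcome)
}

make_roster <- function(player_id, team = "U15", minutes_ssg = 60,
                        minutes_m11 = 90, n_ssg_played = 10) {
  tibble::tibble(
    player_id = player_id, team = team,
    minutes_ssg = rep(minutes_ssg, length.out = length(player_id)),
    minutes_m11 = rep(minutes_m11, length.out = length(player_id)),
    n_ssg_played = rep(n_ssg_played, length.out = length(player_id)),
    sprint_10m = NA_real_, sprint_30m = NA_real_, isrt_tracks = NA_real_,
    agility_left = NA_real_, agility_right = NA_real_,
    agility_mean = NA_real_
  )
}

# small study configuration used where full size is not needed
small_config <- function(seed = 101, ...) {
  generator_config(
    seed = seed,
    teams = tibble::tibble(team = c("U15", "U17", "U19", "U23"),
                           n_players = 8L, n_ssg = 6L, n_m11_halves = 3L),
    ...
  )
}

# Gauss-Hermite nodes/weights by Golub-Welsch (independent of lme4)
gh_rule <- function(n) {
  k <- seq_len(n - 1)
  jac <- matrix(0, n, n)
  jac[cbind(k, k + 1)] <- sqrt(k / 2)
  jac <- jac + t(jac)
  e <- eigen(jac, symmetric = TRUE)
  list(x = e$values, w = (e$vectors[1, ])^2 * sqrt(pi))
}

# brute-force marginal log-likelihood of the random-intercept logistic
# model: per player, integrate the binomial likelihood over u ~ N(0, sigma^2)
gh_marginal_loglik <- function(succ, fail, eta_fixed, sigma, rule) {
  eta_fixed <- rep(eta_fixed, length.out = length(succ))
  sum(vapply(seq_along(succ), function(i) {
    p <- stats::plogis(eta_fixed[i] + sqrt(2) * sigma * rule$x)
    log(sum(rule$w / sqrt(pi) * p^succ[i] * (1 - p)^fail[i])) +
      lchoose(succ[i] + fail[i], succ[i])
  }, numeric(1)))
}
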