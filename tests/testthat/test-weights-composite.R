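two_side_game <- function() {
  ev <- dplyr::bind_rows(
    make_events(rep("p1", 10), "pass_forward",
                rep(c("success", "failure"), c(6, 4)),
                side_team_id = "g1.1"),
    make_events(rep("p1", 2), "shot_on_target", NA_character_,
                side_team_id = "g1.1"),
    make_events(rep("p2", 4), "pass_forward",
                rep(c("success", "failure"), c(3, 1)),
                side_team_id = "g1.2")
  )
  games <- tibble::tibble(
    game_id = "g1", format = "SSG", team = "U15",
    side_team_id = c("g1.1", "g1.2"), shots_on_target = c(2L, 0L),
    coded = TRUE
  )
  list(events = ev, games = games)
}

test_that("team-game totals pair each side with the right proxy", {
  fx <- two_side_game()
  tot <- team_game_indicator_totals(fx$events, fx$games)
  pf <- tot[tot$indicator == "pass_forward", ]
  expect_equal(pf$value[pf$side_team_id == "g1.1"], 6)  # success count
  expect_equal(pf$value[pf$side_team_id == "g1.2"], 3)
  expect_equal(pf$proxy[pf$side_team_id == "g1.1"], 2)  # own shots
  # defensive rows carry the shots conceded (the other side's shots)
  dd <- tot[tot$indicator == "defensive_duel", ]
  expect_equal(dd$proxy[dd$side_team_id == "g1.1"], 0)
  expect_equal(dd$proxy[dd$side_team_id == "g1.2"], 2)
  # zero-event indicators keep explicit zero rows
  expect_equal(dd$value, c(0, 0))
  # the proportion variant divides by attempts
  prop <- team_game_indicator_totals(fx$events, fx$games,
                                     binary_stat = "success_prop")
  pfp <- prop[prop$indicator == "pass_forward", ]
  expect_equal(sort(pfp$value), c(0.6, 0.75))
})

test_that("uncoded sides contribute only the conceded proxy", {
  fx <- two_side_game()
  fx$games$coded <- c(TRUE, FALSE)
  tot <- team_game_indicator_totals(fx$events, fx$games)
  expect_setequal(unique(tot$side_team_id), "g1.1")
  expect_equal(tot$proxy[tot$indicator == "defensive_duel"], 0)
})

test_that("weights recover a generator-controlled common factor", {
  # strong shared team-strength factor: offensive counts and shots rise
  # and fall together game by game
  cfg <- small_config(seed = 55, team_strength_sd = 0.8,
                      rate_effect_sd = 0.1, rate_scale = 3)
  study <- generate_study(cfg)
  tot <- team_game_indicator_totals(study$events, study$games)
  w <- suppressWarnings(derive_weights(tot))
  off <- w$weight[w$indicator %in% c("pass_forward", "chance_created")]
  expect_true(all(off > 0.3))
  # and a configuration with no shared factor stays near zero
  cfg0 <- small_config(seed = 56, team_strength_sd = 0,
                       defense_suppression = 0, rate_effect_sd = 0.1)
  study0 <- generate_study(cfg0)
  w0 <- suppressWarnings(
    derive_weights(team_game_indicator_totals(study0$events, study0$games))
  )
  off0 <- w0$weight[w0$indicator %in% c("pass_forward", "chance_created")]
  expect_true(all(abs(off0) < 0.3))
})

test_that("shots on target always carry fixed weight 1", {
  fx <- two_side_game()
  w <- suppressWarnings(
    derive_weights(team_game_indicator_totals(fx$events, fx$games))
  )
  expect_equal(w$weight[w$indicator == "shot_on_target"], 1)
})

test_that("the composite formula reproduces the published arithmetic", {
  # three players per indicator at values (0, 1, 2): z = (-1, 0, 1), so the
  # top player has z = 1 on every indicator
  inds <- unlist(composite_formula_indicators(), use.names = FALSE)
  scores <- tidyr::expand_grid(player_id = c("lo", "mid", "hi"),
                               indicator = inds) |>
    dplyr::mutate(score = dplyr::case_when(player_id == "lo" ~ 0,
                                           player_id == "mid" ~ 1,
                                           .default = 2))
  roster <- make_roster(c("lo", "mid", "hi"))
  cs <- composite_scores(scores, roster)
  hi <- cs[cs$player_id == "hi", ]
  expect_equal(hi$offensive, 0.21 + 0.17 + 0.50 + 1)   # 1.88
  expect_equal(hi$defensive, -(-0.14 - 0.06 - 0.11))   # 0.31
  mid <- cs[cs$player_id == "mid", ]
  expect_equal(mid$offensive, 0)
  expect_equal(mid$defensive, 0)
  # within-team mean of each composite is 0 when nobody is dropped
  expect_equal(mean(cs$offensive), 0)
  expect_equal(mean(cs$defensive), 0)
})

test_that("composites are monotone in each indicator's z-score", {
  inds <- unlist(composite_formula_indicators(), use.names = FALSE)
  base <- tidyr::expand_grid(player_id = sprintf("p%d", 1:4),
                             indicator = inds) |>
    dplyr::mutate(score = rep(c(1, 2, 3, 4), each = length(inds)))
  roster <- make_roster(sprintf("p%d", 1:4))
  cs0 <- composite_scores(base, roster)
  bumped <- base
  sel <- bumped$player_id == "p2" & bumped$indicator == "defensive_duel"
  bumped$score[sel] <- bumped$score[sel] + 2   # win more duels
  cs1 <- composite_scores(bumped, roster)
  expect_gt(cs1$defensive[cs1$player_id == "p2"],
            cs0$defensive[cs0$player_id == "p2"])
})

test_that("degenerate teams are handled explicitly", {
  inds <- unlist(composite_formula_indicators(), use.names = FALSE)
  flat <- tidyr::expand_grid(player_id = c("a", "b"), indicator = inds) |>
    dplyr::mutate(score = 1)
  roster <- make_roster(c("a", "b"))
  warns <- capture_warnings(cs <- composite_scores(flat, roster))
  expect_true(any(grepl("zero spread", warns)))
  expect_equal(cs$offensive, c(0, 0))
  expect_error(
    composite_scores(flat[flat$player_id == "a", ], make_roster("a")),
    "single scored player"
  )
})

test_that("a player missing a formula indicator gets NA for that composite", {
  inds <- unlist(composite_formula_indicators(), use.names = FALSE)
  scores <- tidyr::expand_grid(player_id = c("a", "b", "c"),
                               indicator = inds) |>
    dplyr::mutate(score = rnorm(dplyr::n()))
  scores <- scores[!(scores$player_id == "a" &
                       scores$indicator == "offensive_duel"), ]
  cs <- composite_scores(scores, make_roster(c("a", "b", "c")))
  expect_true(is.na(cs$offensive[cs$player_id == "a"]))
  expect_false(is.na(cs$defensive[cs$player_id == "a"]))
})
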