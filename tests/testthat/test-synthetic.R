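test_that("generation is deterministic down to the written bytes", {
  cfg <- small_config(seed = 40)
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  expect_identical(s1$events, s2$events)
  expect_identical(s1$truth$players, s2$truth$players)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_study(s1, d1); write_study(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7))
  }
  # and a different seed gives different data
  expect_false(identical(generate_study(small_config(seed = 41))$events,
                         s1$events))
})

test_that("perfect consistency makes format abilities identical", {
  study <- generate_study(small_config(seed = 42, rho = 1))
  pl <- study$truth$players
  expect_equal(pl$off_ssg, pl$off_m11)
  expect_equal(pl$def_ssg, pl$def_m11)
  study0 <- generate_study(small_config(seed = 42, rho = 0))
  pl0 <- study0$truth$players
  expect_lt(abs(cor(pl0$off_ssg, pl0$off_m11)), 0.35)
})

test_that("every player is on exactly one side per game", {
  study <- generate_study(small_config(seed = 43))
  per_game <- study$events |>
    dplyr::distinct(game_id, player_id, side_team_id) |>
    dplyr::count(game_id, player_id)
  expect_true(all(per_game$n == 1))
  # SSG sides are re-shuffled: compositions differ across games
  sides <- study$events |>
    dplyr::filter(format == "SSG", team == "U15") |>
    dplyr::distinct(game_id, side_team_id, player_id) |>
    dplyr::group_by(game_id, side_team_id) |>
    dplyr::summarise(comp = paste(sort(player_id), collapse = ","),
                     .groups = "drop")
  expect_gt(length(unique(sides$comp)), 2)
})

test_that("side shots on target equal the side's generated shot events", {
  study <- generate_study(small_config(seed = 44))
  shots <- study$events |>
    dplyr::filter(indicator == "shot_on_target") |>
    dplyr::count(game_id, side_team_id)
  coded <- study$games[study$games$coded, ]
  joined <- dplyr::left_join(coded, shots, by = c("game_id", "side_team_id"))
  expect_equal(joined$shots_on_target,
               as.integer(dplyr::coalesce(joined$n, 0L)))
  # within a game, one side's shots are the other side's shots conceded
  swapped <- study$games |>
    dplyr::group_by(game_id) |>
    dplyr::summarise(ok = dplyr::n() == 2)
  expect_true(all(swapped$ok))
})

test_that("generated event totals recover the configured rates", {
  # average the realised per-bout rate over replicates; the tolerance is
  # 3 SE of the replicate mean (latent abilities dominate the MC noise)
  cfg <- generator_config(seed = 45)
  lam <- default_event_rates()
  pick <- c("pass_forward", "pass_interception")
  out <- replicate_studies(cfg, 6, function(study, i) {
    bouts <- sum(study$roster$minutes_ssg) / 6
    ssg <- study$events[study$events$format == "SSG", ]
    vapply(pick, function(ind) sum(ssg$indicator == ind) / bouts, numeric(1))
  })
  mat <- do.call(rbind, out$results)
  for (ind in pick) {
    target <- lam$rate[lam$indicator == ind & lam$format == "SSG"]
    se <- sd(mat[, ind]) / sqrt(nrow(mat))
    expect_lt(abs(mean(mat[, ind]) - target), 3 * se + 0.02 * target)
  }
})

test_that("replication is seed-derived, isolated and fault-tolerant", {
  cfg <- small_config(seed = 46)
  one <- replicate_studies(cfg, 1, function(study, i) nrow(study$events))
  cfg_d <- cfg; cfg_d$seed <- as.integer(one$seeds[[1]])
  expect_equal(one$results[[1]], nrow(generate_study(cfg_d)$events))
  # a failing replicate is recorded; the others still run
  flaky <- replicate_studies(cfg, 3, function(study, i) {
    if (i == 2) stop("boom") else i
  })
  expect_equal(names(flaky$errors), "2")
  expect_equal(unlist(flaky$results), c(1, 3))
})

test_that("roster exposure is consistent with the schedule", {
  study <- generate_study(small_config(seed = 47))
  played <- study$events |>
    dplyr::filter(format == "SSG") |>
    dplyr::distinct(game_id, player_id) |>
    dplyr::count(player_id)
  r <- study$roster
  # every SSG appearance is 6 minutes; players may also appear in no event
  appeared <- played$n[match(r$player_id, played$player_id)]
  appeared[is.na(appeared)] <- 0L
  expect_true(all(r$n_ssg_played >= appeared))
  expect_equal(r$minutes_ssg, 6 * r$n_ssg_played)
  expect_equal(r$agility_mean,
               rowMeans(r[, c("agility_left", "agility_right")]))
})

test_that("invalid configurations are rejected", {
  expect_error(generator_config(rho = 1.5), "rho")
  expect_error(generator_config(frobnicate = 1), "unknown option")
  bad_tests <- generator_config()$test_model
  bad_tests$off_loading[1] <- 0.9
  bad_tests$def_loading[1] <- 0.9
  expect_error(generator_config(test_model = bad_tests),
               "positive semi-definite")
})
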