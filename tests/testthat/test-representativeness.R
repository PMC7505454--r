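test_that("expected counts conserve the observed total exactly", {
  counts <- published_event_counts()
  gof <- gof_chi_square(setNames(counts$observed_ssg, counts$indicator),
                        setNames(counts$observed_m11, counts$indicator))
  expect_equal(sum(gof$table$expected_ssg), gof$n)
  expect_equal(sum(gof$table$prop_m11), 1)
  expect_equal(gof$df, nrow(counts) - 1)
})

test_that("chi-square and residuals match a direct-summation oracle", {
  counts <- published_event_counts()
  o <- counts$observed_ssg
  ref <- counts$observed_m11
  p <- ref / sum(ref)
  e <- sum(o) * p
  chi2 <- sum((o - e)^2 / e)
  resid_adj <- (o - e) / sqrt(e * (1 - p))
  gof <- gof_chi_square(setNames(o, counts$indicator),
                        setNames(ref, counts$indicator))
  expect_equal(gof$statistic, chi2)
  expect_equal(gof$table$std_residual, resid_adj)
  # the adjusted multinomial denominator is essential: the plain Pearson
  # residual (O - E)/sqrt(E) is a different number for every cell here
  resid_plain <- (o - e) / sqrt(e)
  expect_false(any(abs(resid_adj - resid_plain) < 1e-3))
})

test_that("proportional observations give a null test", {
  o <- c(a = 30L, b = 60L, c = 90L)
  ref <- c(a = 10L, b = 20L, c = 30L)
  gof <- gof_chi_square(o, ref)
  expect_equal(gof$statistic, 0)
  expect_equal(gof$table$std_residual, rep(0, 3))
  expect_equal(gof$p_value, 1)
})

test_that("dropping a category is explicit and shrinks df and N", {
  counts <- published_event_counts()
  keep <- !grepl("aerial", counts$indicator)
  full <- gof_chi_square(setNames(counts$observed_ssg, counts$indicator),
                         setNames(counts$observed_m11, counts$indicator))
  red <- gof_chi_square(
    setNames(counts$observed_ssg[keep], counts$indicator[keep]),
    setNames(counts$observed_m11[keep], counts$indicator[keep])
  )
  expect_equal(red$df, full$df - 2)
  expect_lt(red$n, full$n)
  # zero reference counts must be removed by the caller, never silently
  expect_error(gof_chi_square(c(a = 5L, b = 5L), c(a = 10L, b = 0L)),
               "remove the category explicitly")
})

test_that("distribution correlation handles ties, identity and degeneracy", {
  expect_equal(distribution_rank_correlation(c(1, 2, 3, 4), c(2, 4, 6, 8))$r,
               1)
  expect_error(distribution_rank_correlation(c(1, 1, 1, 1), c(1, 2, 3, 4)),
               "constant")
  expect_error(distribution_rank_correlation(1:3, 3:1), "at least 4")
  # mid-rank ties: agree with cor(method = "spearman")
  a <- c(3, 3, 10, 1, 7, 7)
  b <- c(2, 5, 9, 2, 6, 8)
  expect_equal(distribution_rank_correlation(a, b)$r,
               cor(a, b, method = "spearman"))
})

test_that("mean events per bout normalises by game duration", {
  ev <- dplyr::bind_rows(
    make_events(rep("p1", 3), "shot_on_target", NA_character_,
                game_id = "s1", format = "SSG"),
    make_events(rep("p1", 15), "pass_forward", "success",
                game_id = "m1", format = "M11")
  )
  games <- tibble::tibble(
    game_id = c("s1", "s1", "m1", "m1"),
    format = c("SSG", "SSG", "M11", "M11"),
    team = "U15",
    side_team_id = c("s1.1", "s1.2", "m1.home", "m1.opp"),
    shots_on_target = 0L, coded = TRUE
  )
  m <- mean_events_per_bout_by_format(ev, games)
  get <- function(f, ind) m$mean_per_bout[m$format == f & m$indicator == ind]
  expect_equal(get("SSG", "shot_on_target"), 3)     # 6 x 3 / 6
  expect_equal(get("M11", "pass_forward"), 2)       # 6 x 15 / 45
  # averaging across games of one format
  ev2 <- dplyr::bind_rows(ev, make_events("p1", "shot_on_target",
                                          NA_character_, game_id = "s2"))
  games2 <- dplyr::bind_rows(games, tibble::tibble(
    game_id = "s2", format = "SSG", team = "U15",
    side_team_id = c("s2.1", "s2.2"), shots_on_target = 0L, coded = TRUE
  ))
  m2 <- mean_events_per_bout_by_format(ev2, games2)
  expect_equal(m2$mean_per_bout[m2$format == "SSG" &
                                  m2$indicator == "shot_on_target"], 2)
})

test_that("synthetic defaults echo the faster-paced SSG pattern", {
  study <- generate_study(generator_config(seed = 14))
  m <- mean_events_per_bout_by_format(study$events, study$games)
  wide <- tidyr::pivot_wider(m[, c("format", "indicator", "mean_per_bout")],
                             names_from = "format",
                             values_from = "mean_per_bout")
  pick <- function(ind) wide[wide$indicator == ind, ]
  # per-bout shots and chances higher in SSGs; aerial duels suppressed
  expect_gt(pick("shot_on_target")$SSG, pick("shot_on_target")$M11)
  expect_gt(pick("chance_created")$SSG, pick("chance_created")$M11)
  expect_lt(pick("defensive_aerial_duel")$SSG,
            pick("defensive_aerial_duel")$M11)
})
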