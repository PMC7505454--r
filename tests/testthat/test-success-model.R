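sim_two_teams <- function(seed = 21, n_players = 30, n_trials = 25,
                          sigma_u = 0.8) {
  simulate_binary_indicator(
    n_players, teams = c("U15", "U17"), beta0 = 0.3,
    team_effects = c(U15 = 0, U17 = 0.4), sigma_u = sigma_u,
    n_trials = n_trials, seed = seed
  )
}

test_that("posterior scores are the additive linear predictor", {
  fit <- structure(list(
    beta0 = 0.4, team_effects = c(U15 = 0, U17 = 0.2),
    sigma_u = 0.5, u = c(p1 = -0.1), n_trials = c(p1 = 12L),
    indicator = "pass_forward", format = "SSG"
  ), class = "ssg_success_fit")
  roster <- make_roster(c("p1", "p2"), team = c("U17", "U17"))
  sc <- player_posterior_scores(fit, roster)
  expect_equal(sc$score[sc$player_id == "p1"], 0.5)
  # a player with no trials gets full shrinkage to beta0 + beta_team
  expect_equal(sc$score[sc$player_id == "p2"], 0.6)
  expect_equal(sc$n_trials[sc$player_id == "p2"], 0L)
})

test_that("within a team, score ranking equals the random-effect ranking", {
  sim <- sim_two_teams()
  fit <- fit_success_model(sim$events, sim$roster)
  sc <- player_posterior_scores(fit, sim$roster)
  for (tm in c("U15", "U17")) {
    ids <- sim$roster$player_id[sim$roster$team == tm]
    expect_equal(rank(sc$score[match(ids, sc$player_id)]),
                 unname(rank(fit$u[ids])))
  }
})

test_that("posterior probabilities shrink towards the team mean", {
  sim <- simulate_binary_indicator(20, beta0 = 0, sigma_u = 1,
                                   n_trials = 15, seed = 4)
  fit <- fit_success_model(sim$events, sim$roster)
  sc <- player_posterior_scores(fit, sim$roster)
  agg <- sim$events |>
    dplyr::group_by(player_id) |>
    dplyr::summarise(naive = mean(outcome == "success"))
  team_mean <- mean(sim$events$outcome == "success")
  post <- plogis(sc$score[match(agg$player_id, sc$player_id)])
  lo <- pmin(agg$naive, team_mean) - 1e-6
  hi <- pmax(agg$naive, team_mean) + 1e-6
  expect_true(all(post >= lo & post <= hi))
})

test_that("shrinkage strengthens as trials decrease at a fixed fraction", {
  # same 80% success fraction observed over 40 vs 5 trials
  ev <- dplyr::bind_rows(
    make_events(rep("many", 40), outcome = rep(c("success", "failure"),
                                               c(32, 8))),
    make_events(rep("few", 5), outcome = rep(c("success", "failure"),
                                             c(4, 1))),
    make_events(rep(sprintf("bg%02d", 1:10), each = 10),
                outcome = rep(rep(c("success", "failure"), c(5, 5)), 10))
  )
  roster <- make_roster(unique(ev$player_id))
  fit <- fit_success_model(ev, roster)
  expect_gt(abs(fit$u[["many"]]), abs(fit$u[["few"]]))
  expect_gt(fit$u[["few"]], 0)
})

test_that("null data yield a near-zero random-intercept SD", {
  sim <- simulate_binary_indicator(40, beta0 = 0.2, sigma_u = 0,
                                   n_trials = 100, seed = 8)
  fit <- fit_success_model(sim$events, sim$roster)
  expect_lte(fit$sigma_u, 0.15)
})

test_that("overall separation is refused; per-team separation is ridged", {
  all_succ <- make_events(rep(c("p1", "p2"), each = 5),
                          outcome = "success")
  expect_error(fit_success_model(all_succ, make_roster(c("p1", "p2"))),
               "separation")
  # one team all-success, the other mixed: guard keeps effects finite
  ev <- dplyr::bind_rows(
    make_events(rep(c("a1", "a2"), each = 8), team = "U15",
                outcome = "success"),
    make_events(rep(c("b1", "b2"), each = 8), team = "U17",
                outcome = rep(c("success", "failure"), 8))
  )
  roster <- make_roster(c("a1", "a2", "b1", "b2"),
                        team = c("U15", "U15", "U17", "U17"))
  fit <- fit_success_model(ev, roster)
  expect_true(fit$diagnostics$separation_ridge)
  expect_equal(fit$diagnostics$ridged_teams, "U15")
  expect_true(all(is.finite(fit$team_effects)))
  expect_false(any(startsWith(names(fit$u), ".prior::")))
})

test_that("opposed extreme players keep finite effects under shrinkage", {
  ev <- dplyr::bind_rows(
    make_events(rep("p1", 10), outcome = "success"),
    make_events(rep("p2", 10), outcome = "failure")
  )
  fit <- fit_success_model(ev, make_roster(c("p1", "p2")))
  expect_true(all(is.finite(fit$u)))
  naive <- c(Inf, -Inf)  # the unpooled logits diverge; the EB modes do not
  expect_true(all(abs(fit$u) < 10))
})

test_that("the fit maximises the same marginal likelihood as brute-force
           Gauss-Hermite quadrature", {
  ev <- dplyr::bind_rows(
    make_events(rep("p1", 10), outcome = rep(c("success", "failure"),
                                             c(7, 3))),
    make_events(rep("p2", 10), outcome = rep(c("success", "failure"),
                                             c(3, 7)))
  )
  fit <- fit_success_model(ev, make_roster(c("p1", "p2")), n_agq = 25)
  rule <- gh_rule(120)
  oracle <- function(th) -gh_marginal_loglik(c(7, 3), c(3, 7), th[1],
                                             exp(th[2]), rule)
  opt <- optim(c(0, -0.5), oracle, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  ll_at_fit <- gh_marginal_loglik(c(7, 3), c(3, 7), fit$beta0, fit$sigma_u,
                                  rule)
  # same likelihood function, same maximum, to 4 decimals
  expect_equal(ll_at_fit, -opt$value, tolerance = 1e-4)
  expect_equal(fit$beta0, opt$par[1], tolerance = 1e-3)
  expect_equal(fit$sigma_u, exp(opt$par[2]), tolerance = 1e-3)
  # the Laplace logLik convention includes the binomial constants
  fit1 <- fit_success_model(ev, make_roster(c("p1", "p2")), n_agq = 1)
  expect_equal(fit1$log_lik, -opt$value, tolerance = 0.05)
})

test_that("fits are deterministic and record their estimation method", {
  sim <- sim_two_teams(seed = 33)
  f1 <- fit_success_model(sim$events, sim$roster)
  f2 <- fit_success_model(sim$events, sim$roster)
  expect_identical(f1$beta0, f2$beta0)
  expect_identical(f1$u, f2$u)
  expect_equal(f1$method, "laplace")
  expect_equal(fit_success_model(sim$events, sim$roster, n_agq = 9)$method,
               "agq9")
})
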