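#' Fit a random-intercept logistic model for one binary indicator
#'
#' Player performance on a success/failure indicator is modelled with a
#' multilevel logistic regression: logit P(success) = beta0 + beta_team +
#' u_player, where u_player ~ N(0, sigma_u^2) and team is a categorical
#' covariate (reference = lexicographically first team). Unlike the naive
#' success fraction, the empirical-Bayes player modes are shrunken towards
#' the team mean in proportion to how little data a player has, so players
#' with few trials are not over- or under-rated.
#'
#' Estimation uses marginal maximum likelihood via `lme4::glmer` on
#' per-player success/failure totals: the Laplace approximation
#' (`n_agq = 1`, the default) or adaptive Gauss-Hermite quadrature
#' (`n_agq > 1`). The method used is recorded in the fit object and, with a
#' fixed optimizer configuration, the fit is deterministic given the data.
#'
#' If every event in the data is a success (or every one a failure) the fit
#' is refused: the likelihood has no interior maximum. If all outcomes
#' within some team are identical, a weakly-informative data-augmentation
#' penalty is applied (one pseudo-player with 1 success + 1 failure in each
#' such team) so the team effect stays finite; this is flagged in the
#' diagnostics and the pseudo-players never receive scores.
#'
#' @param events validated events for a single binary indicator in a single
#'   format (columns `player_id`, `outcome`; extra columns ignored).
#' @param roster roster tibble supplying `team` per player.
#' @param n_agq integer; 1 = Laplace, >1 = adaptive Gauss-Hermite nodes.
#' @return object of class `ssg_success_fit`: `beta0`, `team_effects`
#'   (named, reference 0), `sigma_u`, `u` (named empirical-Bayes modes),
#'   `n_trials` (named), `log_lik`, `method`, `indicator`, `format`,
#'   `diagnostics`, and the underlying `model`.
#' @export
fit_success_model <- function(events, roster, n_agq = 1) {
  stopifnot(all(c("player_id", "outcome") %in% names(events)))
  ind <- unique(events$indicator %||% NA_character_)
  fmt <- unique(events$format %||% NA_character_)
  if (length(ind) > 1 || length(fmt) > 1) {
    stop("fit_success_model(): supply events for one indicator in one format",
         call. = FALSE)
  }
  if (!all(events$outcome %in% c("success", "failure"))) {
    stop("fit_success_model(): outcomes must be success/failure", call. = FALSE)
  }

  agg <- events |>
    dplyr::count(.data$player_id, .data$outcome) |>
    tidyr::pivot_wider(names_from = "outcome", values_from = "n",
                       values_fill = 0L)
  for (col in c("success", "failure")) {
    if (!col %in% names(agg)) agg[[col]] <- 0L
  }
  agg <- dplyr::left_join(agg,
                          dplyr::select(roster, "player_id", "team"),
                          by = "player_id")
  if (anyNA(agg$team)) {
    stop("fit_success_model(): player(s) missing from roster", call. = FALSE)
  }
  if (nrow(agg) < 2) {
    stop("fit_success_model(): need at least 2 players with trials",
         call. = FALSE)
  }
  if (sum(agg$failure) == 0 || sum(agg$success) == 0) {
    stop("fit_success_model(): complete separation (all outcomes identical); ",
         "fit refused", call. = FALSE)
  }

  # separation guard: team with all-identical outcomes gets a pseudo-player
  degenerate <- agg |>
    dplyr::group_by(.data$team) |>
    dplyr::summarise(bad = sum(.data$success) == 0 | sum(.data$failure) == 0,
                     .groups = "drop") |>
    dplyr::filter(.data$bad)
  ridged <- nrow(degenerate) > 0
  if (ridged) {
    pseudo <- tibble::tibble(
      player_id = paste0(".prior::", degenerate$team),
      success = 1L, failure = 1L, team = degenerate$team
    )
    agg <- dplyr::bind_rows(agg, pseudo)
  }

  agg$team <- factor(agg$team, levels = sort(unique(agg$team)))
  form <- if (nlevels(agg$team) > 1) {
    cbind(success, failure) ~ team + (1 | player_id)
  } else {
    cbind(success, failure) ~ 1 + (1 | player_id)
  }
  fit <- lme4::glmer(
    form, data = agg, family = stats::binomial(),
    nAGQ = n_agq,
    control = lme4::glmerControl(optimizer = "bobyqa",
                                 calc.derivs = TRUE)
  )

  beta <- lme4::fixef(fit)
  team_levels <- levels(agg$team)
  team_effects <- stats::setNames(rep(0, length(team_levels)), team_levels)
  if (length(team_levels) > 1) {
    # fixed-effect names are "team<level>"; the reference level stays 0
    for (nm in names(beta)[-1]) {
      team_effects[sub("^team", "", nm)] <- beta[[nm]]
    }
  }
  re <- lme4::ranef(fit)$player_id
  u <- stats::setNames(re[["(Intercept)"]], rownames(re))
  keep <- !startsWith(names(u), ".prior::")
  u <- u[keep]
  n_trials <- stats::setNames(agg$success + agg$failure, agg$player_id)
  n_trials <- n_trials[!startsWith(names(n_trials), ".prior::")]

  msgs <- unlist(fit@optinfo$conv$lme4$messages)
  structure(list(
    beta0 = unname(beta[["(Intercept)"]]),
    team_effects = team_effects,
    sigma_u = sqrt(unname(lme4::VarCorr(fit)$player_id[1, 1])),
    u = u,
    n_trials = n_trials,
    log_lik = as.numeric(stats::logLik(fit)),
    method = if (n_agq == 1) "laplace" else sprintf("agq%d", n_agq),
    indicator = ind, format = fmt,
    diagnostics = list(
      converged = length(msgs) == 0,
      messages = msgs %||% character(),
      separation_ridge = ridged,
      ridged_teams = if (ridged) degenerate$team else character()
    ),
    model = fit
  ), class = "ssg_success_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ssg_success_fit <- function(x, ...) {
  cat(sprintf("Random-intercept logistic fit (%s, %s, %s)\n",
              x$indicator, x$format, x$method))
  cat(sprintf("  beta0 = %.3f  sigma_u = %.3f  logLik = %.3f\n",
              x$beta0, x$sigma_u, x$log_lik))
  cat("  team effects:",
      paste(sprintf("%s=%.3f", names(x$team_effects), x$team_effects),
            collapse = "  "), "\n")
  if (x$diagnostics$separation_ridge) {
    cat("  note: separation guard active for team(s):",
        paste(x$diagnostics$ridged_teams, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Posterior (empirical-Bayes) player scores from a fitted success model
#'
#' A player's score is the logit-scale linear predictor
#' beta0 + beta_team + u_player. A rostered player with no trials on the
#' indicator gets full shrinkage: beta0 + beta_team. The score is a
#' strictly monotone transform of the model's predicted success
#' probability, so any rank-based downstream use is scale-invariant.
#'
#' @param fit `ssg_success_fit` object.
#' @param roster roster tibble (players to score; must include the fitted
#'   players' teams).
#' @return tibble `player_id`, `format`, `indicator`, `n_trials`, `score`.
#' @export
player_posterior_scores <- function(fit, roster) {
  stopifnot(inherits(fit, "ssg_success_fit"))
  teams <- roster$team
  unknown <- setdiff(unique(teams), names(fit$team_effects))
  if (length(unknown) > 0) {
    stop("player_posterior_scores(): team(s) absent from fit: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  u <- fit$u[roster$player_id]
  u[is.na(u)] <- 0
  n_tr <- fit$n_trials[roster$player_id]
  n_tr[is.na(n_tr)] <- 0L
  tibble::tibble(
    player_id = roster$player_id,
    format = fit$format,
    indicator = fit$indicator,
    n_trials = as.integer(n_tr),
    score = fit$beta0 + unname(fit$team_effects[teams]) + unname(u)
  )
}

#' Export a fit summary as a JSON-ready list
#'
#' Mirrors a coefficient-table layout: fixed effects, random-intercept SD,
#' convergence diagnostics and the estimation method.
#'
#' @param fit `ssg_success_fit` object.
#' @return a plain list suitable for `jsonlite::write_json`.
#' @export
success_fit_summary <- function(fit) {
  stopifnot(inherits(fit, "ssg_success_fit"))
  list(
    indicator = fit$indicator,
    format = fit$format,
    method = fit$method,
    fixed_intercept = fit$beta0,
    team_effects = as.list(fit$team_effects),
    random_intercept_sd = fit$sigma_u,
    log_lik = fit$log_lik,
    n_players = length(fit$u),
    converged = fit$diagnostics$converged,
    separation_ridge = fit$diagnostics$separation_ridge
  )
}
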