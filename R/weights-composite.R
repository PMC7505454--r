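#' Team-side per-game indicator totals with the success proxy
#'
#' Aggregates events to the team level: for each coded game side, the
#' per-indicator performance (count indicators: number of events; binary
#' indicators: number of successful events by default, or the success
#' proportion) in the merged-duel view, paired with the side's in-game
#' success proxy — its own shots on target for offensive indicators, the
#' shots on target it conceded (the opposite side's shots) for defensive
#' indicators.
#'
#' Sides marked uncoded in `games` (e.g. the opponent side of an 11-vs-11
#' half) contribute only their shots on target to the conceded proxy of the
#' coded side; they get no indicator rows. Coded sides with no events at
#' all keep their zero rows.
#'
#' @param events validated event tibble (raw labels; duels are merged
#'   internally).
#' @param games game-side tibble (see [read_games()]).
#' @param binary_stat `"success_count"` (default) or `"success_prop"`.
#' @return tibble `game_id`, `format`, `team`, `side_team_id`, `indicator`,
#'   `side`, `value`, `proxy`.
#' @export
team_game_indicator_totals <- function(events, games,
                                       binary_stat = c("success_count",
                                                       "success_prop")) {
  binary_stat <- match.arg(binary_stat)
  games <- validate_games(games)

  # conceded = the other side's shots on target
  games <- games |>
    dplyr::group_by(.data$game_id) |>
    dplyr::mutate(shots_conceded = rev(.data$shots_on_target)) |>
    dplyr::ungroup()

  merged <- merge_indicators(events)
  tax <- indicator_taxonomy()
  # merged-view indicator set: duel components appear only as merged labels;
  # aerial duels are excluded from individual quantification
  inds <- tax |>
    dplyr::filter(is.na(.data$merged_into),
                  !.data$indicator %in%
                    c("offensive_aerial_duel", "defensive_aerial_duel"))

  per_side <- merged |>
    dplyr::group_by(.data$game_id, .data$side_team_id, .data$indicator) |>
    dplyr::summarise(
      n_events = dplyr::n(),
      n_success = sum(.data$outcome == "success", na.rm = TRUE),
      .groups = "drop"
    )

  coded <- games[games$coded, , drop = FALSE]
  grid <- tidyr::expand_grid(
    coded |>
      dplyr::select("game_id", "format", "team", "side_team_id",
                    "shots_on_target", "shots_conceded"),
    indicator = inds$indicator
  )
  otype <- stats::setNames(inds$outcome_type, inds$indicator)
  side_of <- stats::setNames(inds$side, inds$indicator)

  grid |>
    dplyr::left_join(per_side, by = c("game_id", "side_team_id", "indicator")) |>
    dplyr::mutate(
      n_events = dplyr::coalesce(.data$n_events, 0L),
      n_success = dplyr::coalesce(.data$n_success, 0L),
      side = unname(side_of[.data$indicator]),
      value = dplyr::case_when(
        otype[.data$indicator] == "count" ~ as.numeric(.data$n_events),
        binary_stat == "success_count" ~ as.numeric(.data$n_success),
        .default = ifelse(.data$n_events > 0,
                          .data$n_success / .data$n_events, NA_real_)
      ),
      proxy = ifelse(.data$side == "offense",
                     as.numeric(.data$shots_on_target),
                     as.numeric(.data$shots_conceded))
    ) |>
    dplyr::select("game_id", "format", "team", "side_team_id", "indicator",
                  "side", "value", "proxy")
}

#' Indicator weights from success-proxy correlations
#'
#' For each weighted indicator, Spearman's rank correlation between the
#' team-side per-game indicator value and its success proxy is computed
#' within each team-by-format group of game sides and aggregated with the
#' DerSimonian-Laird random-effects meta-analysis ([meta_spearman()]). The
#' aggregated coefficient is the indicator's weight. Shots on target are
#' the proxy itself and carry a fixed weight of 1 in the offensive
#' composite; aerial duels are excluded from individual quantification and
#' get no weight.
#'
#' @param totals output of [team_game_indicator_totals()].
#' @param min_n minimum game sides per group (default 4).
#' @return tibble `indicator`, `side`, `weight`, `ci_low`, `ci_high`, `p`,
#'   `tau2`, `k`, `n_total`, with the per-group coefficients in the
#'   `"provenance"` attribute.
#' @export
derive_weights <- function(totals, min_n = 4) {
  weighted_inds <- setdiff(unique(totals$indicator), "shot_on_target")
  rows <- list()
  provenance <- list()
  for (ind in weighted_inds) {
    d <- totals[totals$indicator == ind, , drop = FALSE]
    d$group <- paste(d$team, d$format, sep = ":")
    res <- tryCatch(
      meta_spearman(d, x = "value", y = "proxy", group = "group",
                    min_n = min_n),
      error = function(e) NULL
    )
    if (is.null(res)) {
      warning("derive_weights(): indicator ", ind,
              " omitted (no usable group)", call. = FALSE)
      next
    }
    rows[[ind]] <- tibble::tibble(
      indicator = ind, side = d$side[[1]], weight = res$r,
      ci_low = res$ci_low, ci_high = res$ci_high, p = res$p,
      tau2 = res$tau2, k = res$k, n_total = res$n_total
    )
    provenance[[ind]] <- res$groups
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::bind_rows(out, tibble::tibble(
    indicator = "shot_on_target", side = "offense", weight = 1,
    ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
    tau2 = NA_real_, k = NA_integer_, n_total = NA_integer_
  ))
  attr(out, "provenance") <- provenance
  out
}

#' Published composite weights
#'
#' The indicator weights published for the original study (the aggregated
#' correlation of each indicator with its success proxy), usable as
#' defaults when weights are not derived from data: offense 0.21 (passes
#' forward), 0.17 (offensive duels), 0.50 (chances created), 1 (shots on
#' target); defense -0.14 (defensive duels), -0.11 (applying pressure),
#' -0.06 (pass interceptions).
#'
#' @return tibble `indicator`, `side`, `weight`.
#' @export
table_weights <- function() {
  tibble::tribble(
    ~indicator,          ~side,     ~weight,
    "pass_forward",      "offense",  0.21,
    "offensive_duel",    "offense",  0.17,
    "chance_created",    "offense",  0.50,
    "shot_on_target",    "offense",  1.00,
    "defensive_duel",    "defense", -0.14,
    "applying_pressure", "defense", -0.11,
    "pass_interception", "defense", -0.06
  )
}

#' Within-team z-scores
#'
#' Standardises a numeric vector within teams using the sample SD (n - 1).
#' A team where the indicator has zero spread gets z = 0 for all its
#' players (with a warning); a team with a single player is an error.
#'
#' @param value numeric vector.
#' @param team team label per element.
#' @return numeric vector of z-scores (NA where `value` is NA).
#' @export
z_within_team <- function(value, team) {
  stopifnot(length(value) == length(team))
  out <- rep(NA_real_, length(value))
  for (tm in unique(team)) {
    idx <- which(team == tm)
    v <- value[idx]
    ok <- !is.na(v)
    if (sum(ok) == 1) {
      stop("z_within_team(): team ", tm,
           " has a single scored player; z-score undefined", call. = FALSE)
    }
    if (sum(ok) == 0) next
    s <- stats::sd(v[ok])
    if (s == 0) {
      warning("z_within_team(): zero spread in team ", tm,
              "; z set to 0", call. = FALSE)
      out[idx][ok] <- 0
    } else {
      out[idx] <- (v - mean(v[ok])) / s
    }
  }
  out
}

#' Indicators entering the offensive and defensive composite formulas
#' @return list with elements `offense` and `defense` (character vectors).
#' @export
composite_formula_indicators <- function() {
  list(
    offense = c("pass_forward", "offensive_duel", "chance_created",
                "shot_on_target"),
    defense = c("defensive_duel", "pass_interception", "applying_pressure")
  )
}

#' Overall offensive and defensive composite scores
#'
#' Combines per-player indicator scores into the two overall performance
#' measures. Scores are first transformed to z-scores within each team;
#' each z-score is multiplied by its indicator weight and summed:
#' offensive = w_pass z_pass + w_duel z_duel + w_chance z_chance +
#' 1 x z_shot; defensive = (w_duel z_duel + w_int z_int + w_press z_press)
#' x (-1), so that a higher score always means better play. A player
#' missing any of a formula's indicator scores gets NA for that composite.
#'
#' @param scores long tibble `player_id`, `indicator`, `score` covering the
#'   formula indicators (merged-duel view; posterior scores for binary
#'   indicators, rates for count indicators).
#' @param roster roster tibble supplying `team`.
#' @param weights weight tibble (`indicator`, `weight`); defaults to the
#'   published weights ([table_weights()]).
#' @return tibble `player_id`, `team`, `offensive`, `defensive`.
#' @export
composite_scores <- function(scores, roster, weights = table_weights()) {
  stopifnot(all(c("player_id", "indicator", "score") %in% names(scores)))
  formula_inds <- composite_formula_indicators()
  w <- stats::setNames(weights$weight, weights$indicator)
  need <- unlist(formula_inds, use.names = FALSE)
  miss_w <- setdiff(need, names(w))
  if (length(miss_w) > 0) {
    stop("composite_scores(): weights missing for: ",
         paste(miss_w, collapse = ", "), call. = FALSE)
  }

  wide <- scores |>
    dplyr::filter(.data$indicator %in% need) |>
    dplyr::select("player_id", "indicator", "score") |>
    tidyr::pivot_wider(names_from = "indicator", values_from = "score") |>
    dplyr::right_join(dplyr::select(roster, "player_id", "team"),
                      by = "player_id")
  for (ind in need) {
    if (!ind %in% names(wide)) wide[[ind]] <- NA_real_
    wide[[paste0("z_", ind)]] <- z_within_team(wide[[ind]], wide$team)
  }
  z <- function(ind) wide[[paste0("z_", ind)]]
  offensive <- Reduce(`+`, lapply(formula_inds$offense,
                                  function(i) w[[i]] * z(i)))
  defensive <- -1 * Reduce(`+`, lapply(formula_inds$defense,
                                       function(i) w[[i]] * z(i)))
  tibble::tibble(player_id = wide$player_id, team = wide$team,
                 offensive = offensive, defensive = defensive)
}
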