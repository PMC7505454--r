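#' Apply the player-exclusion policy
#'
#' Drops players who (a) played no minutes in the 11-vs-11 games, or
#' (b) played strictly fewer SSGs than (team mean - 2 x team SD) of the
#' number of SSGs played, computed per age-category team with the sample SD
#' (n - 1 denominator). "More than 2 SD below" is read literally: a player
#' exactly on the boundary is retained.
#'
#' @param roster roster tibble (see [read_roster()]).
#' @param sd_multiplier SD multiple defining "played in few SSGs"
#'   (default 2).
#' @return list with `retained` (roster subset) and `excluded` (tibble
#'   `player_id`, `team`, `reason`).
#' @export
#' @examples
#' r <- tibble::tibble(
#'   player_id = sprintf("p%02d", 1:5), team = "U15",
#'   minutes_ssg = 60, minutes_m11 = c(0, 90, 90, 90, 90),
#'   n_ssg_played = c(10, 2, 10, 11, 12),
#'   sprint_10m = NA_real_, sprint_30m = NA_real_, isrt_tracks = NA_real_,
#'   agility_left = NA_real_, agility_right = NA_real_
#' )
#' exclude_players(r)$excluded
exclude_players <- function(roster, sd_multiplier = 2) {
  stopifnot(is.data.frame(roster), "n_ssg_played" %in% names(roster))
  roster <- tibble::as_tibble(roster)
  reasons <- rep(NA_character_, nrow(roster))

  no_m11 <- roster$minutes_m11 <= 0
  reasons[no_m11] <- "no 11-vs-11 minutes"

  for (tm in unique(roster$team)) {
    idx <- which(roster$team == tm)
    if (length(idx) < 2) {
      warning("team ", tm, " has fewer than 2 players; ",
              "SSG-count exclusion criterion skipped", call. = FALSE)
      next
    }
    m <- mean(roster$n_ssg_played[idx])
    s <- stats::sd(roster$n_ssg_played[idx])
    threshold <- m - sd_multiplier * s
    few <- roster$n_ssg_played[idx] < threshold  # strict: boundary retained
    hit <- idx[few & is.na(reasons[idx])]
    reasons[hit] <- sprintf("played %d SSGs, more than %g SD below team mean (threshold %.2f)",
                            roster$n_ssg_played[hit], sd_multiplier, threshold)
  }

  excluded <- tibble::tibble(
    player_id = roster$player_id[!is.na(reasons)],
    team = roster$team[!is.na(reasons)],
    reason = reasons[!is.na(reasons)]
  )
  list(retained = roster[is.na(reasons), , drop = FALSE], excluded = excluded)
}
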