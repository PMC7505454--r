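#' @importFrom rlang .data
NULL

events_cols <- c("game_id", "format", "team", "side_team_id",
                 "player_id", "indicator", "outcome")
roster_cols <- c("player_id", "team", "minutes_ssg", "minutes_m11",
                 "n_ssg_played", "sprint_10m", "sprint_30m", "isrt_tracks",
                 "agility_left", "agility_right")
games_cols <- c("game_id", "format", "team", "side_team_id", "shots_on_target")

#' Read a player roster file
#'
#' `roster.csv` carries one row per player: age-category team, playing
#' minutes per format, number of SSGs played, and physiological/motor test
#' results (blank = missing). An `agility_mean` column is derived as the
#' mean of the left and right trials.
#'
#' @param path CSV path.
#' @return tibble of player profiles.
#' @export
read_roster <- function(path) {
  roster <- readr::read_csv(path, show_col_types = FALSE,
                            col_types = readr::cols(
                              player_id = "c", team = "c",
                              .default = readr::col_double()
                            ))
  missing <- setdiff(roster_cols, names(roster))
  if (length(missing) > 0) {
    stop("roster file is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  validate_roster(roster)
}

validate_roster <- function(roster) {
  bad <- which(roster$minutes_ssg < 0 | roster$minutes_m11 < 0 |
                 roster$n_ssg_played < 0)
  if (length(bad) > 0) {
    stop("roster: negative minutes or SSG count at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(roster$player_id)) {
    stop("roster: duplicated player_id", call. = FALSE)
  }
  roster$agility_mean <- rowMeans(roster[, c("agility_left", "agility_right")])
  tibble::as_tibble(roster)
}

#' Read a game summary file
#'
#' One row per game side: shots on target (including goals) for that side.
#' The optional `coded` column marks whether the side's player events were
#' coded (both sides of an SSG are; only the academy side of an 11-vs-11
#' half is, while the opponent side still contributes the
#' shots-on-target-conceded proxy). Absent column means all sides coded.
#'
#' @param path CSV path.
#' @return tibble of game sides.
#' @export
read_games <- function(path) {
  games <- readr::read_csv(path, show_col_types = FALSE,
                           col_types = readr::cols(
                             game_id = "c", format = "c", team = "c",
                             side_team_id = "c",
                             shots_on_target = "i", .default = "?"
                           ))
  missing <- setdiff(games_cols, names(games))
  if (length(missing) > 0) {
    stop("games file is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  validate_games(games)
}

validate_games <- function(games) {
  if (!"coded" %in% names(games)) games$coded <- TRUE
  if (!all(games$format %in% c("SSG", "M11"))) {
    stop("games: format must be SSG or M11", call. = FALSE)
  }
  if (any(games$shots_on_target < 0)) {
    stop("games: negative shots_on_target", call. = FALSE)
  }
  sides <- table(games$game_id)
  if (any(sides != 2)) {
    stop("games: each game_id must have exactly two sides; offending: ",
         paste(utils::head(names(sides)[sides != 2], 5), collapse = ", "),
         call. = FALSE)
  }
  one_format <- tapply(games$format, games$game_id,
                       function(x) length(unique(x)) == 1)
  if (!all(one_format)) {
    stop("games: a game_id maps to more than one format", call. = FALSE)
  }
  tibble::as_tibble(games)
}

#' Read and validate an event log
#'
#' One row per coded on-ball event. Validation enforces the coding scheme:
#' known raw indicator labels only, a success/failure outcome if and only if
#' the indicator is binary-outcome, and (when a roster is supplied)
#' referential integrity of `player_id`. Violations are rejected with the
#' offending row numbers.
#'
#' @param path CSV path.
#' @param roster optional roster tibble for referential checks.
#' @return tibble of validated event records.
#' @export
read_events <- function(path, roster = NULL) {
  events <- readr::read_csv(path, show_col_types = FALSE,
                            col_types = readr::cols(.default = "c"))
  missing <- setdiff(events_cols, names(events))
  if (length(missing) > 0) {
    stop("events file is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  validate_events(events, roster = roster)
}

#' Validate an in-memory event collection
#'
#' @param events tibble with the event schema columns.
#' @param roster optional roster tibble; when given, every `player_id` must
#'   appear in it.
#' @return the validated tibble (outcome normalised to
#'   success/failure/`NA`).
#' @export
validate_events <- function(events, roster = NULL) {
  events <- tibble::as_tibble(events)
  events$outcome[!is.na(events$outcome) & events$outcome == ""] <- NA_character_
  fail_rows <- function(what, rows) {
    stop("events: ", what, " at row(s) ",
         paste(utils::head(rows, 5), collapse = ", "),
         if (length(rows) > 5) sprintf(" (and %d more)", length(rows) - 5),
         call. = FALSE)
  }
  bad <- which(!events$format %in% c("SSG", "M11"))
  if (length(bad) > 0) fail_rows("format must be SSG or M11", bad)
  tax <- indicator_taxonomy(include_merged = FALSE)
  bad <- which(!events$indicator %in% tax$indicator)
  if (length(bad) > 0) fail_rows("unknown indicator label", bad)
  otype <- stats::setNames(tax$outcome_type, tax$indicator)[events$indicator]
  bad <- which(otype == "count" & !is.na(events$outcome))
  if (length(bad) > 0) {
    fail_rows("outcome given for a count-type indicator", bad)
  }
  bad <- which(otype == "binary" &
                 (is.na(events$outcome) |
                    !events$outcome %in% c("success", "failure")))
  if (length(bad) > 0) {
    fail_rows("binary indicator requires outcome success/failure", bad)
  }
  if (!is.null(roster)) {
    bad <- which(!events$player_id %in% roster$player_id)
    if (length(bad) > 0) fail_rows("player_id not in roster", bad)
  }
  # one format and one age-category team per game
  if (nrow(events) > 0) {
    key <- tapply(paste(events$format, events$team), events$game_id,
                  function(x) length(unique(x)) == 1)
    if (!all(key)) {
      stop("events: a game_id maps to more than one format or team",
           call. = FALSE)
    }
  }
  events
}

#' Read a full study from a directory
#'
#' Expects `events.csv`, `roster.csv` and `games.csv` as written by
#' [write_study()] (or by the synthetic generator).
#'
#' @param dir directory path.
#' @return list with elements `events`, `roster`, `games` (and `truth` if a
#'   `ground_truth.json` is present).
#' @export
read_study <- function(dir) {
  roster <- read_roster(file.path(dir, "roster.csv"))
  study <- list(
    events = read_events(file.path(dir, "events.csv"), roster = roster),
    roster = roster,
    games = read_games(file.path(dir, "games.csv"))
  )
  gt <- file.path(dir, "ground_truth.json")
  if (file.exists(gt)) {
    study$truth <- jsonlite::read_json(gt, simplifyVector = TRUE)
  }
  class(study) <- c("ssg_study", class(study))
  study
}

#' Write a study to a directory
#'
#' Writes `events.csv`, `roster.csv`, `games.csv` and, when ground truth is
#' attached, `ground_truth.json` (full double precision, so the truth
#' round-trips losslessly).
#'
#' @param study list with `events`, `roster`, `games`, optional `truth`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  roster <- study$roster
  roster$agility_mean <- NULL  # derived column, not part of the file schema
  readr::write_csv(study$events, file.path(dir, "events.csv"), na = "")
  readr::write_csv(roster, file.path(dir, "roster.csv"), na = "")
  readr::write_csv(study$games, file.path(dir, "games.csv"), na = "")
  if (!is.null(study$truth)) {
    jsonlite::write_json(study$truth, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(dir)
}

#' Published per-format event counts
#'
#' Total observed events per raw performance indicator in each game format,
#' as published for the original study (11 indicators; 5213 events in the
#' 11-vs-11 halves, 6060 in the SSGs). These counts are the input to the
#' representativeness analysis when raw event logs are unavailable.
#'
#' @return tibble with columns `indicator`, `observed_m11`, `observed_ssg`.
#' @export
published_event_counts <- function() {
  path <- system.file("extdata", "published_event_counts.csv",
                      package = "ssgvalidity", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(indicator = "c", .default = "i"))
}
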