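#' Performance-indicator coding scheme
#'
#' The taxonomy of on-ball performance indicators used throughout the
#' package: eleven raw indicators as they are coded from video, plus two
#' merged labels (`offensive_duel` = dribble + take-on, `defensive_duel` =
#' tackle + staying-in-front) that only ever arise from [merge_indicators()].
#'
#' Each indicator belongs to one side of play (`offense` or `defense`) and
#' has one outcome type: `binary` indicators carry a success/failure outcome
#' on every event, `count` indicators are simply counted when they occur and
#' carry no outcome.
#'
#' @param include_merged logical; include the two merged duel labels.
#' @return A tibble with columns `indicator`, `side`, `outcome_type`,
#'   `merged_into` (`NA` for indicators that are not merged) and `merged`
#'   (`TRUE` for the two merged labels themselves).
#' @export
#' @examples
#' indicator_taxonomy()
indicator_taxonomy <- function(include_merged = TRUE) {
  raw <- tibble::tribble(
    ~indicator,              ~side,      ~outcome_type, ~merged_into,
    "pass_forward",          "offense",  "binary",      NA_character_,
    "dribble",               "offense",  "binary",      "offensive_duel",
    "take_on",               "offense",  "binary",      "offensive_duel",
    "chance_created",        "offense",  "count",       NA_character_,
    "shot_on_target",        "offense",  "count",       NA_character_,
    "offensive_aerial_duel", "offense",  "binary",      NA_character_,
    "tackle",                "defense",  "binary",      "defensive_duel",
    "staying_in_front",      "defense",  "binary",      "defensive_duel",
    "applying_pressure",     "defense",  "count",       NA_character_,
    "pass_interception",     "defense",  "count",       NA_character_,
    "defensive_aerial_duel", "defense",  "binary",      NA_character_
  )
  raw$merged <- FALSE
  if (!include_merged) {
    return(raw)
  }
  merged <- tibble::tribble(
    ~indicator,       ~side,     ~outcome_type, ~merged_into,
    "offensive_duel", "offense", "binary",      NA_character_,
    "defensive_duel", "defense", "binary",      NA_character_
  )
  merged$merged <- TRUE
  dplyr::bind_rows(raw, merged)
}

#' Raw indicator labels accepted in input event files
#' @return character vector of the eleven raw labels.
#' @export
raw_indicators <- function() {
  indicator_taxonomy(include_merged = FALSE)$indicator
}

#' Count-type indicators (rate statistics)
#' @return character vector of indicators counted when they occur.
#' @export
count_indicators <- function() {
  tax <- indicator_taxonomy(include_merged = FALSE)
  tax$indicator[tax$outcome_type == "count"]
}

#' Binary-outcome indicators in the merged (player-quantification) view
#'
#' Aerial duels are excluded: more than half of the players have no aerial
#' duel events in SSGs, so they do not enter the individual analysis.
#' @return character vector: pass_forward, offensive_duel, defensive_duel.
#' @export
binary_indicators_merged <- function() {
  c("pass_forward", "offensive_duel", "defensive_duel")
}

#' Merge duel indicators for the player-quantification view
#'
#' Relabels `dribble` and `take_on` as `offensive_duel`, and `tackle` and
#' `staying_in_front` as `defensive_duel`. Outcomes and all other columns
#' are preserved; total event counts are unchanged. The representativeness
#' analysis keeps the raw labels, so both views derive from the same input.
#'
#' @param events event tibble with a raw `indicator` column.
#' @return The same tibble with merged duel labels.
#' @export
merge_indicators <- function(events) {
  stopifnot(is.data.frame(events), "indicator" %in% names(events))
  tax <- indicator_taxonomy(include_merged = FALSE)
  unknown <- setdiff(unique(events$indicator), tax$indicator)
  if (length(unknown) > 0) {
    stop("merge_indicators(): unknown raw indicator label(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  map <- stats::setNames(
    ifelse(is.na(tax$merged_into), tax$indicator, tax$merged_into),
    tax$indicator
  )
  events$indicator <- unname(map[events$indicator])
  events
}
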