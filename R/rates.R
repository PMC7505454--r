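#' Rate statistics per six-minute bout
#'
#' Converts the count-type indicators (pass interceptions, applying
#' pressure, chances created, shots on target) to events per six-minute
#' bout: rate = 6 x (event count) / (player's total minutes in the format).
#' Every player in `roster` gets one row per count indicator; players with
#' no events get rate 0.
#'
#' @param events validated event tibble (raw or merged labels; count
#'   indicators are untouched by merging).
#' @param roster roster tibble of the players to score (post-exclusion).
#' @param format `"SSG"` or `"M11"`.
#' @return tibble `player_id`, `format`, `indicator`, `n_events`,
#'   `exposure_min`, `rate`.
#' @export
events_per_bout <- function(events, roster, format = c("SSG", "M11")) {
  format <- match.arg(format)
  minutes_col <- if (format == "SSG") "minutes_ssg" else "minutes_m11"
  exposure <- stats::setNames(roster[[minutes_col]], roster$player_id)
  if (any(exposure <= 0)) {
    stop("events_per_bout(): player(s) with zero ", format,
         " minutes in roster: ",
         paste(utils::head(names(exposure)[exposure <= 0], 5), collapse = ", "),
         "; exclude them upstream", call. = FALSE)
  }
  counts <- events |>
    dplyr::filter(.data$format == !!format,
                  .data$indicator %in% count_indicators(),
                  .data$player_id %in% roster$player_id) |>
    dplyr::count(.data$player_id, .data$indicator, name = "n_events")
  grid <- tidyr::expand_grid(player_id = roster$player_id,
                             indicator = count_indicators())
  grid |>
    dplyr::left_join(counts, by = c("player_id", "indicator")) |>
    dplyr::mutate(
      n_events = dplyr::coalesce(.data$n_events, 0L),
      format = !!format,
      exposure_min = unname(exposure[.data$player_id]),
      rate = 6 * .data$n_events / .data$exposure_min
    ) |>
    dplyr::select("player_id", "format", "indicator", "n_events",
                  "exposure_min", "rate")
}
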