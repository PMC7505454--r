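#' Run the full analysis pipeline
#'
#' Orchestrates the end-to-end analysis on an event-coded study:
#' player exclusions, duel merging, rate statistics, random-intercept
#' logistic posterior scores, success-proxy weight derivation, composite
#' offensive/defensive scores per format, the representativeness report,
#' and the two validity tables (SSG vs 11-vs-11 scores; physiological and
#' motor tests vs 11-vs-11 composites). All steps are deterministic given
#' the inputs and settings.
#'
#' When `out_dir` is given, report files are written there:
#' `repr_report.csv`, `fig_rates.csv` (mean events per bout by format),
#' `weights.json`, `composite_scores.csv`, `validity_indicators.csv`,
#' `validity_tests.csv`, `success_models.json`, `exclusions.csv` and a
#' `manifest.json` (settings, input hashes, package version) sufficient to
#' reproduce the run.
#'
#' @param events,roster,games validated study tables (see [read_study()]).
#' @param out_dir optional output directory.
#' @param weights_source `"derived"` (from the data via [derive_weights()])
#'   or `"published"` (fixed weights of [table_weights()]).
#' @param binary_stat team-game statistic for binary indicators in weight
#'   derivation (see [team_game_indicator_totals()]).
#' @param n_agq quadrature setting for the success models.
#' @param min_n minimum group size for every meta-analysis.
#' @param exclude apply the player-exclusion policy first.
#' @return list of class `ssg_pipeline`: `roster` (retained), `exclusions`,
#'   `scores` (per format), `fits`, `weights`, `composites` (per format),
#'   `representativeness`, `rates_by_format`, `validity_indicators`,
#'   `validity_tests`, `settings`.
#' @export
run_pipeline <- function(events, roster, games, out_dir = NULL,
                         weights_source = c("derived", "published"),
                         binary_stat = c("success_count", "success_prop"),
                         n_agq = 1, min_n = 4, exclude = TRUE) {
  weights_source <- match.arg(weights_source)
  binary_stat <- match.arg(binary_stat)
  events <- validate_events(events, roster = roster)
  games <- validate_games(games)

  exclusions <- tibble::tibble(player_id = character(), team = character(),
                               reason = character())
  retained <- roster
  if (exclude) {
    ex <- exclude_players(roster)
    retained <- ex$retained
    exclusions <- ex$excluded
  }
  # defensive: a rate denominator needs positive minutes in both formats
  zero_min <- retained$minutes_ssg <= 0 | retained$minutes_m11 <= 0
  if (any(zero_min)) {
    warning("run_pipeline(): dropping ", sum(zero_min),
            " player(s) with zero minutes in a format", call. = FALSE)
    exclusions <- dplyr::bind_rows(exclusions, tibble::tibble(
      player_id = retained$player_id[zero_min],
      team = retained$team[zero_min],
      reason = "zero minutes in a format"
    ))
    retained <- retained[!zero_min, , drop = FALSE]
  }
  ev_kept <- events[events$player_id %in% retained$player_id, , drop = FALSE]

  scored <- list(
    SSG = score_players(ev_kept, retained, "SSG", n_agq = n_agq),
    M11 = score_players(ev_kept, retained, "M11", n_agq = n_agq)
  )

  weights <- if (weights_source == "derived") {
    totals <- team_game_indicator_totals(ev_kept, games,
                                         binary_stat = binary_stat)
    derive_weights(totals, min_n = min_n)
  } else {
    table_weights()
  }

  composites <- lapply(scored, function(s) {
    composite_scores(s$scores, retained, weights = weights)
  })

  counts <- format_event_totals(events)
  repr <- representativeness_report(counts)
  rates_fig <- mean_events_per_bout_by_format(events, games)

  validity_ind <- predictive_validity(
    dplyr::bind_rows(
      scored$SSG$scores,
      tidyr::pivot_longer(composites$SSG, c("offensive", "defensive"),
                          names_to = "indicator", values_to = "score")
    ),
    dplyr::bind_rows(
      scored$M11$scores,
      tidyr::pivot_longer(composites$M11, c("offensive", "defensive"),
                          names_to = "indicator", values_to = "score")
    ),
    retained, min_n = min_n
  )
  validity_tst <- test_validity(retained, composites$M11, min_n = min_n)

  out <- structure(list(
    roster = retained, exclusions = exclusions,
    scores = list(SSG = scored$SSG$scores, M11 = scored$M11$scores),
    fits = list(SSG = scored$SSG$fits, M11 = scored$M11$fits),
    weights = weights, composites = composites,
    representativeness = repr, rates_by_format = rates_fig,
    validity_indicators = validity_ind, validity_tests = validity_tst,
    settings = list(weights_source = weights_source,
                    binary_stat = binary_stat, n_agq = n_agq, min_n = min_n,
                    exclude = exclude)
  ), class = "ssg_pipeline")

  if (!is.null(out_dir)) write_pipeline_outputs(out, events, roster, games,
                                                out_dir)
  out
}

write_pipeline_outputs <- function(res, events, roster, games, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, f) readr::write_csv(x, file.path(out_dir, f), na = "")
  w(res$representativeness$gof$table, "repr_report.csv")
  w(res$rates_by_format, "fig_rates.csv")
  w(res$exclusions, "exclusions.csv")
  w(dplyr::bind_rows(res$composites, .id = "format"), "composite_scores.csv")
  w(res$validity_indicators, "validity_indicators.csv")
  w(res$validity_tests, "validity_tests.csv")
  jsonlite::write_json(
    list(weights = res$weights,
         provenance = lapply(attr(res$weights, "provenance"),
                             as.data.frame)),
    file.path(out_dir, "weights.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, na = "null"
  )
  jsonlite::write_json(
    lapply(unlist(res$fits, recursive = FALSE), success_fit_summary),
    file.path(out_dir, "success_models.json"),
    auto_unbox = TRUE, digits = NA, na = "null"
  )
  manifest <- list(
    package = "ssgvalidity",
    version = as.character(utils::packageVersion("ssgvalidity")),
    settings = res$settings,
    input_hash = list(events = rlang::hash(events),
                      roster = rlang::hash(roster),
                      games = rlang::hash(games)),
    n_players_retained = nrow(res$roster),
    n_events = nrow(events)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(out_dir)
}

#' @export
print.ssg_pipeline <- function(x, ...) {
  cat("ssgvalidity pipeline result\n")
  cat(sprintf("  players retained: %d (excluded: %d)\n",
              nrow(x$roster), nrow(x$exclusions)))
  g <- x$representativeness$gof
  cat(sprintf("  representativeness: chi2(%d, N = %d) = %.2f; r_s = %.2f\n",
              g$df, g$n, g$statistic, x$representativeness$distribution_cor$r))
  cat(sprintf("  weights source: %s\n", x$settings$weights_source))
  cat(sprintf("  validity rows: %d indicator, %d test\n",
              nrow(x$validity_indicators), nrow(x$validity_tests)))
  invisible(x)
}
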