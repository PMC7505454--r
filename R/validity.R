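#' Magnitude label for a correlation coefficient
#'
#' Cohen-style interpretation thresholds on |r|: below 0.1 trivial,
#' 0.1 to below 0.3 small, 0.3 to below 0.5 moderate, 0.5 and above large
#' (left-closed boundaries).
#'
#' @param r numeric vector of correlations (between -1 and 1).
#' @return character vector of labels.
#' @export
#' @examples
#' magnitude_label(c(0.05, 0.1, 0.53, -0.28))
magnitude_label <- function(r) {
  if (any(abs(r) > 1, na.rm = TRUE)) {
    stop("magnitude_label(): |r| > 1", call. = FALSE)
  }
  a <- abs(r)
  dplyr::case_when(
    is.na(a) ~ NA_character_,
    a < 0.1 ~ "trivial",
    a < 0.3 ~ "small",
    a < 0.5 ~ "moderate",
    .default = "large"
  )
}

validity_row <- function(data, label, min_n) {
  res <- tryCatch(
    suppressWarnings(
      meta_spearman(data, x = "x", y = "y", group = "team", min_n = min_n)
    ),
    error = function(e) NULL
  )
  if (is.null(res)) return(NULL)
  tibble::tibble(
    predictor = label, r = res$r, ci_low = res$ci_low, ci_high = res$ci_high,
    p = res$p, n = res$n_total, k = res$k, tau2 = res$tau2,
    magnitude = magnitude_label(res$r)
  )
}

#' Predictive validity of SSG scores for 11-vs-11 scores
#'
#' For each performance indicator (and each composite, when present in the
#' score tables), Spearman's rank correlation between the players' SSG
#' score and their 11-vs-11 score is computed within each age-category
#' team over the complete pairs, then aggregated across teams with the
#' DerSimonian-Laird random-effects meta-analysis. Players missing either
#' side of a pair are dropped for that row only (pairwise deletion), so
#' row-wise n varies.
#'
#' @param ssg_scores,m11_scores long tibbles `player_id`, `indicator`,
#'   `score` (one per format).
#' @param roster roster tibble supplying `team`.
#' @param min_n minimum complete pairs per team (default 4).
#' @return validity tibble: `predictor`, aggregated `r`, `ci_low`,
#'   `ci_high`, `p`, pooled `n`, `k`, `tau2`, `magnitude`.
#' @export
predictive_validity <- function(ssg_scores, m11_scores, roster, min_n = 4) {
  paired <- dplyr::inner_join(
    dplyr::select(ssg_scores, "player_id", "indicator", x = "score"),
    dplyr::select(m11_scores, "player_id", "indicator", y = "score"),
    by = c("player_id", "indicator")
  ) |>
    dplyr::left_join(dplyr::select(roster, "player_id", "team"),
                     by = "player_id")
  rows <- lapply(unique(paired$indicator), function(ind) {
    validity_row(paired[paired$indicator == ind, , drop = FALSE], ind, min_n)
  })
  dplyr::bind_rows(rows)
}

#' Predictive validity of physiological and motor tests
#'
#' Team-wise Spearman correlations between each test result (10 m sprint,
#' 30 m sprint, ISRT tracks, mean agility time) and the overall offensive
#' and defensive 11-vs-11 composite scores, aggregated across teams as in
#' [predictive_validity()]. Note that lower sprint and agility times mean
#' better performance, so negative coefficients there indicate that faster
#' players score higher.
#'
#' @param roster roster tibble carrying the test columns and `team`.
#' @param composites tibble `player_id`, `offensive`, `defensive`
#'   ([composite_scores()] on 11-vs-11 scores).
#' @param min_n minimum complete pairs per team.
#' @return validity tibble with one row per test x composite pair
#'   (`predictor` = "<test> vs <composite>").
#' @export
test_validity <- function(roster, composites, min_n = 4) {
  tests <- c("sprint_10m", "sprint_30m", "isrt_tracks", "agility_mean")
  joined <- dplyr::left_join(
    dplyr::select(roster, "player_id", "team",
                  dplyr::all_of(tests)),
    dplyr::select(composites, "player_id", "offensive", "defensive"),
    by = "player_id"
  )
  rows <- list()
  for (test in tests) {
    for (comp in c("offensive", "defensive")) {
      d <- tibble::tibble(team = joined$team, x = joined[[test]],
                          y = joined[[comp]])
      rows[[paste(test, comp)]] <-
        validity_row(d, paste(test, "vs", comp), min_n)
    }
  }
  dplyr::bind_rows(rows)
}

#' Per-player indicator scores for one format
#'
#' Assembles the per-player performance quantification used by the
#' validity analyses: rates per bout for the four count indicators and
#' posterior logit scores from the random-intercept logistic model for the
#' three binary indicators (merged-duel view). A binary indicator whose
#' model cannot be fitted (e.g. complete separation) is skipped with a
#' warning.
#'
#' @param events validated event tibble (raw labels).
#' @param roster roster of players to score (post-exclusion).
#' @param format `"SSG"` or `"M11"`.
#' @param n_agq quadrature setting for [fit_success_model()].
#' @return list with `scores` (long tibble `player_id`, `format`,
#'   `indicator`, `score`) and `fits` (named list of `ssg_success_fit`).
#' @export
score_players <- function(events, roster, format = c("SSG", "M11"),
                          n_agq = 1) {
  format <- match.arg(format)
  rates <- events_per_bout(events, roster, format) |>
    dplyr::select("player_id", "format", "indicator", score = "rate")
  merged <- merge_indicators(events[events$format == format, , drop = FALSE])
  fits <- list()
  posts <- list()
  for (ind in binary_indicators_merged()) {
    ev <- merged[merged$indicator == ind &
                   merged$player_id %in% roster$player_id, , drop = FALSE]
    fit <- tryCatch(fit_success_model(ev, roster, n_agq = n_agq),
                    error = function(e) {
                      warning("score_players(): ", ind, " (", format,
                              ") not scored: ", conditionMessage(e),
                              call. = FALSE)
                      NULL
                    })
    if (is.null(fit)) next
    fits[[ind]] <- fit
    posts[[ind]] <- player_posterior_scores(fit, roster) |>
      dplyr::select("player_id", "format", "indicator", "score")
  }
  list(scores = dplyr::bind_rows(rates, dplyr::bind_rows(posts)),
       fits = fits)
}
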