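#' Mean events per six-minute bout, by indicator and format
#'
#' For each game, the per-indicator event count is scaled to a six-minute
#' bout (6 x count / duration) and then averaged over the games of each
#' format. Default durations are 6 minutes for an SSG and 45 minutes for
#' an 11-vs-11 half; a `durations` tibble (`game_id`, `duration_min`)
#' overrides them.
#'
#' @param events validated event tibble (raw labels).
#' @param games game-side tibble (defines the set of games, including
#'   zero-event ones).
#' @param durations optional tibble `game_id`, `duration_min`.
#' @return tibble `format`, `indicator`, `mean_per_bout`, `n_games`.
#' @export
mean_events_per_bout_by_format <- function(events, games, durations = NULL) {
  game_tbl <- games |>
    dplyr::distinct(.data$game_id, .data$format)
  if (is.null(durations)) {
    game_tbl$duration_min <- ifelse(game_tbl$format == "SSG", 6, 45)
  } else {
    game_tbl <- dplyr::left_join(game_tbl, durations, by = "game_id")
    if (anyNA(game_tbl$duration_min)) {
      stop("mean_events_per_bout_by_format(): missing duration for game(s)",
           call. = FALSE)
    }
  }
  if (any(game_tbl$duration_min <= 0)) {
    stop("mean_events_per_bout_by_format(): zero or negative game duration",
         call. = FALSE)
  }
  counts <- events |>
    dplyr::count(.data$game_id, .data$indicator, name = "n_events")
  tidyr::expand_grid(game_tbl, indicator = raw_indicators()) |>
    dplyr::left_join(counts, by = c("game_id", "indicator")) |>
    dplyr::mutate(n_events = dplyr::coalesce(.data$n_events, 0L),
                  per_bout = 6 * .data$n_events / .data$duration_min) |>
    dplyr::group_by(.data$format, .data$indicator) |>
    dplyr::summarise(mean_per_bout = mean(.data$per_bout),
                     n_games = dplyr::n(), .groups = "drop")
}

#' Goodness of fit of the SSG event-type distribution
#'
#' Chi-square goodness-of-fit test of the observed SSG event counts per
#' indicator against the relative event frequencies of the 11-vs-11 games
#' taken as the theoretical distribution: E_i = N p_i with
#' p_i = O_i^11 / sum(O^11) and N the SSG total, so sum(E) = N exactly.
#' Cell deviations are reported as adjusted standardized residuals
#' s_i = (O_i - E_i) / sqrt(E_i (1 - p_i)), the multinomial form whose
#' variance accounts for the estimated cell proportion.
#'
#' @param observed_ssg named integer vector of SSG counts per indicator.
#' @param reference_m11 named integer vector of 11-vs-11 counts over the
#'   same indicators; all entries must be positive (drop a zero category
#'   explicitly before calling).
#' @return list of class `ssg_gof`: `table` (per-indicator observed,
#'   proportions, expected, residual), `statistic`, `df`, `p_value`, `n`.
#' @export
gof_chi_square <- function(observed_ssg, reference_m11) {
  if (is.null(names(observed_ssg)) || is.null(names(reference_m11)) ||
      !setequal(names(observed_ssg), names(reference_m11))) {
    stop("gof_chi_square(): both vectors must be named over the same ",
         "indicator set", call. = FALSE)
  }
  reference_m11 <- reference_m11[names(observed_ssg)]
  if (any(reference_m11 <= 0)) {
    stop("gof_chi_square(): reference count(s) of zero for: ",
         paste(names(reference_m11)[reference_m11 <= 0], collapse = ", "),
         "; remove the category explicitly", call. = FALSE)
  }
  p <- reference_m11 / sum(reference_m11)
  ht <- suppressWarnings(stats::chisq.test(x = observed_ssg, p = p))
  out <- list(
    table = tibble::tibble(
      indicator = names(observed_ssg),
      observed_m11 = unname(reference_m11),
      prop_m11 = unname(p),
      observed_ssg = unname(observed_ssg),
      prop_ssg = unname(observed_ssg / sum(observed_ssg)),
      expected_ssg = unname(ht$expected),
      std_residual = unname(ht$stdres)
    ),
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = unname(ht$p.value),
    n = sum(observed_ssg)
  )
  class(out) <- "ssg_gof"
  out
}

#' @export
print.ssg_gof <- function(x, ...) {
  p_shown <- if (x$p_value < 0.01) "< 0.01" else sprintf("= %.2f", x$p_value)
  cat(sprintf("Chi-square goodness of fit: chi2(%d, N = %d) = %.2f, p %s\n",
              x$df, x$n, x$statistic, p_shown))
  print(x$table, n = nrow(x$table))
  invisible(x)
}

#' Rank correlation between two event-count distributions
#'
#' Spearman's rank correlation (mid-ranks for ties) between paired
#' per-indicator totals of two game formats, with a Fisher-z 95%
#' confidence interval (SE 1/sqrt(k - 3)) computed on the unrounded
#' coefficient.
#'
#' @param counts_a,counts_b paired numeric vectors (k >= 4).
#' @param conf confidence level.
#' @return list `r`, `n`, `ci_low`, `ci_high`.
#' @export
distribution_rank_correlation <- function(counts_a, counts_b, conf = 0.95) {
  spearman_fisher_ci(counts_a, counts_b, conf = conf)
}

#' Full representativeness report
#'
#' Runs the goodness-of-fit test and the distribution rank correlation on
#' per-indicator totals, plus (when raw events are supplied) the mean
#' events per bout by format. The aerial-duel sensitivity re-run drops both
#' aerial categories and recomputes everything on the reduced indicator
#' set.
#'
#' @param counts tibble `indicator`, `observed_m11`, `observed_ssg` (e.g.
#'   [published_event_counts()] or totals computed from events).
#' @param drop_aerial logical; also report the re-run without the two
#'   aerial-duel categories.
#' @return list with `gof`, `distribution_cor` and, when `drop_aerial`,
#'   `gof_no_aerial`, `distribution_cor_no_aerial`.
#' @export
representativeness_report <- function(counts, drop_aerial = TRUE) {
  o_ssg <- stats::setNames(counts$observed_ssg, counts$indicator)
  o_m11 <- stats::setNames(counts$observed_m11, counts$indicator)
  out <- list(
    gof = gof_chi_square(o_ssg, o_m11),
    distribution_cor = distribution_rank_correlation(o_m11, o_ssg)
  )
  if (drop_aerial) {
    keep <- !grepl("aerial", names(o_ssg))
    out$gof_no_aerial <- gof_chi_square(o_ssg[keep], o_m11[keep])
    out$distribution_cor_no_aerial <-
      distribution_rank_correlation(o_m11[keep], o_ssg[keep])
  }
  out
}

#' Per-indicator per-format totals from raw events
#'
#' @param events validated event tibble (raw labels).
#' @return tibble `indicator`, `observed_m11`, `observed_ssg` over the raw
#'   indicator set (zero-count indicators included).
#' @export
format_event_totals <- function(events) {
  tidyr::expand_grid(indicator = raw_indicators(),
                     format = c("M11", "SSG")) |>
    dplyr::left_join(
      dplyr::count(events, .data$indicator, .data$format, name = "n"),
      by = c("indicator", "format")
    ) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L)) |>
    tidyr::pivot_wider(names_from = "format", values_from = "n") |>
    dplyr::rename(observed_m11 = "M11", observed_ssg = "SSG")
}
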