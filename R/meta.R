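#' Spearman correlation with a Fisher-z confidence interval
#'
#' Spearman's rank correlation (mid-ranks for ties) with a normal-theory
#' 95% confidence interval on the Fisher-z scale, using standard error
#' 1/sqrt(n - 3) and the unrounded coefficient.
#'
#' @param x,y paired numeric vectors; incomplete pairs are dropped.
#' @param conf confidence level (default 0.95).
#' @return list with `r`, `n`, `ci_low`, `ci_high`.
#' @export
spearman_fisher_ci <- function(x, y, conf = 0.95) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("spearman_fisher_ci(): need at least 4 complete pairs",
                  call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("spearman_fisher_ci(): constant input; correlation undefined",
         call. = FALSE)
  }
  r <- stats::cor(x, y, method = "spearman")
  z <- atanh(clamp_r(r))
  half <- stats::qnorm(1 - (1 - conf) / 2) / sqrt(n - 3)
  list(r = r, n = n, ci_low = tanh(z - half), ci_high = tanh(z + half))
}

# keep atanh finite for |r| = 1 (e.g. perfectly concordant small groups)
clamp_r <- function(r, eps = 1e-12) pmin(pmax(r, -1 + eps), 1 - eps)

#' DerSimonian-Laird random-effects aggregation of correlations
#'
#' Aggregates per-group correlation coefficients on the Fisher-z scale:
#' z_i = atanh(r_i) with within-group variance v_i = 1/(n_i - 3);
#' between-group variance tau^2 by the (non-iterative) DerSimonian-Laird
#' moment estimator, truncated at 0; inverse-variance weights
#' w_i = 1/(v_i + tau^2); the weighted mean is back-transformed with a
#' normal-theory confidence interval and a two-sided p-value from the
#' aggregate z-statistic. With a single group the estimate reduces to that
#' group's coefficient.
#'
#' @param r per-group correlation coefficients.
#' @param n per-group sample sizes (each > 3).
#' @param conf confidence level (default 0.95).
#' @return list with `r` (aggregated, back-transformed), `ci_low`,
#'   `ci_high`, `p`, `tau2`, `q`, `k`, `n_total` and the per-group inputs.
#' @export
#' @examples
#' meta_fisher_dl(r = c(0.2, 0.6), n = c(20, 20))
meta_fisher_dl <- function(r, n, conf = 0.95) {
  stopifnot(length(r) == length(n), length(r) >= 1)
  if (any(n <= 3)) stop("meta_fisher_dl(): every group needs n > 3",
                        call. = FALSE)
  if (any(abs(r) > 1)) stop("meta_fisher_dl(): |r| > 1", call. = FALSE)
  k <- length(r)
  z <- atanh(clamp_r(r))
  v <- 1 / (n - 3)
  w <- 1 / v
  z_fixed <- sum(w * z) / sum(w)
  q <- sum(w * (z - z_fixed)^2)
  tau2 <- if (k > 1) max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w))) else 0
  w_star <- 1 / (v + tau2)
  z_bar <- sum(w_star * z) / sum(w_star)
  se <- sqrt(1 / sum(w_star))
  half <- stats::qnorm(1 - (1 - conf) / 2) * se
  p <- 2 * stats::pnorm(-abs(z_bar / se))
  # exact homogeneity: return the common coefficient unclamped
  r_bar <- if (max(r) - min(r) < 1e-14) r[[1]] else tanh(z_bar)
  list(r = r_bar, ci_low = tanh(z_bar - half), ci_high = tanh(z_bar + half),
       p = p, tau2 = tau2, q = q, k = k, n_total = sum(n),
       groups = tibble::tibble(r = r, n = n, z = z, v = v))
}

#' Meta-analytic Spearman correlation over groups
#'
#' Computes Spearman's rank correlation within each group (after dropping
#' incomplete pairs), then aggregates the coefficients with
#' [meta_fisher_dl()]. Groups with fewer than `min_n` complete pairs or
#' with zero variance in either variable are skipped with a warning.
#'
#' @param data data frame with the pairing.
#' @param x,y,group column names (strings) of the two paired variables and
#'   the grouping variable.
#' @param min_n minimum complete pairs per group (default 4).
#' @param conf confidence level.
#' @return as [meta_fisher_dl()], with a `groups` tibble carrying the group
#'   labels and per-group `r` and `n`, plus `n_total` (pooled complete
#'   pairs over used groups).
#' @export
meta_spearman <- function(data, x = "x", y = "y", group = "group",
                          min_n = 4, conf = 0.95) {
  stopifnot(all(c(x, y, group) %in% names(data)))
  split_idx <- split(seq_len(nrow(data)), data[[group]])
  rs <- c(); ns <- c(); labels <- c()
  for (g in names(split_idx)) {
    xs <- data[[x]][split_idx[[g]]]
    ys <- data[[y]][split_idx[[g]]]
    ok <- stats::complete.cases(xs, ys)
    xs <- xs[ok]; ys <- ys[ok]
    if (length(xs) < min_n) {
      warning("meta_spearman(): group ", g, " skipped (n = ", length(xs),
              " < ", min_n, ")", call. = FALSE)
      next
    }
    if (stats::sd(xs) == 0 || stats::sd(ys) == 0) {
      warning("meta_spearman(): group ", g,
              " skipped (zero variance)", call. = FALSE)
      next
    }
    rs <- c(rs, stats::cor(xs, ys, method = "spearman"))
    ns <- c(ns, length(xs))
    labels <- c(labels, g)
  }
  if (length(rs) == 0) {
    stop("meta_spearman(): no usable group", call. = FALSE)
  }
  out <- meta_fisher_dl(rs, ns, conf = conf)
  out$groups$group <- labels
  out
}
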