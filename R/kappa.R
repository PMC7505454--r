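#' Cohen's kappa for inter-rater agreement
#'
#' Chance-corrected agreement between two aligned sequences of category
#' labels, kappa = (p_o - p_e) / (1 - p_e), with the expected agreement
#' p_e from the product of the raters' marginal category proportions. Used
#' as a coding-reliability check (the original study reports kappa = 0.77
#' over three doubly-coded SSGs).
#'
#' @param codes_a,codes_b equal-length vectors of category labels.
#' @return list with `kappa`, `p_observed`, `p_expected`, `n`.
#' @export
#' @examples
#' cohens_kappa(c("A", "A", "B"), c("A", "B", "B"))$kappa
cohens_kappa <- function(codes_a, codes_b) {
  if (length(codes_a) != length(codes_b)) {
    stop("cohens_kappa(): sequences must be aligned and equal length",
         call. = FALSE)
  }
  if (length(codes_a) == 0) stop("cohens_kappa(): empty input", call. = FALSE)
  lev <- sort(unique(c(codes_a, codes_b)))
  a <- factor(codes_a, levels = lev)
  b <- factor(codes_b, levels = lev)
  n <- length(a)
  p_o <- mean(a == b)
  p_e <- sum((table(a) / n) * (table(b) / n))
  if (isTRUE(all.equal(p_e, 1))) {
    stop("cohens_kappa(): expected agreement is 1 (both raters constant ",
         "and equal); kappa undefined", call. = FALSE)
  }
  list(kappa = (p_o - p_e) / (1 - p_e),
       p_observed = p_o, p_expected = unname(p_e), n = n)
}
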