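#' ABBA and BABA pattern weights
#'
#' Weights each polarized site by its fit to the ABBA and BABA patterns
#' using derived-allele frequencies:
#' cABBA = (1 - p1) p2 p3 (1 - p4) and cBABA = p1 (1 - p2) p3 (1 - p4).
#'
#' @param sites a tibble of polarized sites (from [polarize_sites()]), or
#'   any data frame with frequency columns `p1`..`p4`.
#' @return the input with `cABBA` and `cBABA` columns appended.
#' @export
pattern_weights <- function(sites) {
  stopifnot(all(c("p1", "p2", "p3", "p4") %in% names(sites)))
  dplyr::mutate(
    sites,
    cABBA = (1 - .data$p1) * .data$p2 * .data$p3 * (1 - .data$p4),
    cBABA = .data$p1 * (1 - .data$p2) * .data$p3 * (1 - .data$p4)
  )
}

#' Difference of summed ABBA and BABA weights
#'
#' @param weights a data frame with `cABBA` and `cBABA` columns (see
#'   [pattern_weights()]). An empty table gives 0.
#' @return the scalar S = sum(cABBA) - sum(cBABA).
#' @export
s_statistic <- function(weights) {
  if (nrow(weights) == 0) return(0)
  sum(weights$cABBA) - sum(weights$cBABA)
}

stat_result <- function(statistic, num, den, n, positive_denominator) {
  value <- if (n == 0) NA_real_
  else if (positive_denominator && den <= 0) NA_real_
  else if (!positive_denominator && den == 0) NA_real_
  else num / den
  tibble::tibble(statistic = statistic, value = value, numerator = num,
                 denominator = den, n_sites = as.integer(n))
}

# shared numerator over site frequencies
abba_baba_sums <- function(s) {
  w <- (1 - s$p4)
  cabba <- (1 - s$p1) * s$p2 * s$p3 * w
  cbaba <- s$p1 * (1 - s$p2) * s$p3 * w
  list(num = sum(cabba - cbaba), tot = sum(cabba + cbaba))
}

#' Patterson's D statistic
#'
#' D = sum(cABBA - cBABA) / sum(cABBA + cBABA) over all sites. D is exactly
#' antisymmetric under exchanging the P1 and P2 frequencies and lies in
#' \[-1, 1\]. A zero denominator (no sites informative for either pattern)
#' yields a missing value, not an error.
#'
#' @inheritParams pattern_weights
#' @return a one-row tibble: `statistic`, `value`, `numerator`
#'   (the S sum), `denominator`, `n_sites`.
#' @export
d_statistic <- function(sites) {
  s <- abba_baba_sums(sites)
  stat_result("D", s$num, s$tot, nrow(sites), positive_denominator = FALSE)
}

#' f_hom estimator of the introgression proportion
#'
#' Scales the observed S by the S expected if introgression from P3 into
#' P2 had completely homogenized the P2 and P3 allele frequencies: the
#' denominator substitutes p3 for p2, S(P1, P3, P3, O). Missing when the
#' denominator is not positive.
#'
#' @inheritParams pattern_weights
#' @return a one-row tibble as in [d_statistic()].
#' @export
f_hom <- function(sites) {
  s <- abba_baba_sums(sites)
  w <- (1 - sites$p4)
  den <- sum(((1 - sites$p1) * sites$p3 * sites$p3 -
                sites$p1 * (1 - sites$p3) * sites$p3) * w)
  stat_result("fhom", s$num, den, nrow(sites), positive_denominator = TRUE)
}

#' f_G estimator of the introgression proportion
#'
#' Green et al.'s estimator: the denominator treats P2 as a second lineage
#' sampled from P3 by splitting the P3 sample into halves P3a and P3b,
#' S(P1, P3a, P3b, O). The split is deterministic and interleaved by
#' sample order (see [polarize_sites()]). Because the halves are small,
#' f_G can exceed 1 in small windows, especially with low recombination;
#' values are reported as-is. Missing when the denominator is not positive.
#'
#' @param sites polarized sites containing `p3a` and `p3b` columns
#'   (produced by [polarize_sites()]).
#' @return a one-row tibble as in [d_statistic()].
#' @export
f_g <- function(sites) {
  stopifnot(all(c("p3a", "p3b") %in% names(sites)))
  s <- abba_baba_sums(sites)
  w <- (1 - sites$p4)
  den <- sum(((1 - sites$p1) * sites$p3a * sites$p3b -
                sites$p1 * (1 - sites$p3a) * sites$p3b) * w)
  stat_result("fG", s$num, den, nrow(sites), positive_denominator = TRUE)
}

#' f_d, the dynamic estimator of the introgression proportion
#'
#' At each site the donor population P_D is whichever of P2 and P3 has the
#' higher derived-allele frequency (P3 on ties; either choice yields the
#' same denominator term), and the denominator substitutes P_D for both,
#' S(P1, P_D, P_D, O). This maximizes the denominator site by site, so on
#' windows with D >= 0, f_d lies in \[0, 1\]; windows with D < 0 give
#' negative values that are reported but should not be interpreted as
#' introgression proportions. Missing when the denominator is not
#' positive.
#'
#' @inheritParams pattern_weights
#' @return a one-row tibble as in [d_statistic()].
#' @export
f_d <- function(sites) {
  s <- abba_baba_sums(sites)
  pd <- pmax(sites$p2, sites$p3)
  w <- (1 - sites$p4)
  den <- sum(((1 - sites$p1) * pd * pd - sites$p1 * (1 - pd) * pd) * w)
  stat_result("fd", s$num, den, nrow(sites), positive_denominator = TRUE)
}

#' All four shared-ancestry statistics for a set of sites
#'
#' @inheritParams f_g
#' @return a four-row tibble stacking [d_statistic()], [f_g()], [f_hom()]
#'   and [f_d()].
#' @export
abba_baba_stats <- function(sites) {
  dplyr::bind_rows(d_statistic(sites), f_g(sites), f_hom(sites), f_d(sites))
}

# fast path used by the window scan: plain vectors in, named vector out
site_stats_core <- function(p1, p2, p3, p4, p3a, p3b) {
  w <- 1 - p4
  cabba <- (1 - p1) * p2 * p3 * w
  cbaba <- p1 * (1 - p2) * p3 * w
  num <- sum(cabba - cbaba)
  tot <- sum(cabba + cbaba)
  den_hom <- sum(((1 - p1) * p3 - p1 * (1 - p3)) * p3 * w)
  den_g <- sum(((1 - p1) * p3a - p1 * (1 - p3a)) * p3b * w)
  pd <- pmax(p2, p3)
  den_d <- sum(((1 - p1) * pd - p1 * (1 - pd)) * pd * w)
  c(D = if (tot == 0) NA_real_ else num / tot,
    fG = if (den_g <= 0) NA_real_ else num / den_g,
    fhom = if (den_hom <= 0) NA_real_ else num / den_hom,
    fd = if (den_d <= 0) NA_real_ else num / den_d,
    S = num)
}
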