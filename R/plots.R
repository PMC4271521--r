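#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot window statistics against nucleotide diversity
#'
#' Scatter of D (all windows) and f_d (windows with D >= 0) against mean
#' within-population diversity, the diagnostic for diversity-driven bias
#' in window-based D outliers.
#'
#' @param object a `window_stats_tbl`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.window_stats_tbl <- function(object, ...) {
  w <- tibble::as_tibble(object)
  w$mean_pi <- rowMeans(w[c("pi_P1", "pi_P2", "pi_P3")], na.rm = TRUE)
  long <- dplyr::bind_rows(
    tibble::tibble(mean_pi = w$mean_pi, value = w$D, statistic = "D"),
    tibble::tibble(mean_pi = w$mean_pi[!is.na(w$D) & w$D >= 0],
                   value = w$fd[!is.na(w$D) & w$D >= 0], statistic = "fd")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$mean_pi, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::facet_wrap(~statistic, scales = "free_y") +
    ggplot2::labs(x = "mean nucleotide diversity (pi)", y = "statistic") +
    ggplot2::theme_bw()
}

#' Plot estimator accuracy against the simulated f
#'
#' Mean +/- one standard deviation of each statistic over the simulated
#' introgression proportions, one panel per statistic and direction, with
#' the y = f line of a perfect estimator.
#'
#' @param object an [estimator_accuracy()] tibble.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.estimator_accuracy <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$f, y = .data$mean)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd),
                             size = 0.3) +
    ggplot2::facet_grid(statistic ~ direction) +
    ggplot2::labs(x = "simulated f", y = "estimate (mean +/- sd)") +
    ggplot2::theme_bw()
}

#' Plot outlier d_XY as a percentage of nonoutlier d_XY
#'
#' One point per model: mean P2-P3 d_XY in outlier (or Alternate) windows
#' as a percentage of the nonoutlier (or Background) mean, by scenario.
#'
#' @param object a `model_comparison` tibble (or several row-bound).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.model_comparison <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$scenario,
                                  y = .data$percent_of_nonoutlier,
                                  colour = .data$scenario)) +
    ggplot2::geom_hline(yintercept = 100, linetype = 2, colour = "grey50") +
    ggplot2::geom_jitter(width = 0.15, height = 0) +
    ggplot2::facet_wrap(~partition) +
    ggplot2::labs(y = "outlier P2-P3 dXY, % of nonoutlier") +
    ggplot2::theme_bw() +
    ggplot2::theme(legend.position = "none",
                   axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
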