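#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a d_XY comparison
#' @param x a `dxy_comparison`.
#' @param ... unused.
#' @return the comparison as a plain tibble.
#' @export
tidy.dxy_comparison <- function(x, ...) {
  tibble::as_tibble(unclass_tbl(x))
}

#' Tidy a model-comparison table
#' @param x a `model_comparison`.
#' @param ... unused.
#' @return one row per model as a plain tibble.
#' @export
tidy.model_comparison <- function(x, ...) {
  tibble::as_tibble(unclass_tbl(x))
}

#' One-line summary of a model-comparison run
#' @param x a `model_comparison`.
#' @param ... unused.
#' @return a one-row tibble: number of models, Bonferroni family size,
#'   significance threshold, significant-model count and median percent
#'   of nonoutlier d_XY.
#' @export
glance.model_comparison <- function(x, ...) {
  tibble::tibble(
    n_models = nrow(x),
    m_bonferroni = attr(x, "m") %||% nrow(x),
    alpha = attr(x, "alpha") %||% 0.01,
    n_significant = sum(x$significant, na.rm = TRUE),
    median_percent = stats::median(x$percent_of_nonoutlier, na.rm = TRUE)
  )
}

#' Tidy a chromosome summary
#' @param x a `chromosome_summary`.
#' @param ... unused.
#' @return the per-chromosome tibble.
#' @export
tidy.chromosome_summary <- function(x, ...) x$chromosomes

#' Cross-chromosome correlations of a chromosome summary
#' @param x a `chromosome_summary`.
#' @param ... unused.
#' @return the correlation tibble.
#' @export
glance.chromosome_summary <- function(x, ...) x$correlations

unclass_tbl <- function(x) {
  class(x) <- setdiff(class(x), c("dxy_comparison", "model_comparison",
                                  "window_stats_tbl", "combined_dataset",
                                  "outlier_partition"))
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
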