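#' Select outlier windows for a statistic
#'
#' Outliers are the top `round(top_fraction * n)` values of the chosen
#' statistic among eligible candidates: windows with D > 0 for the D
#' statistic, and windows with D >= 0 (and a non-missing estimate) for the
#' f estimators. If there are fewer candidates than the target count, all
#' candidates become outliers. Ties are broken by window order, so the
#' partition is deterministic and permutation-stable.
#'
#' @param windows a window-statistics tibble with a `D` column and the
#'   requested statistic column.
#' @param statistic one of `"D"`, `"fG"`, `"fhom"`, `"fd"`.
#' @param top_fraction fraction of all windows to take as outliers.
#' @return the input tibble with logical columns `candidate` and
#'   `outlier`, classed `outlier_partition`; attributes record the
#'   statistic and eligibility rule.
#' @export
select_outliers <- function(windows, statistic = c("D", "fd", "fG", "fhom"),
                            top_fraction = 0.1) {
  statistic <- match.arg(statistic)
  stopifnot(top_fraction > 0, top_fraction <= 1)
  if (!statistic %in% names(windows)) {
    stop("statistic column not present: ", statistic)
  }
  v <- windows[[statistic]]
  d <- windows[["D"]]
  candidate <- if (statistic == "D") {
    !is.na(d) & d > 0
  } else {
    !is.na(d) & d >= 0 & !is.na(v)
  }
  target <- round(top_fraction * nrow(windows))
  outlier <- rep(FALSE, nrow(windows))
  idx <- which(candidate)
  if (length(idx) > 0 && target > 0) {
    ord <- idx[order(-v[idx])]   # stable: ties keep window order
    outlier[head(ord, min(target, length(ord)))] <- TRUE
  }
  out <- dplyr::mutate(tibble::as_tibble(windows), candidate = candidate,
                       outlier = outlier)
  attr(out, "statistic") <- statistic
  attr(out, "rule") <- if (statistic == "D") "D > 0" else "D >= 0"
  attr(out, "target") <- target
  class(out) <- c("outlier_partition", class(out))
  out
}

#' One-sided Wilcoxon rank-sum p-value
#'
#' Exact enumeration when the combined sample size is at most 20 and there
#' are no ties; otherwise the normal approximation with tie correction and
#' continuity correction. The default alternative tests whether group A is
#' stochastically smaller than group B.
#'
#' @param a,b numeric vectors.
#' @param alternative `"less"` (default), `"greater"` or `"two.sided"`.
#' @return the p-value, or `NA` if either group is empty.
#' @export
wilcoxon_rank_sum <- function(a, b, alternative = c("less", "greater",
                                                    "two.sided")) {
  alternative <- match.arg(alternative)
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0) return(NA_real_)
  exact <- (length(a) + length(b)) <= 20 && !any(duplicated(c(a, b)))
  suppressWarnings(
    wilcox.test(a, b, alternative = alternative, exact = exact)$p.value
  )
}

#' Bonferroni adjustment
#'
#' @param p raw p-value(s).
#' @param m number of tests.
#' @return `min(1, p * m)` elementwise.
#' @export
bonferroni <- function(p, m) {
  stopifnot(m >= 1)
  p.adjust(p, method = "bonferroni", n = m)
}

#' Compare P2-P3 d_XY between two window sets
#'
#' Splits the windows either by their true simulation labels
#' (Alternate vs Background) or by an outlier partition on a statistic,
#' and tests whether mean P2-P3 d_XY is lower in the Alternate/outlier set
#' (one-sided Wilcoxon rank-sum by default). Reports the outlier mean as a
#' percentage of the nonoutlier mean, and, when true labels are available,
#' the recall (fraction of outliers that are genuine Alternate windows).
#'
#' @param windows a window-statistics tibble with a `dxy_P2P3` column.
#' @param partition `"labels"` to use the `label` column, or a statistic
#'   name passed to [select_outliers()].
#' @param top_fraction passed to [select_outliers()].
#' @param alternative test direction (default `"less"`: outlier d_XY lower).
#' @param dxy_column divergence column to compare.
#' @return a one-row `dxy_comparison` tibble: partition, group sizes,
#'   means, `percent_of_nonoutlier`, `p_value`, `recall`, `status`.
#' @export
compare_dxy <- function(windows, partition = c("labels", "D", "fd", "fG",
                                               "fhom"),
                        top_fraction = 0.1, alternative = "less",
                        dxy_column = "dxy_P2P3") {
  partition <- match.arg(partition)
  stopifnot(dxy_column %in% names(windows))
  if (partition == "labels") {
    stopifnot("label" %in% names(windows))
    outlier <- windows$label == "Alternate"
  } else {
    part <- select_outliers(windows, partition, top_fraction)
    outlier <- part$outlier
  }
  v <- windows[[dxy_column]]
  res <- tibble::tibble(
    partition = partition,
    n_outlier = sum(outlier), n_nonoutlier = sum(!outlier),
    mean_dxy_outlier = NA_real_, mean_dxy_nonoutlier = NA_real_,
    percent_of_nonoutlier = NA_real_, p_value = NA_real_,
    recall = NA_real_, status = "ok"
  )
  if (res$n_outlier == 0 || res$n_nonoutlier == 0) {
    res$status <- if (res$n_outlier == 0) "no_outlier_windows" else
      "no_nonoutlier_windows"
    class(res) <- c("dxy_comparison", class(res))
    return(res)
  }
  res$mean_dxy_outlier <- mean(v[outlier], na.rm = TRUE)
  res$mean_dxy_nonoutlier <- mean(v[!outlier], na.rm = TRUE)
  res$percent_of_nonoutlier <- 100 * res$mean_dxy_outlier /
    res$mean_dxy_nonoutlier
  res$p_value <- wilcoxon_rank_sum(v[outlier], v[!outlier],
                                   alternative = alternative)
  if ("label" %in% names(windows) && partition != "labels") {
    res$recall <- mean(windows$label[outlier] == "Alternate")
  }
  class(res) <- c("dxy_comparison", class(res))
  res
}

#' Evaluate a grid of combined models
#'
#' For every model of a [model_grid()] tibble, simulates the combined
#' Background/Alternate dataset (Background only for null models),
#' partitions the windows (true labels or statistic outliers), compares
#' P2-P3 d_XY and applies a Bonferroni correction over the number of
#' models actually evaluated. A model is flagged significant when the
#' adjusted p-value is below `alpha` AND the outlier mean is below the
#' nonoutlier mean.
#'
#' @param models a [model_grid()] tibble (or subset).
#' @param partition `"labels"` or a statistic name (see [compare_dxy()]).
#' @param windows_per_model total windows per model; combined datasets use
#'   a 90/10 Background/Alternate split, null datasets Background only.
#' @param seed integer seed.
#' @param alpha significance threshold on the adjusted p-value.
#' @param top_fraction passed to [select_outliers()].
#' @return a `model_comparison` tibble: the model parameters joined with
#'   the [compare_dxy()] columns plus `adjusted_p` and `significant`;
#'   attribute `m` records the Bonferroni family size.
#' @export
evaluate_models <- function(models, partition = "labels",
                            windows_per_model = 10000, seed = NULL,
                            alpha = 0.01, top_fraction = 0.1) {
  stopifnot(nrow(models) > 0)
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, nrow(models))
  n_alt <- round(top_fraction * windows_per_model)
  rows <- vector("list", nrow(models))
  for (i in seq_len(nrow(models))) {
    row <- models[i, ]
    mp <- models_from_row(row)
    if (is.null(mp$alternate)) {
      ds <- simulate_combined(mp$background, NULL,
                              n_background = windows_per_model,
                              n_alternate = 0, seed = seeds[i])
    } else {
      ds <- simulate_combined(mp$background, mp$alternate,
                              n_background = windows_per_model - n_alt,
                              n_alternate = n_alt, seed = seeds[i])
    }
    cmp <- compare_dxy(ds, partition = partition,
                       top_fraction = top_fraction)
    rows[[i]] <- dplyr::bind_cols(row, cmp)
  }
  out <- dplyr::bind_rows(rows)
  m <- nrow(models)
  out$adjusted_p <- bonferroni(out$p_value, m)
  out$significant <- !is.na(out$adjusted_p) & out$adjusted_p < alpha &
    out$mean_dxy_outlier < out$mean_dxy_nonoutlier
  attr(out, "m") <- m
  attr(out, "alpha") <- alpha
  class(out) <- c("model_comparison", class(out))
  out
}

#' Count significant models per scenario and partition
#'
#' Summary in the layout of the classic table of simulated-model counts:
#' one row per scenario x partition with the number of models showing a
#' significant P2-P3 d_XY reduction.
#'
#' @param results one `model_comparison` tibble or a list of them.
#' @return a tibble with `scenario`, `partition`, `rho`, `n_models`,
#'   `n_significant`.
#' @export
summarize_models <- function(results) {
  if (inherits(results, "model_comparison")) results <- list(results)
  dplyr::summarise(
    dplyr::group_by(dplyr::bind_rows(lapply(results, tibble::as_tibble)),
                    .data$scenario, .data$partition, .data$rho),
    n_models = dplyr::n(),
    n_significant = sum(.data$significant, na.rm = TRUE),
    .groups = "drop"
  )
}

#' Estimator accuracy over the simulation grid
#'
#' Mean and standard deviation of D, f_G, f_hom and f_d for every grid
#' setting, against the simulated (true) f.
#'
#' @param grid_stats output of [simulate_grid()].
#' @return a tidy tibble: one row per setting x statistic with `mean`,
#'   `sd`, `n` and `n_missing`; classed `estimator_accuracy`.
#' @export
estimator_accuracy <- function(grid_stats) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(grid_stats)[c("direction", "t_gf", "window_length",
                                    "rho", "f", "D", "fG", "fhom", "fd")],
    cols = c("D", "fG", "fhom", "fd"),
    names_to = "statistic", values_to = "value")
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$direction, .data$t_gf, .data$window_length,
                    .data$rho, .data$f, .data$statistic),
    mean = mean(.data$value, na.rm = TRUE),
    sd = sd(.data$value, na.rm = TRUE),
    n = sum(!is.na(.data$value)),
    n_missing = sum(is.na(.data$value)),
    .groups = "drop"
  )
  class(out) <- c("estimator_accuracy", class(out))
  out
}

#' Scaled reproduction of one cell of the model-count table
#'
#' Runs a reduced model grid for one scenario/partition/recombination-rate
#' combination and scales the significant-model count to the size of the
#' full grid (120 gene-flow or structure models, 45 null models).
#'
#' @param scenario passed to [model_grid()].
#' @param partition passed to [evaluate_models()].
#' @param rho per-bp 4Nr.
#' @param n_models number of grid models to run (evenly spaced subsample).
#' @param windows_per_model windows per model.
#' @param seed integer seed.
#' @param alpha significance threshold after Bonferroni over `n_models`.
#' @return a list: `results` (the `model_comparison` tibble),
#'   `n_models`, `n_significant`, `full_grid`, and `scaled_count` =
#'   `n_significant / n_models * full_grid`.
#' @export
table1_cell <- function(scenario, partition = "labels", rho = 0.01,
                        n_models = 10, windows_per_model = 1000,
                        seed = 1, alpha = 0.01) {
  grid <- model_grid(scenario, rho = rho, subsample = n_models)
  res <- evaluate_models(grid, partition = partition,
                         windows_per_model = windows_per_model,
                         seed = seed, alpha = alpha)
  full <- nrow(model_grid(scenario, rho = rho))
  n_sig <- sum(res$significant, na.rm = TRUE)
  list(results = res, n_models = nrow(grid), n_significant = n_sig,
       full_grid = full, scaled_count = n_sig / nrow(grid) * full)
}
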