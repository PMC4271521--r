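#' Window-scan configuration
#'
#' Defaults follow the conventional genome-scan design: nonoverlapping
#' 5-kb windows, discarding windows in which fewer than 3,000 sites have
#' genotype calls for at least half of the individuals.
#'
#' @param window_size window length in bp.
#' @param step step between window starts; defaults to `window_size`
#'   (nonoverlapping).
#' @param min_genotyped_sites minimum number of qualifying sites for a
#'   window to be kept.
#' @param min_called_fraction fraction of individuals that must be called
#'   for a site to qualify ("at least half" uses the ceiling for odd
#'   counts).
#' @param split P3 split rule passed to [polarize_sites()].
#' @param force_p4_zero passed to [polarize_sites()].
#' @param exclude_same_individual passed to [nucleotide_diversity()].
#' @return a `scan_config` list.
#' @export
scan_config <- function(window_size = 5000, step = window_size,
                        min_genotyped_sites = 3000,
                        min_called_fraction = 0.5,
                        split = "interleaved", force_p4_zero = FALSE,
                        exclude_same_individual = TRUE) {
  stopifnot(window_size > 0, step > 0, step <= window_size,
            min_called_fraction > 0, min_called_fraction <= 1,
            min_genotyped_sites >= 0,
            min_genotyped_sites <= window_size)
  structure(list(window_size = window_size, step = step,
                 min_genotyped_sites = min_genotyped_sites,
                 min_called_fraction = min_called_fraction,
                 split = split, force_p4_zero = force_p4_zero,
                 exclude_same_individual = exclude_same_individual),
            class = "scan_config")
}

#' Enumerate scan windows over scaffolds
#'
#' Windows use 0-based half-open coordinates internally, never span
#' scaffold boundaries, and trailing partial windows are kept but flagged.
#'
#' @param scaffolds data frame with columns `scaffold` and `length` (bp).
#' @param config a [scan_config()].
#' @return tibble with `scaffold`, `start`, `end`, `partial`.
#' @export
iterate_windows <- function(scaffolds, config = scan_config()) {
  stopifnot(all(c("scaffold", "length") %in% names(scaffolds)))
  purrr::pmap_dfr(scaffolds[c("scaffold", "length")], function(scaffold, length) {
    if (length <= 0) return(tibble::tibble())
    starts <- seq(0L, max(0L, length - 1L), by = config$step)
    starts <- starts[starts < length]
    ends <- pmin(starts + config$window_size, length)
    tibble::tibble(scaffold = scaffold, start = starts, end = ends,
                   partial = ends - starts < config$window_size)
  })
}

#' Window call-count filter
#'
#' A window is kept iff the number of sites at which at least
#' `min_called_fraction` of the individuals have genotype calls reaches
#' `min_genotyped_sites`.
#'
#' @param called_per_site number of called individuals at each site of the
#'   window.
#' @param n_individuals total number of individuals.
#' @param config a [scan_config()].
#' @return TRUE (keep) or FALSE (discard).
#' @export
window_filter <- function(called_per_site, n_individuals,
                          config = scan_config()) {
  need <- ceiling(config$min_called_fraction * n_individuals)
  sum(called_per_site >= need) >= config$min_genotyped_sites
}

window_stat_names <- function() {
  c("sites", "sitesUsed", "D", "fG", "fhom", "fd", "S",
    "pi_P1", "pi_P2", "pi_P3", "dxy_P1P2", "dxy_P1P3", "dxy_P2P3")
}

# All per-window statistics on an integer-coded alignment. `indiv` maps
# haplotype rows to individuals (NULL = every haplotype is an individual).
window_stats_core <- function(hint, gid, config = scan_config(),
                              indiv = NULL, complete = FALSE) {
  L <- ncol(hint)
  if (complete && !config$force_p4_zero) {
    # no-missing-data fast path: one C++ pass over the alignment
    sp <- split_p3(gid, config$split)
    g6 <- gid
    g6[sp$a] <- 5L
    g6[sp$b] <- 6L
    v <- .window_core_cpp(hint, as.integer(g6))
    ratio <- function(num, den, positive) {
      if ((positive && den <= 0) || (!positive && den == 0)) NA_real_
      else num / den
    }
    return(c(sites = L, sitesUsed = v[["sitesUsed"]],
             D = ratio(v[["num"]], v[["tot"]], FALSE),
             fG = ratio(v[["num"]], v[["den_g"]], TRUE),
             fhom = ratio(v[["num"]], v[["den_hom"]], TRUE),
             fd = ratio(v[["num"]], v[["den_d"]], TRUE),
             S = v[["num"]],
             v[c("pi_P1", "pi_P2", "pi_P3", "dxy_P1P2", "dxy_P1P3",
                 "dxy_P2P3")]))
  }
  iv <- if (is.null(indiv)) seq_len(nrow(hint)) else as.integer(factor(indiv))
  n_ind <- length(unique(iv))
  {
    called_hap <- hint >= 0L
    per_ind <- rowsum(1L * called_hap, iv)          # individuals x sites
    hap_per_ind <- tabulate(iv)
    called_indiv <- colSums(per_ind == hap_per_ind)
  }
  need <- ceiling(config$min_called_fraction * n_ind)
  sites <- sum(called_indiv >= need)

  pol <- polarize_core(hint, gid, split = config$split,
                       force_p4_zero = config$force_p4_zero)
  n_used <- sum(pol$keep)
  st <- if (n_used > 0) {
    site_stats_core(pol$p[[1]], pol$p[[2]], pol$p[[3]], pol$p[[4]],
                    pol$p3a, pol$p3b)
  } else {
    c(D = NA_real_, fG = NA_real_, fhom = NA_real_, fd = NA_real_, S = 0)
  }
  div <- diversity_core(hint, gid, indiv = iv,
                        exclude_same_individual = config$exclude_same_individual &&
                          !is.null(indiv))
  c(sites = sites, sitesUsed = n_used, st, div)
}

#' Compute all window statistics for one alignment window
#'
#' @param haplotypes allele matrix (haplotypes x sites).
#' @param groups group assignment as in [polarize_sites()].
#' @param config a [scan_config()].
#' @param individuals optional haplotype-to-individual map (used for the
#'   call filter and for excluding within-individual pairs from pi).
#' @return a one-row tibble of window statistics (counts `sites` and
#'   `sitesUsed`, D, fG, fhom, fd, S, pi per population, d_XY per pair).
#' @export
window_stats <- function(haplotypes, groups, config = scan_config(),
                         individuals = NULL) {
  hint <- encode_haplotypes(haplotypes)
  gid <- resolve_groups(groups, rownames(hint), nrow(hint))
  v <- window_stats_core(hint, gid, config, indiv = individuals)
  tibble::as_tibble(as.list(v))
}

#' Scan a set of per-window alignments
#'
#' Each alignment is treated as one genomic window (the per-window FASTA
#' input convention). Windows failing the call filter are dropped.
#'
#' @param alignments a named list of allele matrices (haplotypes x sites).
#' @param groups group assignment shared by all windows.
#' @param config a [scan_config()].
#' @param individuals optional haplotype-to-individual map.
#' @return a `window_stats_tbl` tibble, one row per retained window.
#' @export
scan_alignments <- function(alignments, groups, config = scan_config(),
                            individuals = NULL) {
  if (length(alignments) == 0) return(empty_window_tbl())
  ids <- names(alignments)
  if (is.null(ids)) ids <- paste0("window_", seq_along(alignments))
  first <- encode_haplotypes(alignments[[1]])
  gid <- resolve_groups(groups, rownames(first), nrow(first))
  rows <- vector("list", length(alignments))
  keep <- logical(length(alignments))
  for (i in seq_along(alignments)) {
    hint <- encode_haplotypes(alignments[[i]])
    v <- window_stats_core(hint, gid, config, indiv = individuals)
    keep[i] <- v[["sites"]] >= config$min_genotyped_sites
    rows[[i]] <- v
  }
  out <- tibble::as_tibble(do.call(rbind, rows))
  out <- dplyr::bind_cols(
    tibble::tibble(scaffold = ids,
                   start = 0,
                   end = vapply(alignments, ncol, 1L)),
    out
  )[keep, ]
  class(out) <- c("window_stats_tbl", class(out))
  out
}

empty_window_tbl <- function() {
  out <- tibble::as_tibble(setNames(
    as.list(rep(NA_real_, length(window_stat_names()))),
    window_stat_names()))[0, ]
  out <- dplyr::bind_cols(
    tibble::tibble(scaffold = character(), start = double(), end = double()),
    out)
  class(out) <- c("window_stats_tbl", class(out))
  out
}

#' Write a window-statistics table
#'
#' Writes the fixed tab-separated layout (scaffold, start, end, sites,
#' sitesUsed, D, fG, fhom, fd, S, pi_P1..pi_P3, dxy_P1P2, dxy_P1P3,
#' dxy_P2P3). Coordinates are converted from the internal 0-based
#' half-open convention to 1-based inclusive; missing values are `NA`.
#'
#' @param windows a window-statistics tibble.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_window_table <- function(windows, path) {
  cols <- c("scaffold", "start", "end", window_stat_names())
  out <- windows
  out$start <- out$start + 1
  out <- as.data.frame(out[cols])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Per-chromosome summaries of window statistics
#'
#' For each chromosome: the sample variance of D, the sample variance of
#' f_d over windows with D >= 0, and the mean nucleotide diversity (mean
#' of pi over P1..P3). Pearson correlations of the two variances with mean
#' diversity are computed across chromosomes (degrees of freedom n - 2);
#' degenerate cases (a constant column, fewer than 3 chromosomes) give
#' missing correlations.
#'
#' @param windows a window-statistics tibble.
#' @param chromosome_map data frame with columns `scaffold` and
#'   `chromosome`; omit to treat each scaffold as a chromosome.
#' @return an object of class `chromosome_summary`: a list with tibbles
#'   `chromosomes` and `correlations`.
#' @export
summarize_chromosomes <- function(windows, chromosome_map = NULL) {
  w <- tibble::as_tibble(windows)
  if (!is.null(chromosome_map)) {
    w <- dplyr::inner_join(w, tibble::as_tibble(chromosome_map),
                           by = "scaffold")
  } else {
    w$chromosome <- w$scaffold
  }
  w$mean_pi_win <- rowMeans(w[c("pi_P1", "pi_P2", "pi_P3")], na.rm = TRUE)
  per <- dplyr::summarise(
    dplyr::group_by(w, .data$chromosome),
    n_windows = dplyr::n(),
    var_D = if (sum(!is.na(.data$D)) >= 2) var(.data$D, na.rm = TRUE) else NA_real_,
    var_fd = {
      v <- .data$fd[!is.na(.data$D) & .data$D >= 0 & !is.na(.data$fd)]
      if (length(v) >= 2) var(v) else NA_real_
    },
    mean_pi = mean(.data$mean_pi_win, na.rm = TRUE),
    .groups = "drop"
  )
  cors <- dplyr::bind_rows(
    chr_cor(per$var_D, per$mean_pi, "var_D_vs_mean_pi"),
    chr_cor(per$var_fd, per$mean_pi, "var_fd_vs_mean_pi")
  )
  structure(list(chromosomes = per, correlations = cors),
            class = "chromosome_summary")
}

chr_cor <- function(x, y, label) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3 || sd(x[ok]) == 0 || sd(y[ok]) == 0) {
    return(tibble::tibble(comparison = label, r = NA_real_,
                          df = max(0L, sum(ok) - 2L), p_value = NA_real_))
  }
  ct <- cor.test(x[ok], y[ok], method = "pearson")
  tibble::tibble(comparison = label, r = unname(ct$estimate),
                 df = unname(ct$parameter), p_value = ct$p.value)
}

#' @export
print.chromosome_summary <- function(x, ...) {
  cat("Per-chromosome window-statistic summary\n")
  print(x$chromosomes)
  cat("\nCross-chromosome correlations\n")
  print(x$correlations)
  invisible(x)
}
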