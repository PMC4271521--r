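#' Per-site nucleotide diversity (pi)
#'
#' Mean over haplotype pairs of the number of differences divided by the
#' number of jointly called sites, so each pair contributes equally and
#' missing data are excluded pairwise. Pairs with zero jointly called
#' sites are excluded from the mean.
#'
#' @param haplotypes allele matrix (haplotypes x sites), character or
#'   integer-coded; non-ACGT values are missing.
#' @param individuals optional vector assigning each haplotype to an
#'   individual; when given and `exclude_same_individual` is TRUE
#'   (the default), the two haplotypes of one individual never form a pair.
#' @param exclude_same_individual drop within-individual pairs.
#' @return per-site pi, or `NA` with fewer than two haplotypes or no
#'   comparable pairs.
#' @export
nucleotide_diversity <- function(haplotypes, individuals = NULL,
                                 exclude_same_individual = TRUE) {
  h <- encode_haplotypes(haplotypes)
  n <- nrow(h)
  if (is.null(n) || n < 2) return(NA_real_)
  indiv <- if (is.null(individuals)) seq_len(n) else as.integer(factor(individuals))
  pd <- .pairwise_diff_cpp(h, seq_len(n), integer(0), TRUE, indiv,
                           exclude_same_individual && !is.null(individuals))
  pair_mean(pd)
}

#' Per-site absolute divergence (d_XY)
#'
#' Mean over all between-population haplotype pairs of differences per
#' jointly called site, with the same pairwise missing-data handling as
#' [nucleotide_diversity()].
#'
#' @param x,y allele matrices for the two populations (haplotypes x sites).
#' @return per-site d_XY, or `NA` when no pair has a jointly called site.
#' @export
dxy <- function(x, y) {
  hx <- encode_haplotypes(x)
  hy <- encode_haplotypes(y)
  if (is.null(dim(hx))) hx <- matrix(hx, nrow = 1)
  if (is.null(dim(hy))) hy <- matrix(hy, nrow = 1)
  stopifnot(ncol(hx) == ncol(hy))
  h <- rbind(hx, hy)
  pd <- .pairwise_diff_cpp(h, seq_len(nrow(hx)),
                           nrow(hx) + seq_len(nrow(hy)), FALSE,
                           integer(0), FALSE)
  pair_mean(pd)
}

pair_mean <- function(pd) {
  ok <- pd$sites > 0
  if (!any(ok)) return(NA_real_)
  mean(pd$diffs[ok] / pd$sites[ok])
}

# diversity block used by the window scan: pi for P1..P3 and the three
# pairwise dxy values, computed on the integer matrix directly
diversity_core <- function(hint, gid, indiv = NULL,
                           exclude_same_individual = FALSE) {
  idx <- lapply(1:3, function(g) which(gid == g))
  out <- c(pi_P1 = NA_real_, pi_P2 = NA_real_, pi_P3 = NA_real_,
           dxy_P1P2 = NA_real_, dxy_P1P3 = NA_real_, dxy_P2P3 = NA_real_)
  for (g in 1:3) {
    if (length(idx[[g]]) >= 2) {
      iv <- if (is.null(indiv)) seq_along(idx[[g]]) else indiv[idx[[g]]]
      pd <- .pairwise_diff_cpp(hint, idx[[g]], integer(0), TRUE,
                               as.integer(iv), exclude_same_individual)
      out[g] <- pair_mean(pd)
    }
  }
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  for (k in 1:3) {
    a <- pairs[[k]][1]; b <- pairs[[k]][2]
    pd <- .pairwise_diff_cpp(hint, idx[[a]], idx[[b]], FALSE, integer(0), FALSE)
    out[3 + k] <- pair_mean(pd)
  }
  out
}
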