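#' Polarize biallelic sites against the outgroup
#'
#' Classifies each alignment column as ancestral/derived and returns the
#' derived-allele frequency in each of the four groups (P1, P2, P3 and the
#' outgroup O). A site is retained only if it is biallelic across all
#' called haplotypes and every group has at least one called haplotype.
#' The ancestral allele is the allele fixed among called outgroup
#' haplotypes; when the outgroup is not fixed, the most common allele over
#' all called haplotypes is taken as ancestral (ties broken towards the
#' alphabetically first base, deterministically).
#'
#' The outgroup derived-allele frequency `p4` is retained after
#' polarization (it is nonzero when the outgroup is polymorphic and the
#' overall-majority rule applied); set `force_p4_zero = TRUE` to zero it.
#'
#' For the f_G estimator the P3 sample is additionally split into two
#' pseudo-populations P3a/P3b. The default split interleaves haplotypes by
#' sample order (odd indices to P3a, even to P3b, so P3a is the larger half
#' for odd counts); `split = "random"` draws a seedable random split.
#' A contiguous first-half/second-half split is deliberately not offered:
#' with locally identical haplotypes it makes the f_G denominator
#' degenerate at every site.
#'
#' @param haplotypes matrix of alleles, haplotypes in rows (named by
#'   sample) and sites in columns; characters A/C/G/T with anything else
#'   treated as missing, or an integer-coded matrix from
#'   [encode_haplotypes()].
#' @param groups either a named character vector mapping sample name to
#'   group, or a data frame with columns `sample` and `group`; groups must
#'   be P1, P2, P3 and O.
#' @param positions optional site coordinates (defaults to column index).
#' @param split P3 split rule for f_G, `"interleaved"` (default) or
#'   `"random"`.
#' @param force_p4_zero set the outgroup derived frequency to zero after
#'   polarization.
#' @return a tibble of class `polarized_sites` with one row per retained
#'   site: `position`, derived-allele frequencies `p1`..`p4`, the P3
#'   subsample frequencies `p3a`, `p3b`, and called-haplotype counts
#'   `called1`..`called4`.
#' @examples
#' h <- rbind(P1_1 = c("A", "A"), P2_1 = c("T", "A"),
#'            P3_1 = c("T", "T"), O_1  = c("A", "A"))
#' g <- c(P1_1 = "P1", P2_1 = "P2", P3_1 = "P3", O_1 = "O")
#' polarize_sites(h, g)
#' @export
polarize_sites <- function(haplotypes, groups, positions = NULL,
                           split = c("interleaved", "random"),
                           force_p4_zero = FALSE) {
  split <- match.arg(split)
  if (is.null(dim(haplotypes))) haplotypes <- matrix(haplotypes, nrow = 1)
  if (ncol(haplotypes) == 0 || nrow(haplotypes) == 0) {
    return(empty_polarized())
  }
  gid <- resolve_groups(groups, rownames(haplotypes), nrow(haplotypes))
  hint <- encode_haplotypes(haplotypes)
  if (is.null(positions)) positions <- seq_len(ncol(hint))
  res <- polarize_core(hint, gid, split = split,
                       force_p4_zero = force_p4_zero)
  out <- tibble::tibble(
    position = positions[res$keep],
    p1 = res$p[[1]], p2 = res$p[[2]], p3 = res$p[[3]], p4 = res$p[[4]],
    p3a = res$p3a, p3b = res$p3b,
    called1 = res$called[[1]], called2 = res$called[[2]],
    called3 = res$called[[3]], called4 = res$called[[4]]
  )
  class(out) <- c("polarized_sites", class(out))
  out
}

empty_polarized <- function() {
  out <- tibble::tibble(
    position = integer(), p1 = double(), p2 = double(), p3 = double(),
    p4 = double(), p3a = double(), p3b = double(),
    called1 = integer(), called2 = integer(), called3 = integer(),
    called4 = integer()
  )
  class(out) <- c("polarized_sites", class(out))
  out
}

# Map sample -> group id 1..4 (P1,P2,P3,O). Unknown samples or groups are
# configuration errors; every group must have >= 1 sample.
resolve_groups <- function(groups, sample_names, n) {
  lev <- c("P1", "P2", "P3", "O")
  if (is.data.frame(groups)) {
    groups <- setNames(as.character(groups$group), as.character(groups$sample))
  }
  if (!is.null(names(groups)) && !is.null(sample_names)) {
    missing_samples <- setdiff(sample_names, names(groups))
    if (length(missing_samples) > 0) {
      stop("samples without a group assignment: ",
           paste(missing_samples, collapse = ", "))
    }
    extra <- setdiff(names(groups), sample_names)
    if (length(extra) > 0) {
      stop("unknown samples in group map: ", paste(extra, collapse = ", "))
    }
    groups <- groups[sample_names]
  }
  if (length(groups) != n) {
    stop("group assignment length (", length(groups),
         ") does not match number of haplotypes (", n, ")")
  }
  bad <- setdiff(unique(as.character(groups)), lev)
  if (length(bad) > 0) {
    stop("groups must be P1, P2, P3 or O; found: ",
         paste(bad, collapse = ", "))
  }
  gid <- match(as.character(groups), lev)
  if (any(tabulate(gid, 4) == 0)) {
    stop("every group (P1, P2, P3, O) needs at least one haplotype")
  }
  gid
}

# Split P3 haplotype row indices into interleaved (or random) halves.
split_p3 <- function(gid, split) {
  i3 <- which(gid == 3L)
  if (split == "random") i3 <- sample(i3)
  odd <- i3[seq_along(i3) %% 2 == 1]
  even <- i3[seq_along(i3) %% 2 == 0]
  list(a = odd, b = even)
}

# Vectorized polarization on an integer-coded matrix. Returns per-site
# frequencies for groups 1..4 plus the P3a/P3b subsamples.
polarize_core <- function(hint, gid, split = "interleaved",
                          force_p4_zero = FALSE) {
  L <- ncol(hint)
  sp <- split_p3(gid, split)
  g6 <- gid
  g6[sp$a] <- 5L
  g6[sp$b] <- 6L
  # groups 1..6 where 5/6 are the P3 halves; counts for group 3 are the sum
  cnt <- .allele_counts_cpp(hint, as.integer(g6), 6L)
  slab <- function(g) matrix(cnt[, , g], nrow = 4)
  cnt_g <- list(slab(1), slab(2), slab(5) + slab(6), slab(4))
  called <- lapply(cnt_g, colSums)
  tot <- cnt_g[[1]] + cnt_g[[2]] + cnt_g[[3]] + cnt_g[[4]]

  present <- tot > 0
  n_alleles <- colSums(present)
  keep <- n_alleles == 2L
  for (g in 1:4) keep <- keep & called[[g]] >= 1L
  if (!any(keep)) {
    return(list(keep = logical(L), p = rep(list(double()), 4),
                p3a = double(), p3b = double(),
                called = rep(list(integer()), 4)))
  }

  oc <- cnt_g[[4]][, keep, drop = FALSE]
  totk <- tot[, keep, drop = FALSE]
  presk <- present[, keep, drop = FALSE]
  out_fixed <- colSums(oc > 0) == 1L
  anc_out <- max.col(t(oc), ties.method = "first")
  anc_maj <- max.col(t(totk), ties.method = "first")
  anc <- ifelse(out_fixed, anc_out, anc_maj)
  a1 <- max.col(t(presk), ties.method = "first")
  a2 <- max.col(t(presk), ties.method = "last")
  der <- ifelse(anc == a1, a2, a1)

  nk <- sum(keep)
  idx <- cbind(der, seq_len(nk))
  p <- vector("list", 4)
  calledk <- vector("list", 4)
  for (g in 1:4) {
    cg <- cnt_g[[g]][, keep, drop = FALSE]
    calledk[[g]] <- as.integer(called[[g]][keep])
    p[[g]] <- cg[idx] / calledk[[g]]
  }
  if (force_p4_zero) p[[4]] <- rep(0, nk)
  # P3 halves; if one half has no calls at a site, fall back to the full P3
  # frequency so f_G remains defined under missing data
  c5 <- slab(5)[, keep, drop = FALSE]
  c6 <- slab(6)[, keep, drop = FALSE]
  n5 <- colSums(c5)
  n6 <- colSums(c6)
  p3a <- ifelse(n5 > 0, c5[idx] / n5, p[[3]])
  p3b <- ifelse(n6 > 0, c6[idx] / n6, p[[3]])

  list(keep = keep, p = p, p3a = p3a, p3b = p3b, called = calledk)
}
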