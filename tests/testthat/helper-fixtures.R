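# Shared fixtures: small haplotype alignments built in code, a random
# frequency-table generator, and a brute-force Wilcoxon oracle.

# Alignment with explicit per-group haplotypes. Each element of `cols` is a
# character vector giving the allele carried by every haplotype at that
# site, ordered P1 then P2 then P3 then O.
make_alignment <- function(cols, n = c(P1 = 2, P2 = 2, P3 = 2, O = 2)) {
  mat <- do.call(cbind, cols)
  stopifnot(nrow(mat) == sum(n))
  rownames(mat) <- paste0(rep(names(n), n), "_",
                          unlist(lapply(n, seq_len)))
  mat
}

group_map <- function(n = c(P1 = 2, P2 = 2, P3 = 2, O = 2)) {
  setNames(rep(names(n), n),
           paste0(rep(names(n), n), "_", unlist(lapply(n, seq_len))))
}

# random polarized-site tables for property tests
random_sites <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tibble::tibble(
    position = seq_len(n),
    p1 = runif(n), p2 = runif(n), p3 = runif(n), p4 = runif(n) * 0.3,
    p3a = runif(n), p3b = runif(n)
  )
}

# exact one-sided ("less") Wilcoxon p by enumerating all label permutations
perm_wilcoxon_less <- function(a, b) {
  pooled <- c(a, b)
  nA <- length(a)
  r <- rank(pooled)
  obs <- sum(r[seq_len(nA)])
  combs <- utils::combn(length(pooled), nA)
  stats <- apply(combs, 2, function(ix) sum(r[ix]))
  mean(stats <= obs)
}

# handwritten ABBA/BABA sums used as an independent check on the package's
# statistics (direct transcription of the frequency-weighted products)
oracle_stats <- function(s) {
  ca <- (1 - s$p1) * s$p2 * s$p3 * (1 - s$p4)
  cb <- s$p1 * (1 - s$p2) * s$p3 * (1 - s$p4)
  list(S = sum(ca - cb), denomD = sum(ca + cb))
}
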