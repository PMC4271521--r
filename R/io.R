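#' Read a two-column population file
#'
#' Plain text, whitespace- or tab-separated: sample name then group
#' (P1, P2, P3 or O). Lines starting with `#` are ignored.
#'
#' @param path file path.
#' @return named character vector mapping sample to group.
#' @export
read_populations <- function(path) {
  df <- read.table(path, header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE,
                   col.names = c("sample", "group"))
  setNames(df$group, df$sample)
}

# FASTA writing for alignment matrices (rows = sequences), via Biostrings
write_fasta <- function(mat, path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("writing FASTA requires the Biostrings package")
  }
  ids <- rownames(mat)
  if (is.null(ids)) ids <- paste0("seq", seq_len(nrow(mat)))
  seqs <- Biostrings::DNAStringSet(apply(mat, 1, paste0, collapse = ""))
  names(seqs) <- ids
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a FASTA alignment as a haplotype matrix
#'
#' @param path FASTA file with equal-length sequences.
#' @return character matrix, one row per sequence, named by header.
#' @export
read_fasta_alignment <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("reading FASTA requires the Biostrings package")
  }
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(unique(Biostrings::width(seqs))) != 1) {
    stop("sequences in ", path, " are not aligned (unequal lengths)")
  }
  mat <- as.matrix(seqs)
  rownames(mat) <- sub("\\s.*$", "", names(seqs))
  mat
}

#' Expand VCF genotypes to a haplotype matrix
#'
#' Reads a (plain or bgzipped) VCF with `vcfR`, keeps single-nucleotide
#' REF/ALT records, and expands each diploid genotype into two haplotype
#' rows (`sample_1`, `sample_2`); unphased genotypes are allowed because
#' all downstream statistics are frequency- or pairwise-difference-based.
#' Missing genotypes become missing alleles.
#'
#' @param path VCF file.
#' @return a list: `haplotypes` (character matrix, haplotypes x sites),
#'   `scaffold`, `position` (1-based site coordinates), `individuals`
#'   (individual id per haplotype row).
#' @export
read_vcf_haplotypes <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package")
  }
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- vcfR::getFIX(v)
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  gt <- vcfR::extract.gt(v, element = "GT")
  snp <- nchar(ref) == 1 & !is.na(alt) & !grepl(",", alt) & nchar(alt) == 1
  chrom <- chrom[snp]; pos <- pos[snp]; ref <- ref[snp]; alt <- alt[snp]
  gt <- gt[snp, , drop = FALSE]
  # the first out-of-order record is a hard error: windows need sorted input
  n_rec <- length(pos)
  if (n_rec > 1) {
    same <- chrom[-1] == chrom[-n_rec]
    bad <- which(same & diff(pos) <= 0)       # position goes backwards
    rl <- rle(chrom)
    if (anyDuplicated(rl$values)) {           # scaffold blocks interleaved
      block_start <- cumsum(c(1, head(rl$lengths, -1)))
      bad <- c(bad, block_start[duplicated(rl$values)] - 1)
    }
    if (length(bad) > 0) {
      i <- min(bad) + 1
      stop("input not sorted by scaffold and position: record ", i, " (",
           chrom[i], ":", pos[i], ")")
    }
  }
  samples <- colnames(gt)
  n_sites <- length(pos)
  hap <- matrix(NA_character_, nrow = 2 * length(samples), ncol = n_sites)
  indiv <- rep(samples, each = 2)
  rownames(hap) <- paste0(indiv, "_", rep(1:2, length(samples)))
  al1 <- substr(gt, 1, 1)
  al3 <- substr(gt, 3, 3)
  for (j in seq_along(samples)) {
    a <- al1[, j]; b <- al3[, j]
    hap[2 * j - 1, ] <- ifelse(a == "0", ref, ifelse(a == "1", alt, NA))
    hap[2 * j, ] <- ifelse(b == "0", ref, ifelse(b == "1", alt, NA))
  }
  list(haplotypes = hap, scaffold = chrom, position = pos,
       individuals = indiv)
}

#' Window scan over a VCF
#'
#' Computes all window statistics over nonoverlapping windows of a sorted
#' VCF. Because a typical VCF stores variant sites only, the call-count
#' filter applies to the records present; supply `min_genotyped_sites`
#' accordingly (or 0 to keep every window).
#'
#' @param path VCF file.
#' @param populations named vector or data frame assigning each sample to
#'   P1/P2/P3/O (see [read_populations()]).
#' @param config a [scan_config()].
#' @return a `window_stats_tbl` tibble with one row per retained window;
#'   coordinates are 0-based half-open.
#' @export
scan_vcf <- function(path, populations, config = scan_config()) {
  vc <- read_vcf_haplotypes(path)
  if (is.data.frame(populations)) {
    populations <- setNames(as.character(populations$group),
                            as.character(populations$sample))
  }
  gid <- resolve_groups(populations[vc$individuals], NULL,
                        nrow(vc$haplotypes))
  hint <- encode_haplotypes(vc$haplotypes)
  wins <- iterate_windows(
    tibble::tibble(scaffold = unique(vc$scaffold),
                   length = vapply(unique(vc$scaffold), function(s)
                     max(vc$position[vc$scaffold == s]), 1)),
    config)
  rows <- list()
  for (i in seq_len(nrow(wins))) {
    sel <- vc$scaffold == wins$scaffold[i] &
      vc$position > wins$start[i] & vc$position <= wins$end[i]
    if (!any(sel)) next
    v <- window_stats_core(hint[, sel, drop = FALSE], gid, config,
                           indiv = vc$individuals)
    if (v[["sites"]] < config$min_genotyped_sites) next
    rows[[length(rows) + 1]] <- c(i = i, v)
  }
  if (length(rows) == 0) return(empty_window_tbl())
  m <- do.call(rbind, rows)
  out <- dplyr::bind_cols(wins[m[, "i"], c("scaffold", "start", "end")],
                          tibble::as_tibble(m[, -1, drop = FALSE]))
  class(out) <- c("window_stats_tbl", class(out))
  out
}
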