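test_that("pi matches hand-computed pairwise enumeration", {
  # two identical haplotypes
  h <- rbind(rep("A", 100), rep("A", 100))
  expect_equal(nucleotide_diversity(h), 0)
  # one difference in 100 jointly called sites
  h2 <- h
  h2[2, 7] <- "T"
  expect_equal(nucleotide_diversity(h2), 0.01)
  # missing data handled pairwise: pairs give 1/4, 0/3, 0/3
  h3 <- rbind(c("A", "C", "G", "T"),
              c("A", "C", "G", "A"),
              c("A", "C", "G", "N"))
  expect_equal(nucleotide_diversity(h3), mean(c(0.25, 0, 0)),
               tolerance = 1e-12)
  # fewer than two haplotypes
  expect_true(is.na(nucleotide_diversity(h3[1, , drop = FALSE])))
})

test_that("pi can exclude within-individual haplotype pairs", {
  h <- rbind(c("A", "A"), c("T", "T"), c("A", "T"), c("A", "A"))
  # all 6 pairs: diffs/2 = 1, .5, 0, 1, .5, .5 -> mean = 0.5833...
  expect_equal(nucleotide_diversity(h), mean(c(1, 0.5, 0, 1, 0.5, 0.5)))
  # individuals (1,1,2,2): pairs (1,3),(1,4),(2,3),(2,4) remain
  expect_equal(nucleotide_diversity(h, individuals = c(1, 1, 2, 2)),
               mean(c(0.5, 0, 1, 0.5)))
})

test_that("dxy matches hand-computed examples and is order-invariant", {
  expect_equal(dxy(rbind(c("A", "A", "A", "A")),
                   rbind(c("A", "A", "A", "T"))), 0.25)
  expect_equal(dxy(rbind(c("A", "C", "N", "T")),
                   rbind(c("A", "C", "G", "A"))), 1 / 3, tolerance = 1e-12)
  # identical single haplotypes
  expect_equal(dxy(rbind(c("A", "C")), rbind(c("A", "C"))), 0)
  set.seed(2)
  x <- matrix(sample(c("A", "C", "G", "T", "N"), 60, replace = TRUE), 3, 20)
  y <- matrix(sample(c("A", "C", "G", "T", "N"), 40, replace = TRUE), 2, 20)
  expect_equal(dxy(x, y), dxy(x[c(3, 1, 2), ], y[c(2, 1), ]))
  expect_equal(dxy(x, y), dxy(y, x))
  expect_gte(dxy(x, y), 0)
  # no jointly called sites at all
  expect_true(is.na(dxy(rbind(c("N", "A")), rbind(c("T", "N")))))
})

test_that("windows tile scaffolds without spanning joins", {
  cfg <- scan_config()
  w <- iterate_windows(tibble::tibble(scaffold = "s1", length = 12000), cfg)
  expect_equal(w$start, c(0, 5000, 10000))
  expect_equal(w$end, c(5000, 10000, 12000))
  expect_equal(w$partial, c(FALSE, FALSE, TRUE))
  w2 <- iterate_windows(tibble::tibble(scaffold = c("a", "b"),
                                       length = c(5000, 5000)), cfg)
  expect_equal(nrow(w2), 2)
  expect_equal(w2$scaffold, c("a", "b"))
  expect_equal(nrow(iterate_windows(
    tibble::tibble(scaffold = "empty", length = 0), cfg)), 0)
})

test_that("the qualifying-site filter cuts exactly below threshold", {
  cfg <- scan_config(min_genotyped_sites = 3000, min_called_fraction = 0.5)
  # 8 individuals: a site qualifies with >= 4 called
  expect_true(window_filter(rep(4, 3000), 8, cfg))
  expect_false(window_filter(c(rep(4, 2999), 3), 8, cfg))
  # odd individual counts round the threshold up ("at least half")
  expect_false(window_filter(rep(2, 5000), 5, cfg))   # need ceiling(2.5) = 3
  expect_true(window_filter(rep(3, 3000), 5, cfg))
  expect_true(window_filter(numeric(0), 8,
                            scan_config(min_genotyped_sites = 0)))
})

test_that("window_stats ties polarization, statistics and diversity together", {
  n <- c(P1 = 2, P2 = 2, P3 = 2, O = 2)
  # one fixed ABBA site and one monomorphic site
  h <- make_alignment(list(
    c("A", "A", "T", "T", "T", "T", "A", "A"),
    rep("A", 8)
  ), n)
  st <- window_stats(h, group_map(n), scan_config(min_genotyped_sites = 0))
  expect_equal(st$sites, 2)
  expect_equal(st$sitesUsed, 1)
  expect_equal(st$D, 1)
  expect_equal(st$fd, 1)
  expect_equal(st$pi_P2, 0)
  expect_equal(st$dxy_P1P2, 0.5)   # differ at 1 of 2 sites, all pairs
  expect_equal(st$dxy_P2P3, 0)
})

test_that("scan_alignments keeps qualifying windows and is deterministic", {
  n <- c(P1 = 2, P2 = 2, P3 = 2, O = 2)
  aln <- list(
    win1 = make_alignment(list(c("A", "A", "T", "T", "T", "T", "A", "A"),
                               c("A", "T", "A", "A", "T", "T", "A", "A")), n),
    win2 = make_alignment(list(rep("A", 8), rep("N", 8)), n)
  )
  cfg <- scan_config(window_size = 2, min_genotyped_sites = 2)
  out <- scan_alignments(aln, group_map(n), cfg)
  expect_equal(out$scaffold, "win1")     # win2 has a fully missing site
  out2 <- scan_alignments(aln, group_map(n), cfg)
  expect_identical(out, out2)
  # P2 identical to P1 at every site forces D = 0
  aln3 <- list(w = make_alignment(list(c("A", "T", "A", "T", "T", "T", "A", "A"),
                                       c("T", "A", "T", "A", "T", "A", "A", "A")), n))
  out3 <- scan_alignments(aln3, group_map(n),
                          scan_config(window_size = 2, min_genotyped_sites = 0))
  expect_equal(out3$D, 0)
})

test_that("chromosome summaries compute variances and correlations", {
  w <- tibble::tibble(
    scaffold = rep(c("c1", "c2", "c3"), each = 2),
    D = c(0, 0.5, 0.1, 0.1, 0.4, 0.9),
    fd = c(0.1, 0.2, 0.05, 0.05, 0.2, 0.5),
    pi_P1 = rep(c(0.01, 0.02, 0.005), each = 2),
    pi_P2 = rep(c(0.01, 0.02, 0.005), each = 2),
    pi_P3 = rep(c(0.01, 0.02, 0.005), each = 2)
  )
  s <- summarize_chromosomes(w)
  expect_equal(s$chromosomes$var_D[s$chromosomes$chromosome == "c1"], 0.125)
  expect_equal(s$chromosomes$var_D[s$chromosomes$chromosome == "c2"], 0)
  expect_equal(s$chromosomes$mean_pi,
               c(0.01, 0.02, 0.005)[order(c("c1", "c2", "c3"))])
  expect_equal(s$correlations$df, c(1L, 1L))
  # single-window chromosomes have no variance; constant columns no cor
  s2 <- summarize_chromosomes(w[c(1, 3, 5), ])
  expect_true(all(is.na(s2$chromosomes$var_D)))
  expect_true(all(is.na(s2$correlations$r)))
  expect_s3_class(tidy(s), "tbl_df")
  expect_equal(nrow(glance(s)), 2)
})

test_that("window tables round-trip through the fixed TSV layout", {
  n <- c(P1 = 2, P2 = 2, P3 = 2, O = 2)
  aln <- list(w1 = make_alignment(list(c("A", "A", "T", "T", "T", "T", "A", "A")), n))
  out <- scan_alignments(aln, group_map(n),
                         scan_config(window_size = 1, min_genotyped_sites = 0))
  path <- tempfile(fileext = ".tsv")
  write_window_table(out, path)
  back <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(names(back),
               c("scaffold", "start", "end", "sites", "sitesUsed", "D", "fG",
                 "fhom", "fd", "S", "pi_P1", "pi_P2", "pi_P3", "dxy_P1P2",
                 "dxy_P1P3", "dxy_P2P3"))
  expect_equal(back$start, 1)  # reports are 1-based inclusive
  expect_equal(back$D, out$D)
})

test_that("window_stats honours within-individual pair exclusion for pi", {
  n <- c(P1 = 4, P2 = 2, P3 = 2, O = 2)
  h <- make_alignment(list(
    c("A", "T", "A", "T", "T", "T", "T", "T", "A", "A"),
    c("A", "T", "A", "T", "T", "A", "T", "T", "A", "A")
  ), n)
  indiv <- c("i1", "i1", "i2", "i2", "i3", "i3", "i4", "i4", "i5", "i5")
  all_pairs <- window_stats(h, group_map(n),
                            scan_config(min_genotyped_sites = 0,
                                        exclude_same_individual = FALSE),
                            individuals = indiv)
  between <- window_stats(h, group_map(n),
                          scan_config(min_genotyped_sites = 0,
                                      exclude_same_individual = TRUE),
                          individuals = indiv)
  # P1 haplotypes (A,A), (T,T), (A,A), (T,T); individuals pair 1+2 and 3+4,
  # so exclusion drops the two fully different within-individual pairs
  expect_equal(all_pairs$pi_P1, mean(c(1, 0, 1, 1, 0, 1)))
  expect_equal(between$pi_P1, mean(c(0, 1, 1, 0)))
  expect_equal(all_pairs$dxy_P1P2, between$dxy_P1P2)
})

test_that("the complete-data fast path equals the general path exactly", {
  # dual route: the one-pass C++ kernel used for simulated windows must
  # agree with the general R polarization + pairwise-difference path
  m <- demographic_model(window_length = 800, rho = 0.01)
  gid <- rep(1:4, each = 8)
  cfg <- scan_config(min_genotyped_sites = 0)
  for (seed in 1:5) {
    h <- encode_haplotypes(simulate_window(m, seed = seed))
    fast <- fdscan:::window_stats_core(h, gid, cfg, complete = TRUE)
    slow <- fdscan:::window_stats_core(h, gid, cfg, complete = FALSE)
    expect_equal(fast, slow, tolerance = 1e-12)
  }
})
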