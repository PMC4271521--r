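test_that("model validation rejects inconsistent histories", {
  expect_error(demographic_model(t12 = 2, t23 = 1), "t12 < t23")
  expect_error(demographic_model(admixture = list(direction = "P3_to_P2",
                                                  t_gf = 1.5, f = 0.1)),
               "t_gf")
  expect_error(demographic_model(topology = "alternate"), "admixture|t_str")
  expect_error(demographic_model(topology = "alternate", t_str = 1.5),
               "t23 < t_str")
  expect_error(demographic_model(admixture = list(direction = "P3_to_P2",
                                                  t_gf = 0.1, f = 1.2)),
               "f")
  expect_silent(demographic_model(topology = "alternate", t_str = 2.5))
})

test_that("simulated windows have the right shape and are seed-deterministic", {
  m <- demographic_model()
  a <- simulate_window(m, seed = 7)
  b <- simulate_window(m, seed = 7)
  c <- simulate_window(m, seed = 8)
  expect_identical(dim(a), c(32L, 5000L))
  expect_identical(rownames(a)[c(1, 9, 17, 25)],
                   c("P1_1", "P2_1", "P3_1", "O_1"))
  expect_true(all(a %in% c("A", "C", "G", "T")))
  expect_identical(a, b)
  expect_false(identical(a, c))
  st1 <- simulate_window_stats(m, 5, seed = 11)
  st2 <- simulate_window_stats(m, 5, seed = 11)
  expect_identical(st1, st2)
  expect_equal(length(unique(st1$seed)), 5)
})

test_that("HKY transition probabilities agree with the matrix exponential", {
  skip_if_not_installed("Matrix")
  for (case in list(list(t = 0.05, kappa = 1, pi = rep(0.25, 4)),
                    list(t = 0.3, kappa = 4, pi = c(0.1, 0.2, 0.3, 0.4)),
                    list(t = 1.2, kappa = 0.5, pi = c(0.4, 0.3, 0.2, 0.1)))) {
    p <- hky_transition(case$t, case$kappa, case$pi)
    # rate matrix built independently, normalized to unit mean rate
    ts <- matrix(c(0, 0, 1, 0, 0, 0, 0, 1, 1, 0, 0, 0, 0, 1, 0, 0), 4, 4)
    q <- matrix(rep(case$pi, each = 4), 4, 4) *
      ifelse(ts == 1, case$kappa, 1)
    diag(q) <- 0
    diag(q) <- -rowSums(q)
    q <- q / sum(case$pi * -diag(q))
    pexp <- as.matrix(Matrix::expm(q * case$t))
    expect_equal(unname(p), unname(pexp), tolerance = 1e-8)
    expect_equal(unname(rowSums(p)), rep(1, 4), tolerance = 1e-12)
  }
})

test_that("sequence composition and substitution spectrum follow the model", {
  freqs <- c(0.4, 0.3, 0.2, 0.1)
  m <- demographic_model(window_length = 4000, rho = 0,
                         base_freq = freqs, kappa = 8)
  h <- simulate_window(m, seed = 5)
  emp <- prop.table(table(factor(h, levels = c("A", "C", "G", "T"))))
  expect_equal(as.numeric(emp), freqs, tolerance = 0.08)
  # high kappa: differences between two haplotypes are mostly transitions
  x <- h[1, ]; y <- h[32, ]
  d <- which(x != y)
  is_ts <- (x[d] == "A" & y[d] == "G") | (x[d] == "G" & y[d] == "A") |
    (x[d] == "C" & y[d] == "T") | (x[d] == "T" & y[d] == "C")
  expect_gt(mean(is_ts), 0.5)
})

test_that("diversity and divergence match coalescent expectations", {
  m <- demographic_model(t12 = 1, t23 = 2, window_length = 2000, rho = 0.01)
  st <- simulate_window_stats(m, 300, seed = 21)
  # E[pi] ~ 2 * E[pairwise TMRCA = 0.5] * 0.01, minus multiple-hit loss
  expect_equal(mean(st$pi_P1), 0.01, tolerance = 0.08)
  expect_equal(mean(st$pi_P3), 0.01, tolerance = 0.08)
  # E[dxy] ~ 2 (t_split + 0.5) * 0.01 with Jukes-Cantor-style saturation
  jc <- function(d) 0.75 * (1 - exp(-4 * d / 3))
  expect_equal(mean(st$dxy_P1P2), jc(0.03), tolerance = 0.05)
  expect_equal(mean(st$dxy_P2P3), jc(0.05), tolerance = 0.05)
  expect_equal(mean(st$dxy_P1P3), jc(0.05), tolerance = 0.05)
})

test_that("without gene flow D is centred on zero", {
  m <- demographic_model(t12 = 1, t23 = 2, window_length = 1000, rho = 0.01)
  st <- simulate_window_stats(m, 500, seed = 31)
  d <- st$D[!is.na(st$D)]
  expect_gt(length(d), 300)  # 1-kb windows often lack informative sites
  se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d)), 3 * se)
  # f_d stays within [0, 1] on windows with D >= 0
  fd <- st$fd[!is.na(st$D) & st$D >= 0 & !is.na(st$fd)]
  expect_true(all(fd >= 0 & fd <= 1 + 1e-9))
})

test_that("an f = 0 admixture pulse is a distributional no-op", {
  null <- demographic_model(window_length = 1000, rho = 0.01)
  pulse0 <- demographic_model(window_length = 1000, rho = 0.01,
                              admixture = list(direction = "P3_to_P2",
                                               t_gf = 0.1, f = 0))
  a <- simulate_window_stats(null, 150, seed = 41)
  b <- simulate_window_stats(pulse0, 150, seed = 42)
  p <- suppressWarnings(stats::ks.test(a$D[!is.na(a$D)],
                                       b$D[!is.na(b$D)])$p.value)
  expect_gt(p, 0.001)
})

test_that("complete introgression homogenizes P2 and P3", {
  m <- demographic_model(admixture = list(direction = "P3_to_P2",
                                          t_gf = 0.1, f = 1),
                         window_length = 2000)
  st <- simulate_window_stats(m, 120, seed = 51)
  expect_gt(mean(st$fhom, na.rm = TRUE), 0.85)
  expect_gt(mean(st$D, na.rm = TRUE), 0.9)
  # P2-P3 divergence collapses towards within-population diversity
  expect_lt(mean(st$dxy_P2P3), 0.6 * mean(st$dxy_P1P3))
})

test_that("D is more variable in low-diversity windows", {
  lo <- demographic_model(window_length = 1000, rho = 0.01,
                          mut_scale = 0.002)
  hi <- demographic_model(window_length = 1000, rho = 0.01,
                          mut_scale = 0.02)
  a <- simulate_window_stats(lo, 120, seed = 61)
  b <- simulate_window_stats(hi, 120, seed = 62)
  expect_lt(mean(a$pi_P1), mean(b$pi_P1))
  expect_gt(var(a$D, na.rm = TRUE), var(b$D, na.rm = TRUE))
})

test_that("model grids reproduce the published enumeration counts", {
  expect_equal(nrow(model_grid("null")), 45)
  expect_equal(nrow(model_grid("geneflow_P3_to_P2")), 120)
  expect_equal(nrow(model_grid("geneflow_P2_to_P3")), 120)
  expect_equal(nrow(model_grid("structure")), 120)
  total <- sum(vapply(c("null", "geneflow_P3_to_P2", "geneflow_P2_to_P3",
                        "structure"),
                      function(s) nrow(model_grid(s)), 1))
  expect_equal(total, 405)
  g <- model_grid("structure")
  expect_true(all(g$t12 < g$t23 & g$t23 < g$t_event))
  sub <- model_grid("null", subsample = 10)
  expect_equal(nrow(sub), 10)
  expect_true(all(sub$model %in% model_grid("null")$model))
})

test_that("the estimator grid covers the full factorial design", {
  g <- estimator_grid()
  expect_equal(nrow(g), 2 * 11 * 2 * 3 * 3)
  expect_equal(unique(g$windows), 100)
  expect_error(estimator_grid(directions = character(0)), "empty")
  sub <- estimator_grid(directions = "P3_to_P2", f = c(0, 1), t_gf = 0.1,
                        window_length = 1000, rho = 0.01,
                        windows_per_setting = 3)
  sim <- simulate_grid(sub, seed = 71)
  expect_equal(nrow(sim), 6)
  expect_identical(sim, {
    set.seed(99)  # prove simulate_grid reseeds internally
    simulate_grid(sub, seed = 71)
  })
  acc <- estimator_accuracy(sim)
  expect_setequal(unique(acc$statistic), c("D", "fd", "fG", "fhom"))
  expect_equal(nrow(acc), 2 * 4)
})

test_that("combined datasets carry labels and honour their design", {
  row <- model_grid("geneflow_P3_to_P2", rho = 0.01, window_length = 500,
                    subsample = 1)
  mp <- fdscan:::models_from_row(row[1, ])
  ds <- simulate_combined(mp$background, mp$alternate, n_background = 27,
                          n_alternate = 3, seed = 81)
  expect_equal(nrow(ds), 30)
  expect_equal(sum(ds$label == "Background"), 27)
  ds2 <- simulate_combined(mp$background, mp$alternate, n_background = 27,
                           n_alternate = 3, seed = 81)
  expect_identical(ds, ds2)
  # the published design defaults to 9,000 + 1,000 windows
  expect_equal(eval(formals(simulate_combined)$n_background), 9000)
  expect_equal(eval(formals(simulate_combined)$n_alternate), 1000)
  # null datasets: background only
  dsn <- simulate_combined(mp$background, NULL, n_background = 5,
                           n_alternate = 0, seed = 82)
  expect_equal(unique(dsn$label), "Background")
  # scenario/time mismatches are rejected before any simulation
  expect_error(
    simulate_combined(
      demographic_model(t12 = 0.3, t23 = 2),
      demographic_model(topology = "alternate", t12 = 0.6, t23 = 2,
                        admixture = list(direction = "P3_to_P2", t_gf = 0.5)),
      n_background = 1, n_alternate = 1),
    "more recent")
  expect_error(
    simulate_combined(
      demographic_model(t12 = 0.5, t23 = 1.5),
      demographic_model(topology = "alternate", t12 = 0.5, t23 = 0.8,
                        t_str = 1.0),
      n_background = 1, n_alternate = 1),
    "older")
})

test_that("alternate histories move P2-P3 divergence as the scenarios predict", {
  bg <- demographic_model(t12 = 0.6, t23 = 0.8, window_length = 1000)
  gf <- demographic_model(topology = "alternate", t12 = 0.6, t23 = 0.8,
                          admixture = list(direction = "P2_to_P3",
                                           t_gf = 0.4),
                          window_length = 1000)
  str <- demographic_model(topology = "alternate", t12 = 0.6, t23 = 0.8,
                           t_str = 1.0, window_length = 1000)
  ds_gf <- simulate_combined(bg, gf, 80, 40, seed = 91)
  ds_str <- simulate_combined(bg, str, 80, 40, seed = 92)
  mg <- tapply(ds_gf$dxy_P2P3, ds_gf$label, mean)
  ms <- tapply(ds_str$dxy_P2P3, ds_str$label, mean)
  expect_lt(mg[["Alternate"]], 0.85 * mg[["Background"]])
  expect_gt(ms[["Alternate"]], 0.85 * ms[["Background"]])
  expect_lt(ms[["Alternate"]], 1.15 * ms[["Background"]])
  # structure still produces an ABBA excess (positive D)
  expect_gt(mean(ds_str$D[ds_str$label == "Alternate"], na.rm = TRUE), 0.3)
})

test_that("written window sets are reproducible from their manifest", {
  dir1 <- file.path(tempdir(), "simout1")
  dir2 <- file.path(tempdir(), "simout2")
  m <- demographic_model(window_length = 300)
  write_windows(m, 3, dir1, seed = 5)
  write_windows(m, 3, dir2, seed = 5)
  f1 <- list.files(dir1, pattern = "fa$", full.names = TRUE)
  f2 <- list.files(dir2, pattern = "fa$", full.names = TRUE)
  expect_equal(length(f1), 3)
  expect_identical(lapply(f1, readLines), lapply(f2, readLines))
  man <- read.table(file.path(dir1, "manifest.tsv"), header = TRUE,
                    sep = "\t", comment.char = "#")
  expect_equal(nrow(man), 3)
  # a single window can be regenerated from its recorded seed
  aln <- read_fasta_alignment(f1[1])
  regen <- simulate_window(m, seed = man$seed[1])
  expect_identical(unname(apply(aln, 1, paste0, collapse = "")),
                   unname(apply(regen, 1, paste0, collapse = "")))
})
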