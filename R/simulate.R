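#' Specify a four-taxon demographic model
#'
#' Times are in units of 4N generations with N constant and equal across
#' populations. The `background` topology is (((P1,P2),P3),O) with splits
#' at `t12` < `t23` < `t_root`; an optional instantaneous admixture pulse
#' at `t_gf` moves each lineage of the recipient population through the
#' donor with probability `f`. The `alternate` topology ((P1,(P2,P3)),O)
#' represents complete sharing between P2 and P3: under gene flow the
#' P2/P3 join is at `t_gf` (more recent than `t12`) and P1 joins at `t23`;
#' under ancestral structure the P2/P3 join stays at `t23` and P1 joins at
#' the structure time `t_str` > `t23`, leaving P2-P3 divergence unchanged.
#'
#' @param topology `"background"` or `"alternate"`.
#' @param t12,t23,t_root split times in 4N-generation units.
#' @param admixture optional list with elements `direction`
#'   (`"P3_to_P2"` or `"P2_to_P3"`), `t_gf` and (background topology only)
#'   `f`, the probability that a recipient lineage traces its ancestry
#'   through the donor.
#' @param t_str structure split time (alternate topology only).
#' @param samples_per_pop haplotypes sampled per population.
#' @param window_length window length in bp.
#' @param rho per-bp population recombination rate 4Nr; the whole window
#'   recombines at `rho * window_length` (e.g. 0.01/bp over 5 kb gives 50).
#' @param mut_scale branch scaling factor: expected substitutions per site
#'   per 4N generations.
#' @param kappa HKY transition/transversion rate ratio (1 with equal base
#'   frequencies corresponds to a transition:transversion ratio of 0.5).
#' @param base_freq equilibrium base frequencies (A, C, G, T).
#' @return a validated `demographic_model` object.
#' @examples
#' # the classic grid point: f = 0.2, gene flow P3 -> P2 at 0.1
#' m <- demographic_model(t12 = 1, t23 = 2,
#'                        admixture = list(direction = "P3_to_P2",
#'                                         t_gf = 0.1, f = 0.2))
#' @export
demographic_model <- function(topology = c("background", "alternate"),
                              t12 = 1, t23 = 2, t_root = 3,
                              admixture = NULL, t_str = NULL,
                              samples_per_pop = 8, window_length = 5000,
                              rho = 0.01, mut_scale = 0.01, kappa = 1,
                              base_freq = rep(0.25, 4)) {
  topology <- match.arg(topology)
  stopifnot(samples_per_pop >= 1, window_length >= 1, rho >= 0,
            mut_scale > 0, kappa > 0, length(base_freq) == 4,
            abs(sum(base_freq) - 1) < 1e-8)
  if (!is.null(admixture)) {
    stopifnot(is.list(admixture),
              admixture$direction %in% c("P3_to_P2", "P2_to_P3"))
    if (topology == "background") {
      stopifnot(!is.null(admixture$f), admixture$f >= 0, admixture$f <= 1)
    }
  }
  if (topology == "background") {
    if (!(0 < t12 && t12 < t23 && t23 < t_root)) {
      stop("background topology needs 0 < t12 < t23 < t_root")
    }
    if (!is.null(admixture) && !(0 < admixture$t_gf && admixture$t_gf < t12)) {
      stop("admixture time must satisfy 0 < t_gf < t12")
    }
    if (!is.null(t_str)) stop("t_str applies to the alternate topology only")
  } else {
    if (!is.null(admixture) && !is.null(t_str)) {
      stop("alternate topology takes either an admixture time or t_str")
    }
    if (!is.null(admixture)) {
      if (!(0 < admixture$t_gf && admixture$t_gf < t12 && t12 < t23)) {
        stop("alternate gene-flow topology needs 0 < t_gf < t12 < t23")
      }
    } else if (!is.null(t_str)) {
      if (!(t23 < t_str && t_str < t_root)) {
        stop("ancestral structure needs t23 < t_str < t_root")
      }
    } else {
      stop("alternate topology needs an admixture event or t_str")
    }
    if (!(0 < t12 && t12 < t23 && t23 < t_root)) {
      stop("alternate topology needs 0 < t12 < t23 < t_root")
    }
  }
  structure(list(topology = topology, t12 = t12, t23 = t23, t_root = t_root,
                 admixture = admixture, t_str = t_str,
                 samples_per_pop = samples_per_pop,
                 window_length = window_length, rho = rho,
                 mut_scale = mut_scale, kappa = kappa,
                 base_freq = base_freq),
            class = "demographic_model")
}

# Compile a model to ms-style events: joins (time, from, to) move all
# lineages of `from` into `to`; pulses additionally carry the per-lineage
# probability. Populations are 1..4 = P1, P2, P3, O.
model_events <- function(model) {
  joins <- NULL
  pulses <- matrix(numeric(0), ncol = 4)
  if (model$topology == "background") {
    joins <- rbind(c(model$t12, 2, 1), c(model$t23, 3, 1),
                   c(model$t_root, 4, 1))
    if (!is.null(model$admixture)) {
      a <- model$admixture
      pulses <- if (a$direction == "P3_to_P2") {
        rbind(c(a$t_gf, 2, 3, a$f))
      } else {
        rbind(c(a$t_gf, 3, 2, a$f))
      }
    }
  } else if (!is.null(model$admixture)) {
    joins <- if (model$admixture$direction == "P3_to_P2") {
      rbind(c(model$admixture$t_gf, 2, 3), c(model$t23, 3, 1),
            c(model$t_root, 4, 1))
    } else {
      rbind(c(model$admixture$t_gf, 3, 2), c(model$t23, 2, 1),
            c(model$t_root, 4, 1))
    }
  } else {
    joins <- rbind(c(model$t23, 2, 3), c(model$t_str, 3, 1),
                   c(model$t_root, 4, 1))
  }
  list(joins = joins[order(joins[, 1]), , drop = FALSE], pulses = pulses)
}

sim_window_int <- function(model) {
  ev <- model_events(model)
  .sim_window_cpp(as.integer(model$samples_per_pop), 4L,
                  as.integer(model$window_length),
                  ev$joins, ev$pulses,
                  model$rho * model$window_length,
                  model$mut_scale, model$kappa, model$base_freq)
}

sim_group_ids <- function(model) {
  rep(1:4, each = model$samples_per_pop)
}

sim_sample_names <- function(model) {
  paste0(rep(c("P1", "P2", "P3", "O"), each = model$samples_per_pop), "_",
         rep(seq_len(model$samples_per_pop), 4))
}

#' Simulate one sequence window
#'
#' Draws genealogies under the model's demographic history with
#' recombination (Hudson's ancestral recombination graph with ms
#' semantics) and evolves finite-site sequences along the marginal trees
#' under HKY mutation. Deterministic given `seed`.
#'
#' @param model a [demographic_model()].
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return a character matrix (`4 * samples_per_pop` rows named P1_1..O_n,
#'   `window_length` columns) of A/C/G/T.
#' @export
simulate_window <- function(model, seed = NULL) {
  stopifnot(inherits(model, "demographic_model"))
  if (!is.null(seed)) set.seed(seed)
  h <- sim_window_int(model)
  out <- matrix(BASES[h + 1L], nrow = nrow(h))
  rownames(out) <- sim_sample_names(model)
  out
}

#' Simulate many windows and return their statistics
#'
#' The workhorse for simulation studies: windows are simulated one at a
#' time and only per-window statistics are kept. Per-window seeds are
#' drawn once from `seed`, so any window can be regenerated independently.
#'
#' @param model a [demographic_model()].
#' @param n number of windows.
#' @param seed integer seed.
#' @param label label attached to every window (e.g. "Background").
#' @param config a [scan_config()]; the default applies no call filter so
#'   every simulated window is returned.
#' @return a `window_stats_tbl` tibble with columns `window`, `label`,
#'   `seed` and the statistics of [window_stats()].
#' @export
simulate_window_stats <- function(model, n, seed = NULL,
                                  label = "Background",
                                  config = scan_config(min_genotyped_sites = 0)) {
  stopifnot(inherits(model, "demographic_model"), n >= 0)
  if (!is.null(seed)) set.seed(seed)
  wseeds <- sample.int(.Machine$integer.max - 1L, n)
  gid <- sim_group_ids(model)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(wseeds[i])
    hint <- sim_window_int(model)
    rows[[i]] <- window_stats_core(hint, gid, config, complete = TRUE)
  }
  out <- if (n > 0) tibble::as_tibble(do.call(rbind, rows)) else
    tibble::as_tibble(empty_window_tbl()[window_stat_names()])
  out <- dplyr::bind_cols(
    tibble::tibble(window = seq_len(n), label = rep(label, n),
                   seed = wseeds[seq_len(n)]),
    out)
  class(out) <- c("window_stats_tbl", class(out))
  out
}

#' Simulate a combined Background/Alternate dataset
#'
#' Combines windows from a background model (no sharing between P2 and P3)
#' with windows from an alternate model in which sharing is complete
#' (f = 1 by topology), the standard design being 9,000 + 1,000 windows.
#' Null datasets use `alternate = NULL` and `n_alternate = 0`.
#'
#' @param background a background-topology [demographic_model()].
#' @param alternate an alternate-topology [demographic_model()] or `NULL`.
#' @param n_background,n_alternate window counts.
#' @param seed integer seed.
#' @return a `combined_dataset` tibble of per-window statistics with a
#'   `label` column ("Background"/"Alternate").
#' @export
simulate_combined <- function(background, alternate = NULL,
                              n_background = 9000, n_alternate = 1000,
                              seed = NULL) {
  stopifnot(inherits(background, "demographic_model"),
            background$topology == "background")
  if (is.null(alternate)) {
    stopifnot(n_alternate == 0)
  } else {
    stopifnot(inherits(alternate, "demographic_model"),
              alternate$topology == "alternate")
    if (!is.null(alternate$admixture) &&
        alternate$admixture$t_gf >= background$t12) {
      stop("gene-flow alternate windows need t_gf more recent than the ",
           "background P1-P2 split")
    }
    if (!is.null(alternate$t_str) && alternate$t_str <= background$t23) {
      stop("ancestral-structure alternate windows need t_str older than ",
           "the background P2-P3 split")
    }
  }
  if (!is.null(seed)) set.seed(seed)
  s_bg <- sample.int(.Machine$integer.max - 1L, 1)
  s_alt <- sample.int(.Machine$integer.max - 1L, 1)
  bg <- simulate_window_stats(background, n_background, seed = s_bg,
                              label = "Background")
  out <- if (n_alternate > 0) {
    alt <- simulate_window_stats(alternate, n_alternate, seed = s_alt,
                                 label = "Alternate")
    alt$window <- alt$window + n_background
    dplyr::bind_rows(bg, alt)
  } else {
    bg
  }
  class(out) <- c("combined_dataset", "window_stats_tbl",
                  setdiff(class(out), c("combined_dataset", "window_stats_tbl")))
  attr(out, "models") <- list(background = background, alternate = alternate)
  out
}

#' Enumerate the split-time model grid for a scenario
#'
#' Split times (and the gene-flow/structure times) take values on the grid
#' 0.2, 0.4, ..., 2.0 (4N units) with the root fixed at 3.0. Orderings
#' follow the scenario's constraints: null models are pairs t12 < t23
#' (45 models); gene-flow models are triples t_gf < t12 < t23 (120 per
#' direction); structure models are triples t12 < t23 < t_str (120).
#'
#' @param scenario one of `"null"`, `"geneflow_P3_to_P2"`,
#'   `"geneflow_P2_to_P3"`, `"structure"`.
#' @param times candidate split times.
#' @param t_root root time.
#' @param rho per-bp 4Nr.
#' @param window_length window length in bp.
#' @param samples_per_pop haplotypes per population.
#' @param mut_scale branch scaling factor.
#' @param subsample optionally keep only this many models, evenly spaced
#'   over the enumeration (desk-scale runs).
#' @return a tibble with one row per model: `model`, `scenario`, `t12`,
#'   `t23`, `t_event` (t_gf or t_str; NA for null) and the simulation
#'   parameters.
#' @export
model_grid <- function(scenario = c("null", "geneflow_P3_to_P2",
                                    "geneflow_P2_to_P3", "structure"),
                       times = seq(0.2, 2.0, by = 0.2), t_root = 3.0,
                       rho = 0.01, window_length = 5000,
                       samples_per_pop = 8, mut_scale = 0.01,
                       subsample = NULL) {
  scenario <- match.arg(scenario)
  times <- sort(times)
  if (scenario == "null") {
    g <- expand.grid(t12 = times, t23 = times)
    g <- g[g$t12 < g$t23, ]
    g$t_event <- NA_real_
  } else if (scenario == "structure") {
    g <- expand.grid(t12 = times, t23 = times, t_event = times)
    g <- g[g$t12 < g$t23 & g$t23 < g$t_event, ]
  } else {
    g <- expand.grid(t_event = times, t12 = times, t23 = times)
    g <- g[g$t_event < g$t12 & g$t12 < g$t23, ]
  }
  g <- g[order(g$t12, g$t23, g$t_event), c("t12", "t23", "t_event")]
  out <- tibble::as_tibble(g)
  out <- dplyr::mutate(out, scenario = scenario, t_root = t_root, rho = rho,
                       window_length = window_length,
                       samples_per_pop = samples_per_pop,
                       mut_scale = mut_scale,
                       model = dplyr::row_number(), .before = 1)
  if (!is.null(subsample)) {
    stopifnot(subsample >= 1)
    idx <- unique(round(seq(1, nrow(out), length.out = min(subsample, nrow(out)))))
    out <- out[idx, ]
  }
  out
}

# Background/alternate model pair for one grid row.
models_from_row <- function(row) {
  common <- list(t_root = row$t_root, samples_per_pop = row$samples_per_pop,
                 window_length = row$window_length, rho = row$rho,
                 mut_scale = row$mut_scale)
  bg <- do.call(demographic_model,
                c(list(topology = "background", t12 = row$t12, t23 = row$t23),
                  common))
  alt <- NULL
  if (row$scenario %in% c("geneflow_P3_to_P2", "geneflow_P2_to_P3")) {
    dir <- if (row$scenario == "geneflow_P3_to_P2") "P3_to_P2" else "P2_to_P3"
    alt <- do.call(demographic_model,
                   c(list(topology = "alternate", t12 = row$t12,
                          t23 = row$t23,
                          admixture = list(direction = dir,
                                           t_gf = row$t_event)),
                     common))
  } else if (row$scenario == "structure") {
    alt <- do.call(demographic_model,
                   c(list(topology = "alternate", t12 = row$t12,
                          t23 = row$t23, t_str = row$t_event),
                     common))
  }
  list(background = bg, alternate = alt)
}

#' Settings grid for the estimator-accuracy study
#'
#' The full design crosses both gene-flow directions, 11 introgression
#' proportions f = 0, 0.1, ..., 1, two times of gene flow (0.1 and 0.5),
#' three window lengths (1, 5 and 10 kb) and three per-bp recombination
#' rates (0.001, 0.01, 0.1), with fixed splits t12 = 1, t23 = 2 and root
#' 3. Any subset of the grid can be selected for desk-scale runs.
#'
#' @param directions gene-flow directions to include.
#' @param f introgression proportions.
#' @param t_gf times of gene flow (4N units).
#' @param window_length window lengths (bp).
#' @param rho per-bp 4Nr values.
#' @param windows_per_setting windows to simulate per setting.
#' @return a tibble of simulation settings.
#' @export
estimator_grid <- function(directions = c("P3_to_P2", "P2_to_P3"),
                           f = seq(0, 1, by = 0.1), t_gf = c(0.1, 0.5),
                           window_length = c(1000, 5000, 10000),
                           rho = c(0.001, 0.01, 0.1),
                           windows_per_setting = 100) {
  if (length(directions) == 0 || length(f) == 0 || length(t_gf) == 0 ||
      length(window_length) == 0 || length(rho) == 0) {
    stop("empty estimator grid selection")
  }
  g <- expand.grid(direction = directions, f = f, t_gf = t_gf,
                   window_length = window_length, rho = rho,
                   stringsAsFactors = FALSE)
  out <- tibble::as_tibble(g)
  dplyr::mutate(out, setting = dplyr::row_number(),
                windows = windows_per_setting, .before = 1)
}

#' Simulate the estimator grid
#'
#' Simulates `windows` windows for every setting of an [estimator_grid()]
#' under the background topology (splits 1/2/3) with the setting's
#' admixture pulse, and records the per-window statistics together with
#' the true f.
#'
#' @param grid an [estimator_grid()] tibble (or a subset of one).
#' @param seed integer seed.
#' @param samples_per_pop,mut_scale simulation parameters.
#' @return a tibble of per-window statistics with the setting columns.
#' @export
simulate_grid <- function(grid, seed = NULL, samples_per_pop = 8,
                          mut_scale = 0.01) {
  stopifnot(nrow(grid) > 0)
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, nrow(grid))
  res <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    adm <- if (g$f > 0) list(direction = g$direction, t_gf = g$t_gf, f = g$f)
    model <- demographic_model(topology = "background", t12 = 1, t23 = 2,
                               t_root = 3, admixture = adm,
                               samples_per_pop = samples_per_pop,
                               window_length = g$window_length, rho = g$rho,
                               mut_scale = mut_scale)
    st <- simulate_window_stats(model, g$windows, seed = seeds[i])
    res[[i]] <- dplyr::bind_cols(g[rep(1, nrow(st)), ], st)
  }
  out <- dplyr::bind_rows(res)
  class(out) <- c("estimator_grid_sim", class(out))
  out
}

#' Write simulated windows to FASTA with a manifest
#'
#' Writes one FASTA alignment per window (sequences named P1_1..O_n) plus
#' a tab-separated manifest (window id, label, model parameters, seed)
#' whose header carries `# key=value` comment lines.
#'
#' @param model a [demographic_model()].
#' @param n number of windows.
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @param label window label recorded in the manifest.
#' @return the manifest path, invisibly.
#' @export
write_windows <- function(model, n, dir, seed = NULL, label = "Background") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(seed)) set.seed(seed)
  wseeds <- sample.int(.Machine$integer.max - 1L, n)
  names <- sim_sample_names(model)
  files <- character(n)
  for (i in seq_len(n)) {
    set.seed(wseeds[i])
    h <- sim_window_int(model)
    files[i] <- file.path(dir, sprintf("window_%05d.fa", i))
    write_fasta(matrix(BASES[h + 1L], nrow = nrow(h),
                       dimnames = list(names, NULL)), files[i])
  }
  manifest <- file.path(dir, "manifest.tsv")
  con <- file(manifest, "w")
  writeLines(c(
    paste0("# fdscan_version=", as.character(packageVersion("fdscan"))),
    paste0("# topology=", model$topology),
    paste0("# t12=", model$t12), paste0("# t23=", model$t23),
    paste0("# t_root=", model$t_root),
    paste0("# rho=", model$rho),
    paste0("# window_length=", model$window_length),
    paste0("# mut_scale=", model$mut_scale),
    paste0("# seed=", if (is.null(seed)) NA else seed)
  ), con)
  df <- data.frame(window = seq_len(n), file = basename(files),
                   label = label, seed = wseeds[seq_len(n)])
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  close(con)
  invisible(manifest)
}
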