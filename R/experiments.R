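# Drivers for the four tissue-scale studies: homogeneous-mutation
# overcrowding, mutant-patch persistence, clonal takeover probability, and
# healthy-vs-mutant cell areas in heterogeneous crypts.
#
# Every driver equilibrates one healthy crypt per replicate seed and then
# branches that crypt across the experimental conditions, so conditions are
# compared on identical initial tissues and the equilibration cost is paid
# once per replicate.

#' Experiment specification
#'
#' @param experiment one of `"overcrowding"`, `"persistence"`,
#'   `"takeover"`, `"areas"`.
#' @param model `"vl"` or `"tan"`.
#' @param gamma_grid mutation levels to sweep.
#' @param replicates independent crypts per condition.
#' @param seed base RNG seed; replicate r uses `seed + r - 1`.
#' @param equilibration_time hours of healthy dynamics before mutation.
#' @param observation_time hours tracked after mutation.
#' @param H0 patch-centre heights (persistence only).
#' @param fractions initial mutant fractions (takeover only).
#' @param record_times times at which persistence heights are reported.
#' @param max_time verdict cap for takeover runs, hours.
#' @param mechanics a [mechanics_config()].
#' @export
experiment_spec <- function(experiment = c("overcrowding", "persistence",
                                           "takeover", "areas"),
                            model = "vl",
                            gamma_grid = seq(0, 1, by = 0.1),
                            replicates = 20,
                            seed = 1,
                            equilibration_time = 500,
                            observation_time = 50,
                            H0 = c(4, 12),
                            fractions = c(0.25, 0.5, 0.75),
                            record_times = seq(0, 50, by = 10),
                            max_time = 1000,
                            mechanics = mechanics_config()) {
  experiment <- match.arg(experiment)
  stopifnot(replicates >= 1, all(gamma_grid >= 0 & gamma_grid <= 1))
  structure(as.list(environment()), class = "experiment_spec")
}

.rep_config <- function(spec, rep, ...) {
  simulation_config(model = spec$model,
                    mechanics = spec$mechanics,
                    equilibration_time = spec$equilibration_time,
                    observation_time = spec$observation_time,
                    seed = spec$seed + rep - 1, ...)
}

.equilibrated <- function(spec, rep) {
  equilibrate_crypt(.rep_config(spec, rep))
}

#' Overcrowding after homogeneous mutation
#'
#' Mutates every cell of an equilibrated crypt to each gamma, under both
#' uniform drag (`eta = 1`) and the adhesion-complex-dependent drag law,
#' and reports the cell count 50 h (the observation time) later, averaged
#' over replicates. Lower gamma enlarges the proliferative compartment and
#' (in the adhesion mode) raises drag, so counts grow as gamma falls.
#'
#' @param spec an [experiment_spec()].
#' @return Data frame: gamma, drag_mode, mean/sd of the final cell count,
#'   replicate count.
#' @export
overcrowding_experiment <- function(spec) {
  rows <- list()
  for (rep in seq_len(spec$replicates)) {
    eq <- .equilibrated(spec, rep)
    for (gamma in spec$gamma_grid) {
      for (mode in c("uniform", "adhesion")) {
        cfg <- .rep_config(spec, rep, drag_mode = mode,
                           mutation = protocol_all(gamma),
                           takeover_multiplier = 1e6)
        rec <- run_simulation(cfg, init_population = eq)
        m <- rec$metrics
        rows[[length(rows) + 1]] <- data.frame(
          rep = rep, gamma = gamma, drag_mode = mode,
          cells_start = m$cells[1], cells_end = m$cells[nrow(m)])
      }
    }
  }
  raw <- do.call(rbind, rows)
  agg <- aggregate(cells_end ~ gamma + drag_mode, raw, mean)
  names(agg)[3] <- "mean_cells"
  agg$sd_cells <- aggregate(cells_end ~ gamma + drag_mode, raw, sd)$cells_end
  agg$replicates <- spec$replicates
  attr(agg, "raw") <- raw
  agg
}

#' Persistence of a mutant patch
#'
#' Mutates a 2-CD-radius patch centred at height `H0` in an equilibrated
#' crypt and records the minimum height of any mutant cell at the requested
#' times. When every mutant has been sloughed the entry is `NA` (extinct),
#' so averages are over surviving-mutant crypts; the extinct fraction is
#' reported alongside.
#'
#' @param spec an [experiment_spec()].
#' @return Data frame: gamma, H0, time, mean minimum mutant height over
#'   surviving replicates, number surviving, extinct fraction.
#' @export
persistence_experiment <- function(spec) {
  rows <- list()
  for (rep in seq_len(spec$replicates)) {
    eq <- .equilibrated(spec, rep)
    for (gamma in spec$gamma_grid) {
      for (H0 in spec$H0) {
        cfg <- .rep_config(spec, rep, drag_mode = "adhesion",
                           mutation = protocol_patch(H0, 2, gamma),
                           takeover_multiplier = 1e6)
        rec <- run_simulation(cfg, init_population = eq)
        m <- rec$metrics
        idx <- vapply(spec$record_times,
                      function(t) which.min(abs(m$time - t)), 1L)
        rows[[length(rows) + 1]] <- data.frame(
          rep = rep, gamma = gamma, H0 = H0, time = m$time[idx],
          min_mutant_height = m$min_mutant_height[idx])
      }
    }
  }
  raw <- do.call(rbind, rows)
  agg <- aggregate(min_mutant_height ~ gamma + H0 + time, raw,
                   function(v) mean(v, na.rm = TRUE), na.action = NULL)
  agg$surviving <- aggregate(min_mutant_height ~ gamma + H0 + time, raw,
                             function(v) sum(!is.na(v)),
                             na.action = NULL)$min_mutant_height
  agg$extinct_fraction <- 1 - agg$surviving / spec$replicates
  attr(agg, "raw") <- raw
  agg
}

#' Probability of mutant takeover
#'
#' Mutates a random fraction of cells in an equilibrated crypt and runs to
#' a verdict: mutant takeover (no healthy cells left, or mutant
#' overcrowding beyond the takeover multiplier), healthy takeover (no
#' mutants left), or censored at `max_time`. Reports the frequency of
#' mutant takeover with a normal-approximation binomial interval.
#'
#' @param spec an [experiment_spec()].
#' @param drag_mode `"adhesion"` or `"uniform"` (the neutral-drift
#'   control).
#' @export
takeover_experiment <- function(spec, drag_mode = "adhesion") {
  rows <- list()
  for (rep in seq_len(spec$replicates)) {
    eq <- .equilibrated(spec, rep)
    for (gamma in spec$gamma_grid) {
      for (frac in spec$fractions) {
        cfg <- .rep_config(spec, rep, drag_mode = drag_mode,
                           mutation = protocol_fraction(frac, gamma))
        cfg$observation_time <- spec$max_time
        rec <- run_simulation(cfg, init_population = eq,
                              stop_on_verdict = TRUE)
        rows[[length(rows) + 1]] <- data.frame(
          rep = rep, gamma = gamma, fraction = frac,
          verdict = rec$verdict,
          time = rec$metrics$time[nrow(rec$metrics)])
      }
    }
  }
  raw <- do.call(rbind, rows)
  agg <- aggregate(verdict ~ gamma + fraction, raw,
                   function(v) mean(v == "mutant"))
  names(agg)[3] <- "p_mutant"
  nrep <- spec$replicates
  se <- sqrt(pmax(agg$p_mutant * (1 - agg$p_mutant), 0) / nrep)
  agg$ci_lo <- pmax(agg$p_mutant - 1.96 * se, 0)
  agg$ci_hi <- pmin(agg$p_mutant + 1.96 * se, 1)
  agg$censored <- aggregate(verdict ~ gamma + fraction, raw,
                            function(v) mean(v == "censored"))$verdict
  agg$replicates <- nrep
  attr(agg, "raw") <- raw
  agg
}

#' Cell areas in heterogeneous crypts
#'
#' Mutates a random half of the cells of an equilibrated crypt (default
#' Tan model, gamma = 0.5), runs 20 h, and measures every cell's Voronoi
#' area, stratified by mutation status. In heterogeneous crypts the mutant
#' cells - larger drag, larger proliferative range - retain more area than
#' their healthy neighbours even as the whole tissue gets denser.
#'
#' @param spec an [experiment_spec()]; `gamma_grid[1]` is the mutant
#'   gamma and `fractions[1]` the mutant fraction.
#' @return List: `summary` data frame (per-type mean/sd areas pooled over
#'   crypts), `areas` per-cell data frame for histograms.
#' @export
area_experiment <- function(spec) {
  gamma <- spec$gamma_grid[1]
  frac <- spec$fractions[1]
  cells <- list()
  for (rep in seq_len(spec$replicates)) {
    eq <- .equilibrated(spec, rep)
    cfg <- .rep_config(spec, rep, drag_mode = "adhesion",
                       mutation = protocol_fraction(frac, gamma),
                       takeover_multiplier = 1e6)
    cfg$observation_time <- spec$observation_time
    rec <- run_simulation(cfg, init_population = eq)
    snap <- population_snapshot(rec$population)
    snap$rep <- rep
    cells[[rep]] <- snap
  }
  areas <- do.call(rbind, cells)
  areas$type <- ifelse(areas$gamma < 1, "mutant", "healthy")
  summary <- aggregate(area ~ type, areas, mean)
  names(summary)[2] <- "mean_area"
  summary$sd_area <- aggregate(area ~ type, areas, sd)$area
  summary$n_cells <- aggregate(area ~ type, areas, length)$area
  list(summary = summary, areas = areas)
}
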