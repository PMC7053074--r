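#' Wnt level at a crypt height
#'
#' The imposed Wnt gradient is static and linear: 1 at the crypt base,
#' decreasing to 0 at the top (and 0 above it).
#'
#' @param y height(s) in cell diameters (>= 0).
#' @param height crypt height in CD.
#' @export
wnt_level <- function(y, height = 20) {
  stopifnot(all(y >= 0))
  pmax(1 - y / height, 0)
}

#' Mutation protocols
#'
#' Constructors for the three ways mutations are introduced into an
#' equilibrated crypt: mutate every cell (`protocol_all`), mutate a circular
#' patch of radius `radius` CD centred at height `H0` (`protocol_patch`,
#' distance Euclidean with periodic x), or mutate a uniformly random
#' fraction `p` of cells (`protocol_fraction`). `protocol_none()` leaves
#' the crypt healthy.
#'
#' @param gamma mutation level assigned to selected cells, in `[0, 1]`.
#' @param H0 patch centre height in CD.
#' @param radius patch radius in CD.
#' @param p fraction of cells to mutate, in `[0, 1]`.
#' @export
protocol_all <- function(gamma) {
  stopifnot(gamma >= 0, gamma <= 1)
  structure(list(kind = "all", gamma = gamma), class = "mutation_protocol")
}

#' @rdname protocol_all
#' @export
protocol_patch <- function(H0, radius = 2, gamma) {
  stopifnot(gamma >= 0, gamma <= 1, radius > 0)
  structure(list(kind = "patch", H0 = H0, radius = radius, gamma = gamma),
            class = "mutation_protocol")
}

#' @rdname protocol_all
#' @export
protocol_fraction <- function(p, gamma) {
  stopifnot(gamma >= 0, gamma <= 1, p >= 0, p <= 1)
  structure(list(kind = "fraction", p = p, gamma = gamma),
            class = "mutation_protocol")
}

#' @rdname protocol_all
#' @export
protocol_none <- function() {
  structure(list(kind = "none"), class = "mutation_protocol")
}

#' Apply a mutation protocol to a population
#'
#' Sets `gamma` for the selected cells. Subcellular states are left
#' untouched: the dynamics respond through the changed rates, so
#' concentrations relax continuously to the mutant equilibrium.
#'
#' @param pop a `crypt_population`.
#' @param protocol a mutation protocol.
#' @export
mutate_population <- function(pop, protocol) {
  stopifnot(inherits(protocol, "mutation_protocol"))
  sel <- switch(
    protocol$kind,
    none = integer(0),
    all = seq_len(pop$n),
    patch = {
      if (protocol$H0 < 0 || protocol$H0 > pop$height)
        stop("patch centre height outside the crypt")
      cx <- pop$width / 2 # patch centre x: mid-domain (x is periodic)
      dx <- abs(pop$x - cx)
      dx <- pmin(dx, pop$width - dx)
      which(dx^2 + (pop$y - protocol$H0)^2 <= protocol$radius^2)
    },
    fraction = {
      k <- round(protocol$p * pop$n)
      sample(pop$n, k)
    }
  )
  if (length(sel) > 0) pop$gamma[sel] <- protocol$gamma
  pop
}

#' Simulation configuration
#'
#' @param model `"vl"`, `"tan"`, or an adapter from [bind_ode_model()].
#' @param params optional subcellular parameter override.
#' @param drag_mode `"adhesion"` (drag from the adhesion-complex level via
#'   the drag law) or `"uniform"` (every cell has drag 1).
#' @param mechanics a [mechanics_config()].
#' @param equilibration_time hours run before the mutation protocol is
#'   applied (time is relabelled to 0 at mutation).
#' @param observation_time hours run after mutation.
#' @param mutation a mutation protocol.
#' @param seed RNG seed.
#' @param w_star Wnt level of the healthy proliferative boundary used to
#'   calibrate the proliferation threshold.
#' @param threshold optional explicit proliferation threshold; by default
#'   the steady-state transcription complex at `(w_star, 1)`.
#' @param drag_params optional explicit [drag_parameters()].
#' @param takeover_multiplier a crypt whose cell count exceeds this
#'   multiple of the equilibrium count is declared taken over by mutants.
#' @param record_interval spacing of recorded metrics, hours.
#' @param snapshot_times times (post-mutation) at which full per-cell
#'   snapshots are kept.
#' @export
simulation_config <- function(model = "vl", params = NULL,
                              drag_mode = c("adhesion", "uniform"),
                              mechanics = mechanics_config(),
                              equilibration_time = 500,
                              observation_time = 50,
                              mutation = protocol_none(),
                              seed = 1,
                              w_star = 0.75,
                              threshold = NULL,
                              drag_params = NULL,
                              takeover_multiplier = 2,
                              record_interval = 1,
                              snapshot_times = numeric(0)) {
  drag_mode <- match.arg(drag_mode)
  stopifnot(equilibration_time >= 0, observation_time >= 0,
            takeover_multiplier > 1)
  structure(list(model = model, params = params, drag_mode = drag_mode,
                 mechanics = mechanics,
                 equilibration_time = equilibration_time,
                 observation_time = observation_time, mutation = mutation,
                 seed = seed, w_star = w_star, threshold = threshold,
                 drag_params = drag_params,
                 takeover_multiplier = takeover_multiplier,
                 record_interval = record_interval,
                 snapshot_times = snapshot_times),
            class = "simulation_config")
}

# resolve coupling constants once per run
.coupling_constants <- function(pop, config) {
  adapter <- pop$adapter
  list(
    threshold = if (!is.null(config$threshold)) config$threshold
    else .adapter_threshold(adapter, config$w_star),
    dp = if (!is.null(config$drag_params)) config$drag_params
    else .adapter_drag_parameters(adapter),
    uniform = identical(config$drag_mode, "uniform")
  )
}

#' One multiscale step
#'
#' Advances the crypt by one mechanics timestep, in order: (1) integrate
#' every cell's subcellular ODEs over `dt` at the Wnt level of its current
#' height and its own gamma; (2) re-evaluate proliferative status against
#' the transcription-complex threshold - a cell below threshold becomes
#' differentiated permanently (sticky), a non-differentiated cell above it
#' is proliferative; (3) set each cell's drag from its adhesion-complex
#' level (or 1 in uniform mode); (4) age cycles and perform due divisions;
#' (5) recompute connectivity and spring forces and update positions;
#' (6) clamp the base and slough the top.
#'
#' @param pop a `crypt_population`.
#' @param config a [simulation_config()].
#' @param coupling internal: precomputed coupling constants.
#' @export
crypt_step <- function(pop, config, coupling = NULL) {
  if (is.null(coupling)) coupling <- .coupling_constants(pop, config)
  dt <- pop$dt
  adapter <- pop$adapter

  # (1) subcellular dynamics at the local Wnt level
  W <- wnt_level(pop$y, pop$height)
  pop$states <- adapter$advance(pop$states, W, pop$gamma, dt)

  # (2) proliferative status; differentiation is irreversible
  above <- is_proliferative(adapter$transcription_level(pop$states),
                            coupling$threshold)
  newly_diff <- !above & !pop$differentiated
  pop$differentiated[newly_diff] <- TRUE
  # a differentiated cell abandons any cycle in progress and never divides;
  # age keeps running because it also clocks sibling-pair maturation
  pop$proliferative <- above & !pop$differentiated

  # (3) drag from the adhesion complex
  pop$drag <- if (coupling$uniform) rep(1, pop$n)
  else drag(adapter$adhesion_level(pop$states),
            coupling$dp)

  # (4) cycle progression and division
  pop$age <- pop$age + dt
  pop <- attempt_divisions(pop)

  # (5) mechanics
  tess <- crypt_tessellation(pop)
  forces <- .net_forces(pop, tess$edges)
  pop <- step_positions(pop, forces, dt)

  # (6) boundaries
  pop <- slough(pop)

  pop$time <- pop$time + dt
  pop
}

#' Equilibrate a crypt
#'
#' Runs the healthy multiscale model for `hours` so the tissue reaches
#' dynamic equilibrium (stable proliferative compartment and cell count)
#' before an experiment perturbs it.
#'
#' @param config a [simulation_config()].
#' @param hours equilibration duration; defaults to the config value.
#' @param pop optional starting population.
#' @export
equilibrate_crypt <- function(config, hours = config$equilibration_time,
                              pop = NULL) {
  if (is.null(pop)) {
    set.seed(config$seed)
    pop <- initialize_crypt(config$mechanics, config$model, config$params)
  }
  coupling <- .coupling_constants(pop, config)
  steps <- round(hours / pop$dt)
  for (k in seq_len(steps)) pop <- crypt_step(pop, config, coupling)
  pop
}

#' Run a multiscale crypt simulation
#'
#' Equilibrates the crypt, applies the mutation protocol at (relabelled)
#' time 0, then advances until `observation_time` or until a takeover
#' verdict is reached: `"mutant"` when no healthy cell remains or the cell
#' count exceeds `takeover_multiplier` times the equilibrium count (mutant
#' overcrowding), `"healthy"` when no mutant cell remains, `"censored"`
#' otherwise.
#'
#' @param config a [simulation_config()].
#' @param init_population optional pre-equilibrated population; when given,
#'   the equilibration phase is skipped and `config$seed` seeds only the
#'   post-mutation randomness.
#' @param stop_on_verdict end the run as soon as the takeover verdict is
#'   decided (used by the takeover experiment).
#' @return A `simulation_record`: data frame `metrics` (time, cell count,
#'   proliferative-compartment height, minimum mutant height), `snapshots`,
#'   the `verdict`, the equilibrium count, and the final population.
#' @export
run_simulation <- function(config, init_population = NULL,
                           stop_on_verdict = FALSE) {
  if (is.null(init_population)) {
    pop <- equilibrate_crypt(config)
  } else {
    set.seed(config$seed)
    pop <- init_population
  }
  equilibrium_count <- pop$n
  pop$time <- 0
  pop <- mutate_population(pop, config$mutation)
  coupling <- .coupling_constants(pop, config)

  dt <- pop$dt
  steps <- round(config$observation_time / dt)
  rec_every <- max(1L, round(config$record_interval / dt))
  snap_steps <- unique(round(config$snapshot_times / dt))

  metrics <- list()
  snapshots <- list()
  record <- function(pop) {
    mutant <- pop$gamma < 1
    prolif <- pop$proliferative & !pop$differentiated
    data.frame(
      time = pop$time,
      cells = pop$n,
      prolif_height = if (any(prolif)) max(pop$y[prolif]) else NA_real_,
      min_mutant_height = if (any(mutant)) min(pop$y[mutant]) else NA_real_,
      mutants = sum(mutant)
    )
  }
  metrics[[1]] <- record(pop)
  if (0 %in% snap_steps) snapshots[["0"]] <- population_snapshot(pop)

  verdict <- "censored"
  for (k in seq_len(steps)) {
    pop <- crypt_step(pop, config, coupling)
    if (k %% rec_every == 0) metrics[[length(metrics) + 1]] <- record(pop)
    if (k %in% snap_steps)
      snapshots[[format(pop$time)]] <- population_snapshot(pop)

    mutants <- sum(pop$gamma < 1)
    if (mutants == pop$n ||
        pop$n > config$takeover_multiplier * equilibrium_count) {
      verdict <- "mutant"
    } else if (mutants == 0) {
      verdict <- "healthy"
    } else {
      verdict <- "censored"
    }
    if (stop_on_verdict && verdict != "censored") break
  }

  structure(list(metrics = do.call(rbind, metrics),
                 snapshots = snapshots,
                 verdict = verdict,
                 equilibrium_count = equilibrium_count,
                 population = pop),
            class = "simulation_record")
}

#' @export
print.simulation_record <- function(x, ...) {
  m <- x$metrics
  cat(sprintf(
    "<simulation_record: %d samples over %.1f h, %d -> %d cells, verdict %s>\n",
    nrow(m), max(m$time), x$equilibrium_count, m$cells[nrow(m)], x$verdict))
  invisible(x)
}

#' Write a simulation record to CSV files
#'
#' @param record a `simulation_record`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @export
write_simulation_record <- function(record, dir, prefix = "crypt") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(record$metrics,
            file.path(dir, paste0(prefix, "_metrics.csv")),
            row.names = FALSE)
  for (nm in names(record$snapshots)) {
    write.csv(record$snapshots[[nm]],
              file.path(dir, paste0(prefix, "_snapshot_t", nm, ".csv")),
              row.names = FALSE)
  }
  invisible(dir)
}

#' Read a simulation configuration from a JSON file
#'
#' The file mirrors [simulation_config()]: top-level keys are the
#' constructor arguments; `mechanics` is a nested object of
#' [mechanics_config()] arguments; `mutation` is an object with a `kind`
#' ("none", "all", "patch", "fraction") plus that protocol's fields;
#' `params` is a nested object of subcellular parameter overrides.
#'
#' @param path path to a JSON file.
#' @return A [simulation_config()].
#' @export
read_simulation_config <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("reading JSON configs requires the jsonlite package")
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- raw
  if (!is.null(raw$mechanics))
    args$mechanics <- do.call(mechanics_config, as.list(raw$mechanics))
  if (!is.null(raw$mutation)) {
    m <- as.list(raw$mutation)
    kind <- m$kind
    m$kind <- NULL
    args$mutation <- switch(kind,
                            none = protocol_none(),
                            all = do.call(protocol_all, m),
                            patch = do.call(protocol_patch, m),
                            fraction = do.call(protocol_fraction, m),
                            stop("unknown mutation kind: ", kind))
  }
  if (!is.null(raw$params)) {
    model <- if (!is.null(raw$model)) raw$model else "vl"
    args$params <- do.call(default_parameters,
                           c(list(model = model), as.list(raw$params)))
  }
  do.call(simulation_config, args)
}
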