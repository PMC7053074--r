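#' Mechanics configuration
#'
#' Tissue-level constants of the cell-centre model. Lengths are in cell
#' diameters (1 CD = 10 um), times in hours. The spring constant and
#' timestep are the cell-centre framework conventions for this model family
#' (they are not varied in any experiment).
#'
#' Defaults: `mu = 50` with `dt = 1/240` h. The spring constant must be
#' large enough that spring compression can drive the homeostatic upward
#' flux without runaway densification of the proliferative zone (see the
#' methods vignette); the timestep sits inside the forward-Euler stability
#' limit `mu * dt * degree < 2` for Delaunay degree ~6.
#'
#' @param mu spring constant (force per CD).
#' @param dt mechanics timestep in hours.
#' @param width crypt circumference in CD.
#' @param height crypt height in CD (slough boundary).
#' @param cutoff neighbour cutoff: Delaunay edges longer than this are
#'   discarded (suppresses spurious long edges along the free top boundary).
#' @param division_sep separation of newborn daughter centres in CD.
#' @param maturation time over which a newborn pair's rest length grows to
#'   1 CD (equal to the M phase).
#' @export
mechanics_config <- function(mu = 50, dt = 1 / 240, width = 10, height = 20,
                             cutoff = 1.5, division_sep = 0.1,
                             maturation = 1) {
  cfg <- list(mu = mu, dt = dt, width = width, height = height,
              cutoff = cutoff, division_sep = division_sep,
              maturation = maturation)
  stopifnot(all(unlist(cfg) > 0))
  structure(cfg, class = "mechanics_config")
}

#' Sample cell-cycle phase durations
#'
#' The cycle is M (1 h), G1 (Normal(2, 1) truncated to positive values, by
#' rejection), S (5 h) and G2 (4 h); the total duration is therefore a
#' truncated Normal(12, 1) draw, always above 10 h.
#'
#' @param n number of cells to draw for.
#' @return List with vectors `G1` and `total`.
#' @export
sample_cycle_durations <- function(n = 1) {
  g1 <- numeric(n)
  todo <- seq_len(n)
  while (length(todo) > 0) {
    draw <- rnorm(length(todo), mean = 2, sd = 1)
    ok <- draw > 0
    g1[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  list(G1 = g1, total = g1 + 10)
}

#' Cell-cycle phase from age
#'
#' @param age hours since birth.
#' @param G1 the cell's G1 duration draw.
#' @param proliferative logical; differentiated cells have no phase.
#' @return Character vector: "M", "G1", "S", "G2" or "none".
#' @export
cycle_phase <- function(age, G1, proliferative = TRUE) {
  phase <- rep("none", length(age))
  p <- which(rep_len(proliferative, length(age)))
  a <- age[p]
  g <- G1[p]
  phase[p] <- ifelse(a < 1, "M",
                     ifelse(a < 1 + g, "G1",
                            ifelse(a < 6 + g, "S", "G2")))
  phase
}

#' Build an initial crypt cell population
#'
#' Places one cell per site of an offset (honeycomb-like) lattice filling
#' the crypt rectangle at unit spacing: `width` columns by `height` rows,
#' alternate rows shifted by half a cell diameter. Every cell is healthy
#' (`gamma = 1`), carries its subcellular model at the steady state for the
#' local Wnt level, and starts at a uniformly random age within a freshly
#' sampled cycle duration, so divisions desynchronise immediately.
#'
#' @param config a [mechanics_config()].
#' @param model `"vl"`, `"tan"`, or an adapter from [bind_ode_model()].
#' @param params optional subcellular parameter override.
#' @param seed optional RNG seed for reproducible construction.
#' @return A `crypt_population`.
#' @export
initialize_crypt <- function(config = mechanics_config(), model = "vl",
                             params = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  adapter <- as_model_adapter(model, params)

  ncol_ <- as.integer(round(config$width))
  nrow_ <- as.integer(round(config$height))
  ij <- expand.grid(i = seq_len(ncol_) - 1L, j = seq_len(nrow_) - 1L)
  x <- (ij$i + 0.25 + 0.5 * (ij$j %% 2)) %% config$width
  y <- (ij$j + 0.5) * config$height / nrow_
  n <- length(x)

  W <- wnt_level(y, config$height)
  states <- adapter$steady_states(W, rep(1, n))

  dur <- sample_cycle_durations(n)
  age <- runif(n) * dur$total

  pop <- list(
    n = n,
    id = seq_len(n),
    next_id = n + 1L,
    x = x, y = y,
    gamma = rep(1, n),
    states = states,
    age = age,
    G1 = dur$G1,
    duration = dur$total,
    proliferative = rep(TRUE, n),
    differentiated = rep(FALSE, n),
    drag = rep(1, n),
    partner = rep(NA_integer_, n),
    time = 0,
    adapter = adapter,
    mu = config$mu, dt = config$dt, width = config$width,
    height = config$height, cutoff = config$cutoff,
    division_sep = config$division_sep, maturation = config$maturation
  )
  class(pop) <- "crypt_population"
  pop
}

#' @export
print.crypt_population <- function(x, ...) {
  cat(sprintf(
    "<crypt_population: %d cells, model %s, t = %.2f h, %d mutant>\n",
    x$n, x$adapter$model, x$time, sum(x$gamma < 1)))
  invisible(x)
}

.subset_population <- function(pop, idx) {
  for (f in c("id", "x", "y", "gamma", "age", "G1", "duration",
              "proliferative", "differentiated", "drag", "partner")) {
    pop[[f]] <- pop[[f]][idx]
  }
  pop$states <- pop$states[idx, , drop = FALSE]
  pop$n <- length(idx)
  # orphaned maturation partners keep their rest length schedule via age,
  # but a dangling partner id must not match a surviving cell
  pop$partner[!(pop$partner %in% pop$id)] <- NA_integer_
  pop
}

#' Divide every cell whose cycle is complete
#'
#' A proliferative, non-differentiated cell whose age has reached its
#' sampled cycle duration is replaced by two daughters placed half the
#' division separation either side of the parent centre, in a uniformly
#' random direction. Daughters inherit the parent's mutation level and a
#' copy of its subcellular state (concentrations are intensive; no
#' halving), draw fresh cycle durations, and form a maturing sibling pair.
#'
#' @param pop a `crypt_population`.
#' @return The population with divisions applied.
#' @export
attempt_divisions <- function(pop) {
  due <- which(pop$proliferative & !pop$differentiated &
                 pop$age >= pop$duration)
  if (length(due) == 0) return(pop)
  for (i in due) {
    theta <- runif(1, 0, 2 * pi)
    u <- c(cos(theta), sin(theta)) * pop$division_sep / 2
    dur <- sample_cycle_durations(2)
    id2 <- pop$next_id
    pop$next_id <- pop$next_id + 1L

    # parent row becomes daughter 1
    x0 <- pop$x[i]
    y0 <- pop$y[i]
    pop$x[i] <- (x0 + u[1]) %% pop$width
    pop$y[i] <- max(y0 + u[2], 0)
    pop$age[i] <- 0
    pop$G1[i] <- dur$G1[1]
    pop$duration[i] <- dur$total[1]
    parent_partner <- pop$id[i]
    pop$partner[i] <- id2

    pop$id <- c(pop$id, id2)
    pop$x <- c(pop$x, (x0 - u[1]) %% pop$width)
    pop$y <- c(pop$y, max(y0 - u[2], 0))
    pop$gamma <- c(pop$gamma, pop$gamma[i])
    pop$states <- rbind(pop$states, pop$states[i, , drop = FALSE])
    pop$age <- c(pop$age, 0)
    pop$G1 <- c(pop$G1, dur$G1[2])
    pop$duration <- c(pop$duration, dur$total[2])
    pop$proliferative <- c(pop$proliferative, pop$proliferative[i])
    pop$differentiated <- c(pop$differentiated, pop$differentiated[i])
    pop$drag <- c(pop$drag, pop$drag[i])
    pop$partner <- c(pop$partner, parent_partner)
    pop$n <- pop$n + 1L
  }
  pop
}

#' Population snapshot as a data frame
#'
#' One row per cell: position, mutation level, cycle phase, proliferative
#' status, drag, Voronoi area and the coupling readouts of the subcellular
#' state. Suitable for CSV export and plotting.
#'
#' @param pop a `crypt_population`.
#' @param areas optional precomputed Voronoi areas.
#' @export
population_snapshot <- function(pop, areas = NULL) {
  if (is.null(areas)) areas <- voronoi_areas(pop)
  data.frame(
    time = pop$time,
    id = pop$id,
    x = pop$x,
    y = pop$y,
    gamma = pop$gamma,
    phase = cycle_phase(pop$age, pop$G1,
                        pop$proliferative & !pop$differentiated),
    proliferative = pop$proliferative & !pop$differentiated,
    drag = pop$drag,
    area = areas,
    adhesion = pop$adapter$adhesion_level(pop$states),
    transcription = pop$adapter$transcription_level(pop$states)
  )
}
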