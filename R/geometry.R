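#' Periodic tessellation of a crypt population
#'
#' Computes cell connectivity and Voronoi areas on the periodic strip in one
#' sweep. Connectivity is the Delaunay triangulation of the cell centres
#' with x-periodicity (cells interact across the seam), with edges longer
#' than the neighbour cutoff discarded. Areas are the Voronoi regions
#' clipped to the crypt rectangle `[0, width] x [0, height]`, in square cell
#' diameters.
#'
#' @param pop a `crypt_population`.
#' @return List with `edges` (two-column index matrix, row indices into the
#'   population, `i < j`) and `areas` (numeric, one per cell).
#' @export
crypt_tessellation <- function(pop) {
  tessellation_cpp(pop$x, pop$y, pop$width, pop$height, pop$cutoff)
}

#' @rdname crypt_tessellation
#' @export
neighbours <- function(pop) {
  if (pop$n < 3) stop("need at least 3 cells for a triangulation")
  crypt_tessellation(pop)$edges
}

#' @rdname crypt_tessellation
#' @export
voronoi_areas <- function(pop) {
  if (pop$n < 3) stop("need at least 3 cells for a tessellation")
  crypt_tessellation(pop)$areas
}

# minimum-image displacement from cell i to cell j (vectors of indices)
.displacement <- function(pop, i, j) {
  dx <- pop$x[j] - pop$x[i]
  dx <- dx - pop$width * round(dx / pop$width)
  cbind(dx = dx, dy = pop$y[j] - pop$y[i])
}

# rest lengths for an edge list: 1 CD for mature pairs, growing linearly
# from the division separation for newborn sibling pairs
.rest_lengths <- function(pop, edges) {
  s <- rep(1, nrow(edges))
  if (nrow(edges) == 0) return(s)
  i <- edges[, 1]
  j <- edges[, 2]
  sib <- !is.na(pop$partner[i]) & pop$partner[i] == pop$id[j] &
    pop$age[i] < pop$maturation
  if (any(sib)) {
    frac <- pop$age[i[sib]] / pop$maturation
    s[sib] <- pop$division_sep + (1 - pop$division_sep) * frac
  }
  s
}

#' Spring force between two connected cells
#'
#' Linear spring along the (minimum-image) separation vector:
#' `F_ij = mu * r_hat_ij * (|r_ij| - s_ij)`, acting on cell `i` toward `j`
#' when the pair is overstretched. The rest length `s_ij` is one cell
#' diameter for mature pairs; for a newborn sibling pair it grows linearly
#' from the division separation to 1 CD over the maturation hour.
#'
#' @param i,j row indices of the two cells.
#' @param pop a `crypt_population`.
#' @return Length-2 force vector on cell `i`.
#' @export
pairwise_force <- function(i, j, pop) {
  d <- .displacement(pop, i, j)
  len <- sqrt(sum(d^2))
  if (len < 1e-12) stop("coincident cell centres: force direction undefined")
  s <- .rest_lengths(pop, matrix(c(i, j), nrow = 1))
  as.numeric(pop$mu * (len - s) * d / len)
}

# net force on every cell from an edge list; returns an n x 2 matrix
.net_forces <- function(pop, edges) {
  if (nrow(edges) == 0) return(matrix(0, pop$n, 2))
  net_forces_cpp(pop$x, pop$y, edges, .rest_lengths(pop, edges), pop$mu,
                 pop$width)
}

#' Overdamped position update
#'
#' Forward-Euler step of the overdamped equation of motion
#' `eta_i dr_i/dt = F_i`: each cell moves by `dt / eta_i * F_i`. x is
#' wrapped into the periodic domain; the solid crypt base clamps y at 0.
#' A displacement above one cell diameter in a single step aborts (the
#' timestep is too large for the force scale).
#'
#' @param pop a `crypt_population`.
#' @param forces n x 2 matrix of net forces (from the current edge set).
#' @param dt timestep in hours.
#' @export
step_positions <- function(pop, forces, dt = pop$dt) {
  disp <- forces * (dt / pop$drag)
  if (any(sqrt(disp[, 1]^2 + disp[, 2]^2) > 1)) {
    stop("cell displacement exceeded 1 cell diameter in one step; ",
         "reduce dt")
  }
  pop$x <- (pop$x + disp[, 1]) %% pop$width
  pop$y <- pmax(pop$y + disp[, 2], 0)
  pop
}

#' Remove cells sloughed at the crypt top
#'
#' Cells whose vertical position reaches the crypt height are shed into the
#' lumen and removed from the simulation.
#'
#' @param pop a `crypt_population`.
#' @export
slough <- function(pop) {
  keep <- pop$y < pop$height
  if (all(keep)) return(pop)
  .subset_population(pop, which(keep))
}
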