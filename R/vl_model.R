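#' The one-compartment beta-catenin model (VL)
#'
#' State of the destruction-complex model: active destruction complexes `D`,
#' axin `X`, ubiquitinated beta-catenin `C_u`, open and closed free
#' beta-catenin `C_o`/`C_c`, adhesion molecules `A`, the
#' beta-catenin/adhesion complex `C_A`, transcription molecules `T`, the
#' open/closed beta-catenin/TCF transcription complexes `C_oT`/`C_cT`, and
#' Wnt target protein `Y`. The composites `C_F = C_o + C_c` (free
#' beta-catenin) and `C_T = C_oT + C_cT` (total transcription complex) are
#' always derived, never stored.
#'
#' @param D,X,C_u,C_o,C_c,A,C_A,T,C_oT,C_cT,Y non-negative concentrations.
#' @return Named numeric vector of class `vl_state`.
#' @export
vl_state <- function(D = 0, X = 0, C_u = 0, C_o = 0, C_c = 0, A = 0,
                     C_A = 0, T = 0, C_oT = 0, C_cT = 0, Y = 0) {
  y <- c(D = D, X = X, C_u = C_u, C_o = C_o, C_c = C_c, A = A, C_A = C_A,
         T = T, C_oT = C_oT, C_cT = C_cT, Y = Y)
  .check_state(y)
  structure(y, class = "vl_state")
}

.vl_state_names <- c("D", "X", "C_u", "C_o", "C_c", "A", "C_A", "T",
                     "C_oT", "C_cT", "Y")
.tan_state_names <- c("B_C", "B_N", "L_C", "N_C", "L_N", "N_N")

.check_state <- function(y) {
  if (anyNA(y) || any(y < 0))
    stop("state components must be non-negative")
  invisible(y)
}

#' @rdname vl_state
#' @param state a `vl_state`.
#' @export
vl_C_F <- function(state) unname(state[["C_o"]] + state[["C_c"]])

#' @rdname vl_state
#' @export
vl_C_T <- function(state) unname(state[["C_oT"]] + state[["C_cT"]])

#' Time derivative of the VL model
#'
#' Evaluates the right-hand side of the destruction-complex ODE system. The
#' Wnt level modifies the destruction-complex and axin turnover rates
#' (`d_D + xi_D W`, `d_Dx + xi_Dx W`, `d_X + xi_X W`); the mutation
#' parameter gamma multiplies the destruction-complex formation rate `s_D`,
#' so `gamma < 1` models APC knockdown.
#'
#' @param state a [vl_state()].
#' @param params a [vl_parameters()] set.
#' @param env a [cell_environment()].
#' @return Named numeric vector: d(state)/dt in concentration per hour.
#' @export
vl_rhs <- function(state, params = vl_parameters(), env) {
  .check_state(state)
  dy <- vl_rhs_cpp(as.numeric(state), .param_vector(params), env$W, env$gamma)
  setNames(dy, .vl_state_names)
}

#' Closed-form steady state of the VL model
#'
#' Evaluates the analytic fixed point of the destruction-complex model for a
#' given Wnt level and mutation level. `gamma = 0` is allowed (the
#' destruction complex vanishes and the formulas stay finite).
#'
#' @inheritParams vl_rhs
#' @return A [vl_state()] at equilibrium.
#' @export
vl_steady_state <- function(params = vl_parameters(), env) {
  W <- env$W
  gamma <- env$gamma
  dD <- params$d_D + params$xi_D * W
  dDx <- params$d_Dx + params$xi_Dx * W
  dX <- params$d_X + params$xi_X * W
  pc <- params$p_c + params$xi_c * W

  D <- gamma * params$s_D * params$s_X /
    (gamma * params$s_D * dD + dX * (dD + dDx))
  X <- if (gamma > 0) D * (dD + dDx) / (gamma * params$s_D) else
    params$s_X / dX

  # free beta-catenin from its quadratic balance, then the open/closed split
  a <- params$s_C - params$d_C * params$K_D - params$p_u * D
  C_F <- (a + sqrt(a^2 + 4 * params$s_C * params$d_C * params$K_D)) /
    (2 * params$d_C)
  zstar <- params$d_C + params$p_u * D / (C_F + params$K_D)
  b <- params$s_C - pc - zstar * params$K_C
  C_o <- (b + sqrt(b^2 + 4 * zstar * params$s_C * params$K_C)) / (2 * zstar)
  C_c <- C_F - C_o
  if (C_c < 0 && C_c > -1e-9) C_c <- 0

  C_u <- params$p_u * D * C_F / (params$d_u * (C_F + params$K_D))
  A <- params$s_A / params$d_A
  C_A <- A * params$s_CA * C_o / params$d_CA
  T <- params$s_T / params$d_T
  C_oT <- params$s_CT * T * C_o / params$d_CT
  C_cT <- if (C_o > 0) C_oT * C_c / C_o else 0
  Y <- params$s_Y * params$s_T * params$s_CT * C_F /
    (params$d_Y * (params$s_T * params$s_CT * C_F +
                     params$d_T * params$d_CT * params$K_T))

  vl_state(D = D, X = X, C_u = C_u, C_o = C_o, C_c = C_c, A = A, C_A = C_A,
           T = T, C_oT = C_oT, C_cT = C_cT, Y = Y)
}
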