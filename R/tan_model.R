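#' The two-compartment beta-catenin model (Tan)
#'
#' State of the binding/shuttling model: free beta-catenin in the
#' cytosol-membrane (`B_C`) and nucleus (`B_N`), free ligands (`L_C`:
#' adhesion molecules, `L_N`: transcription molecules), and bound complexes
#' (`N_C`: adhesion complex, `N_N`: nuclear transcription complex). The
#' sums `L_C + N_C` and `L_N + N_N` are conserved along every trajectory.
#'
#' @param B_C,B_N,L_C,N_C,L_N,N_N non-negative concentrations.
#' @return Named numeric vector of class `tan_state`.
#' @export
tan_state <- function(B_C = 0, B_N = 0, L_C = 0, N_C = 0, L_N = 0, N_N = 0) {
  y <- c(B_C = B_C, B_N = B_N, L_C = L_C, N_C = N_C, L_N = L_N, N_N = N_N)
  .check_state(y)
  structure(y, class = "tan_state")
}

#' Time derivative of the Tan model
#'
#' Right-hand side of the two-compartment model. Degradation acts on free
#' cytosolic beta-catenin at rate `k_deg * gamma * (1 - W/2)`, so both Wnt
#' signalling and the APC knockdown gamma slow degradation. Passive
#' shuttling (`k_diff`) and active transport between compartments are scaled
#' by the compartment volumes `V_C`, `V_N`.
#'
#' @param state a [tan_state()].
#' @param params a [tan_parameters()] set.
#' @param env a [cell_environment()].
#' @export
tan_rhs <- function(state, params = tan_parameters(), env) {
  .check_state(state)
  dy <- tan_rhs_cpp(as.numeric(state), .param_vector(params), env$W, env$gamma)
  setNames(dy, .tan_state_names)
}

#' Closed-form steady state of the Tan model
#'
#' For `gamma > 0` the fixed point is
#' `B_C = B_synth / (k_deg * gamma * (1 - W/2))`, with the nuclear level and
#' the bound/free ligand split following from the transport and binding
#' balances. For `gamma = 0` degradation vanishes and free beta-catenin
#' grows without bound; the saturated-ligand limit is returned
#' (`N_C = L_C_total`, `N_N = L_N_total`, free beta-catenin infinite) with
#' attribute `unbounded = TRUE`.
#'
#' @inheritParams tan_rhs
#' @export
tan_steady_state <- function(params = tan_parameters(), env) {
  if (env$gamma == 0) {
    y <- tan_state(B_C = Inf, B_N = Inf, L_C = 0, N_C = params$L_C_total,
                   L_N = 0, N_N = params$L_N_total)
    attr(y, "unbounded") <- TRUE
    return(y)
  }
  B_C <- params$B_synth / (params$k_deg * env$gamma * (1 - env$W / 2))
  B_N <- (params$k_diff + params$k_active_C) /
    (params$k_diff + params$k_active_N) * B_C
  L_C <- params$L_C_total * params$k_R_C /
    (params$k_R_C + params$k_F_C * B_C)
  N_C <- params$L_C_total * params$k_F_C * B_C /
    (params$k_R_C + params$k_F_C * B_C)
  L_N <- params$L_N_total * params$k_R_N /
    (params$k_R_N + params$k_F_N * B_N)
  N_N <- params$L_N_total * params$k_F_N * B_N /
    (params$k_R_N + params$k_F_N * B_N)
  tan_state(B_C = B_C, B_N = B_N, L_C = L_C, N_C = N_C, L_N = L_N, N_N = N_N)
}
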