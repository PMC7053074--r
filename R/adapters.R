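# Uniform interface between the multiscale loop and a subcellular model.
# The two built-in models get compiled kernels; SBML-translated systems get
# the same contract through bind_ode_model() (see sbml_adapter.R).

#' Model adapter interface
#'
#' The simulation loop talks to subcellular models through a small adapter:
#' batch state advance, steady-state construction, and the two coupling
#' readouts (adhesion and transcription complex). `as_model_adapter()`
#' builds one from a model id ("vl"/"tan") or passes through an existing
#' adapter such as the result of [bind_ode_model()].
#'
#' @param model model id or `sbml_model_adapter`.
#' @param params optional parameter set for the built-in models.
#' @export
as_model_adapter <- function(model, params = NULL) {
  if (inherits(model, "model_adapter")) return(model)
  model <- model_id(model)
  if (is.null(params)) params <- default_parameters(model)
  if (model == "vl") .check_model_state(model, vl_state(), params)
  else .check_model_state(model, tan_state(), params)
  nm <- if (model == "vl") .vl_state_names else .tan_state_names
  ss_fun <- if (model == "vl") vl_steady_state else tan_steady_state
  adhesion_col <- if (model == "vl") "C_A" else "N_C"
  # native time unit of the kinetic constants relative to tissue hours.
  # The Tan rate table is in per-minute units (k_deg = 0.0163/min is the
  # ~42-minute beta-catenin half-life), so one tissue hour advances the
  # model by 60 native time units; steady states are unaffected.
  time_scale <- if (model == "vl") 1 else 60

  adapter <- list(
    model = model,
    params = params,
    state_names = nm,
    nstate = length(nm),
    steady_states = function(W, gamma) {
      out <- matrix(0, length(W), length(nm), dimnames = list(NULL, nm))
      for (i in seq_along(W)) {
        out[i, ] <- as.numeric(ss_fun(params, cell_environment(W[i],
                                                               gamma[i])))
      }
      out
    },
    time_scale = time_scale,
    advance = function(states, W, gamma, dt) {
      .advance_states(model, states, params, W, gamma, dt * time_scale)
    },
    adhesion_level = function(states) unname(states[, adhesion_col]),
    transcription_level = function(states) {
      if (model == "vl") unname(states[, "C_oT"] + states[, "C_cT"])
      else unname(states[, "N_N"])
    }
  )
  class(adapter) <- "model_adapter"
  adapter
}

# runtime coupling constants for an adapter; custom adapters must carry
# their own drag parameters and threshold
.adapter_drag_parameters <- function(adapter) {
  if (!is.null(adapter$drag_parameters)) return(adapter$drag_parameters)
  drag_parameters(adapter$model)
}

.adapter_threshold <- function(adapter, w_star = 0.75) {
  if (!is.null(adapter$threshold)) return(adapter$threshold)
  compute_proliferation_threshold(adapter$model, w_star,
                                  adapter$params)$threshold
}
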