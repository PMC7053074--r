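#' Drag-law parameters
#'
#' The per-cell drag coefficient is a clamped linear function of the
#' adhesion-complex level A: `eta = max((A - alpha) / beta, 1)`. The default
#' constants are calibrated so that at subcellular equilibrium a healthy
#' cell at full Wnt has drag 1 and a fully mutated cell has drag 20.
#'
#' @param model `"vl"` or `"tan"`.
#' @param alpha adhesion-complex offset.
#' @param beta adhesion-complex scale (> 0).
#' @return List of class `drag_parameters`.
#' @export
drag_parameters <- function(model, alpha = NULL, beta = NULL) {
  model <- model_id(model)
  defaults <- list(
    vl = list(alpha = 98.84798, beta = 3.98617),
    tan = list(alpha = 697.82302, beta = 14.45674)
  )[[model]]
  alpha <- if (is.null(alpha)) defaults$alpha else alpha
  beta <- if (is.null(beta)) defaults$beta else beta
  stopifnot(beta > 0)
  structure(list(model = model, alpha = alpha, beta = beta),
            class = "drag_parameters")
}

#' Adhesion-complex readout of a subcellular state
#'
#' The scalar that couples subcellular signalling to mechanics: the
#' membrane-bound beta-catenin/cadherin complex, `C_A` for the VL model and
#' `N_C` for the Tan model.
#'
#' @param model `"vl"` or `"tan"`.
#' @param state matching state vector.
#' @export
adhesion_complex_level <- function(model, state) {
  model <- model_id(model)
  if (model == "vl") {
    if (!inherits(state, "vl_state")) stop("expected a vl_state")
    unname(state[["C_A"]])
  } else {
    if (!inherits(state, "tan_state")) stop("expected a tan_state")
    unname(state[["N_C"]])
  }
}

#' Transcription-complex readout of a subcellular state
#'
#' The scalar compared against the proliferation threshold: the total
#' beta-catenin/TCF complex `C_T = C_oT + C_cT` (VL) or the nuclear bound
#' complex `N_N` (Tan).
#'
#' @inheritParams adhesion_complex_level
#' @export
transcription_complex_level <- function(model, state) {
  model <- model_id(model)
  if (model == "vl") {
    if (!inherits(state, "vl_state")) stop("expected a vl_state")
    vl_C_T(state)
  } else {
    if (!inherits(state, "tan_state")) stop("expected a tan_state")
    unname(state[["N_N"]])
  }
}

#' Drag coefficient from an adhesion-complex level
#'
#' `eta = max((level - alpha) / beta, 1)`. There is no upper clamp: the
#' calibration spans drags 1-20 across the healthy-to-fully-mutated
#' equilibrium range, but transient levels above the fully-mutated
#' equilibrium give proportionally larger drag.
#'
#' @param level adhesion-complex concentration (>= 0).
#' @param dp a [drag_parameters()] set.
#' @export
drag <- function(level, dp) {
  stopifnot(all(level >= 0))
  pmax((level - dp$alpha) / dp$beta, 1)
}

#' Calibrate the drag-law constants from subcellular equilibria
#'
#' Solves the two linear conditions `drag = 1` at `(W, gamma) = (1, 1)` and
#' `drag = 20` at `(W, gamma) = (1, 0)`, evaluated at the model's
#' steady-state adhesion-complex level: `alpha + beta = A(1, 1)` and
#' `alpha + 20 beta = A(1, 0)`. For the Tan model the `gamma = 0`
#' equilibrium is the saturated-ligand limit `N_C = L_C_total`.
#'
#' This reproduces the published VL constants to four significant figures.
#' The published Tan constants are close to, but not exactly, the analytic
#' limit fit (see the methods vignette); [drag_parameters()] holds the
#' published values used at run time.
#'
#' @param model `"vl"` or `"tan"`.
#' @param params optional parameter override.
#' @return A [drag_parameters()] object with the fitted constants.
#' @export
fit_drag_parameters <- function(model, params = NULL) {
  model <- model_id(model)
  if (is.null(params)) params <- default_parameters(model)
  ss <- function(W, gamma) {
    env <- cell_environment(W, gamma)
    if (model == "vl") vl_steady_state(params, env)
    else tan_steady_state(params, env)
  }
  A11 <- adhesion_complex_level(model, ss(1, 1))
  A10 <- adhesion_complex_level(model, ss(1, 0))
  if (!(A10 > A11))
    stop("degenerate drag fit: adhesion level at (1,0) must exceed (1,1)")
  beta <- (A10 - A11) / 19
  alpha <- A11 - beta
  drag_parameters(model, alpha = alpha, beta = beta)
}

#' Proliferation threshold on the transcription complex
#'
#' A cell proliferates while its transcription-complex level strictly
#' exceeds the threshold. The threshold is calibrated so that, at
#' subcellular equilibrium, healthy cells with Wnt above `w_star` (default
#' 0.75, i.e. the bottom quarter of the crypt) proliferate:
#' `compute_proliferation_threshold()` evaluates the steady-state
#' transcription complex at `(W = w_star, gamma = 1)`.
#' `proliferation_threshold()` returns the published calibrated constants
#' (11.667 for VL, 739.949 for Tan).
#'
#' @param model `"vl"` or `"tan"`.
#' @param w_star Wnt level at the proliferative boundary, in (0, 1).
#' @param params optional parameter override.
#' @export
compute_proliferation_threshold <- function(model, w_star = 0.75,
                                            params = NULL) {
  model <- model_id(model)
  stopifnot(w_star > 0, w_star < 1)
  if (is.null(params)) params <- default_parameters(model)
  env <- cell_environment(w_star, 1)
  ss <- if (model == "vl") vl_steady_state(params, env)
  else tan_steady_state(params, env)
  structure(list(model = model,
                 threshold = transcription_complex_level(model, ss)),
            class = "proliferation_threshold")
}

#' @rdname compute_proliferation_threshold
#' @export
proliferation_threshold <- function(model) {
  model <- model_id(model)
  structure(list(model = model,
                 threshold = c(vl = 11.667, tan = 739.949)[[model]]),
            class = "proliferation_threshold")
}

#' @rdname compute_proliferation_threshold
#' @param level transcription-complex level(s).
#' @param threshold a `proliferation_threshold` or a number.
#' @export
is_proliferative <- function(level, threshold) {
  if (inherits(threshold, "proliferation_threshold"))
    threshold <- threshold$threshold
  level > threshold
}
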