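#' Advance a subcellular state in time
#'
#' Integrates the chosen model over `dt` hours with an adaptive embedded
#' Runge-Kutta 4(5) (Cash-Karp) method, absolute tolerance 1e-8 and relative
#' tolerance 1e-6 by default. Components whose magnitude falls below 1e-12
#' are clipped to zero so states stay non-negative.
#'
#' @param model `"vl"` or `"tan"`.
#' @param state a `vl_state` or `tan_state` matching `model`.
#' @param params matching parameter set (defaults for the model).
#' @param env a [cell_environment()].
#' @param dt time step in hours (> 0).
#' @param atol,rtol integration tolerances.
#' @return The advanced state, same class as the input.
#' @export
advance_state <- function(model, state, params = NULL, env, dt,
                          atol = 1e-8, rtol = 1e-6) {
  model <- model_id(model)
  if (is.null(params)) params <- default_parameters(model)
  .check_model_state(model, state, params)
  stopifnot(dt > 0)
  .check_state(state)
  y <- ode_advance_cpp(.model_int(model), as.numeric(state),
                       .param_vector(params), env$W, env$gamma, dt,
                       atol, rtol)
  nm <- if (model == "vl") .vl_state_names else .tan_state_names
  structure(setNames(y, nm), class = paste0(model, "_state"))
}

.check_model_state <- function(model, state, params) {
  want <- if (model == "vl") "vl_state" else "tan_state"
  wantp <- if (model == "vl") "vl_parameters" else "tan_parameters"
  if (!inherits(state, want))
    stop("model '", model, "' requires a ", want, ", got ",
         paste(class(state), collapse = "/"))
  if (!inherits(params, wantp))
    stop("model '", model, "' requires ", wantp)
  invisible(TRUE)
}

# batch advance used by the multiscale loop: one row per cell
.advance_states <- function(model, Y, params, W, gamma, dt,
                            atol = 1e-8, rtol = 1e-6) {
  ode_advance_batch_cpp(.model_int(model), Y, .param_vector(params),
                        W, gamma, dt, atol, rtol)
}

#' Generic adaptive Runge-Kutta integrator
#'
#' Pure-R Cash-Karp RK4(5) driver for an arbitrary derivative function.
#' Used to execute translated SBML systems, and as an integration route
#' independent of the compiled kernels.
#'
#' @param f `function(y) -> dy/dt` over the state vector.
#' @param y0 initial state.
#' @param dt time to advance (hours).
#' @param atol,rtol tolerances.
#' @export
rk45_advance <- function(f, y0, dt, atol = 1e-8, rtol = 1e-6) {
  b <- list(c(1 / 5),
            c(3 / 40, 9 / 40),
            c(3 / 10, -9 / 10, 6 / 5),
            c(-11 / 54, 5 / 2, -70 / 27, 35 / 27),
            c(1631 / 55296, 175 / 512, 575 / 13824, 44275 / 110592,
              253 / 4096))
  c5 <- c(37 / 378, 0, 250 / 621, 125 / 594, 0, 512 / 1771)
  c4 <- c(2825 / 27648, 0, 18575 / 48384, 13525 / 55296, 277 / 14336, 1 / 4)

  y <- y0
  t <- 0
  h <- dt
  for (iter in seq_len(1e6)) {
    if (t >= dt) return(y)
    h <- min(h, dt - t)
    k <- vector("list", 6)
    k[[1]] <- f(y)
    for (s in 2:6) {
      ys <- y + h * Reduce(`+`, Map(`*`, b[[s - 1]], k[seq_len(s - 1)]))
      k[[s]] <- f(ys)
    }
    y5 <- y + h * Reduce(`+`, Map(`*`, c5, k))
    y4 <- y + h * Reduce(`+`, Map(`*`, c4, k))
    err <- max(abs(y5 - y4) / (atol + rtol * pmax(abs(y), abs(y5))))
    if (is.na(err)) stop("integration produced non-finite values")
    if (err <= 1) {
      t <- t + h
      y <- y5
      h <- h * min(5, if (err > 1e-10) 0.9 * err^-0.2 else 5)
    } else {
      h <- h * max(0.1, 0.9 * err^-0.25)
      if (h < 1e-14 * dt) stop("integration step size underflow")
    }
  }
  stop("integration failed to converge over dt = ", dt)
}
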