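#' Runtime ODE system representation
#'
#' The executable form a translated SBML document is reduced to: an ordered
#' set of state variables with initial values, named parameters with
#' defaults, and one right-hand-side expression per variable (an arithmetic
#' expression over variables, parameters and the supported functions).
#'
#' @param variables character vector of state-variable names (ordered).
#' @param initial named numeric initial values (one per variable).
#' @param parameters named numeric parameter defaults.
#' @param rhs named list of R expressions, one per variable.
#' @param name model name.
#' @export
ode_system <- function(variables, initial, parameters, rhs, name = "model") {
  stopifnot(length(variables) >= 1,
            setequal(names(rhs), variables),
            setequal(names(initial), variables))
  rhs <- rhs[variables]
  initial <- initial[variables]

  known <- c(variables, names(parameters))
  for (v in variables) {
    syms <- .expr_symbols(rhs[[v]])
    bad <- setdiff(syms, known)
    if (length(bad) > 0)
      stop("unresolved symbol(s) in d", v, "/dt: ",
           paste(bad, collapse = ", "))
    funs <- setdiff(.expr_functions(rhs[[v]]), .supported_funs)
    if (length(funs) > 0)
      stop("unsupported function(s) in d", v, "/dt: ",
           paste(funs, collapse = ", "))
  }
  sys <- structure(list(variables = variables, initial = initial,
                        parameters = parameters, rhs = rhs, name = name),
                   class = "ode_system")
  val <- ode_system_rhs_fn(sys)(initial, parameters)
  if (any(!is.finite(val)))
    stop("RHS evaluation at the initial state is not finite")
  sys
}

#' @export
print.ode_system <- function(x, ...) {
  cat(sprintf("<ode_system '%s': %d variables, %d parameters>\n",
              x$name, length(x$variables), length(x$parameters)))
  invisible(x)
}

#' Compile an ODE system to an evaluable derivative function
#'
#' Builds (and byte-compiles) `function(y, p)` returning the derivative
#' vector, with `y` ordered as `system$variables` and `p` a full named
#' parameter vector.
#'
#' @param system an [ode_system()].
#' @export
ode_system_rhs_fn <- function(system) {
  vars <- system$variables
  body_lines <- c(
    lapply(seq_along(vars), function(i) {
      call("<-", as.name(vars[i]), call("[[", as.name("y"), i))
    }),
    lapply(names(system$parameters), function(pn) {
      call("<-", as.name(pn), call("[[", as.name("p"), pn))
    }),
    list(as.call(c(as.name("c"), system$rhs)))
  )
  f <- function(y, p) NULL
  body(f) <- as.call(c(as.name("{"), body_lines))
  environment(f) <- baseenv()
  compiler::cmpfun(f)
}

#' Evaluate the RHS of an ODE system
#'
#' @param system an [ode_system()].
#' @param state named or ordered numeric state vector.
#' @param parameters overrides merged over the system defaults.
#' @export
ode_system_rhs <- function(system, state, parameters = NULL) {
  p <- system$parameters
  if (!is.null(parameters)) p[names(parameters)] <- parameters
  y <- if (!is.null(names(state))) as.numeric(state[system$variables])
  else as.numeric(state)
  setNames(ode_system_rhs_fn(system)(y, p), system$variables)
}
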