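#' Parameter sets for the subcellular models
#'
#' `vl_parameters()` returns the rate constants of the one-compartment
#' destruction-complex model of beta-catenin regulation (the "VL" model);
#' `tan_parameters()` those of the two-compartment binding/shuttling model
#' (the "Tan" model). Defaults are the published values; any subset can be
#' overridden by name. Concentrations are in the models' arbitrary units and
#' all rates are per hour.
#'
#' The two ligand totals `L_C_total` and `L_N_total` of the Tan model are
#' conserved quantities fixed by the initial condition rather than published
#' rate constants; the default of 1000 for each is back-solved from the
#' calibrated nuclear-complex proliferation threshold (see the methods
#' vignette).
#'
#' @param ... named parameter overrides.
#' @return A named list of class `vl_parameters` or `tan_parameters`.
#' @export
vl_parameters <- function(...) {
  p <- list(
    s_A = 20, s_CA = 250, s_C = 25, s_CT = 30, s_D = 100, s_T = 10,
    s_X = 10, s_Y = 10,
    d_A = 2, d_CA = 350, d_C = 1, d_CT = 750, d_D = 5, d_Dx = 5,
    d_T = 0.4, d_u = 50, d_X = 100, d_Y = 1,
    K_C = 200, K_D = 5, K_T = 50,
    p_c = 0, p_u = 100,
    xi_D = 5, xi_Dx = 5, xi_X = 200, xi_c = 0
  )
  p <- .override_params(p, list(...), "vl_parameters")
  if (any(unlist(p) < 0)) stop("VL parameters must be non-negative")
  structure(p, class = "vl_parameters")
}

#' @rdname vl_parameters
#' @export
tan_parameters <- function(...) {
  p <- list(
    B_synth = 1.306, k_deg = 0.0163,
    k_R_C = 0.000647, k_F_C = 0.00001,
    k_R_N = 0.00349, k_F_N = 0.0001,
    k_diff = 39.13, k_active_C = 4.5, k_active_N = 17.16,
    V_C = 1.16, V_N = 0.65,
    L_C_total = 1000, L_N_total = 1000
  )
  p <- .override_params(p, list(...), "tan_parameters")
  if (any(unlist(p) <= 0)) stop("Tan parameters must be positive")
  structure(p, class = "tan_parameters")
}

.override_params <- function(defaults, overrides, what) {
  if (length(overrides) == 0) return(defaults)
  nm <- names(overrides)
  if (is.null(nm) || any(nm == ""))
    stop("all ", what, " overrides must be named")
  unknown <- setdiff(nm, names(defaults))
  if (length(unknown) > 0)
    stop("unknown ", what, ": ", paste(unknown, collapse = ", "))
  defaults[nm] <- lapply(overrides, as.numeric)
  defaults
}

#' Default parameters for a model id
#' @param model `"vl"` or `"tan"`.
#' @param ... overrides passed to the constructor.
#' @export
default_parameters <- function(model, ...) {
  if (model_id(model) == "vl") vl_parameters(...) else tan_parameters(...)
}

#' Cell environment: Wnt level and mutation level
#'
#' The extracellular state a crypt cell experiences: the Wnt signal
#' `W` (dimensionless, 1 at the crypt base decreasing to 0 at the top) and
#' the APC mutation parameter `gamma` (1 = healthy, 0 = full knockout).
#'
#' @param W Wnt level in `[0, 1]`.
#' @param gamma mutation level in `[0, 1]`.
#' @export
cell_environment <- function(W, gamma = 1) {
  stopifnot(is.numeric(W), length(W) == 1, W >= 0, W <= 1,
            is.numeric(gamma), length(gamma) == 1, gamma >= 0, gamma <= 1)
  structure(list(W = W, gamma = gamma), class = "cell_environment")
}

# fixed orderings used by the compiled kernels
.vl_param_order <- c(
  "s_A", "s_CA", "s_C", "s_CT", "s_D", "s_T", "s_X", "s_Y",
  "d_A", "d_CA", "d_C", "d_CT", "d_D", "d_Dx", "d_T", "d_u", "d_X", "d_Y",
  "K_C", "K_D", "K_T", "p_c", "p_u", "xi_D", "xi_Dx", "xi_X", "xi_c"
)
.tan_param_order <- c(
  "B_synth", "k_deg", "k_R_C", "k_F_C", "k_R_N", "k_F_N",
  "k_diff", "k_active_C", "k_active_N", "V_C", "V_N"
)

.param_vector <- function(params) {
  if (inherits(params, "vl_parameters"))
    unlist(params[.vl_param_order])
  else
    unlist(params[.tan_param_order])
}

#' Read a parameter set from a plain-text config file
#'
#' The file holds one `key = value` pair per line (`#` starts a comment),
#' with keys named exactly as in the parameter constructors.
#'
#' @param path file path.
#' @param model `"vl"` or `"tan"`.
#' @export
read_parameter_config <- function(path, model) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- vapply(kv, function(p) length(p) != 2, logical(1))
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  keys <- trimws(vapply(kv, `[[`, "", 1))
  vals <- suppressWarnings(as.numeric(trimws(vapply(kv, `[[`, "", 2))))
  if (anyNA(vals)) stop("non-numeric value for key: ", keys[is.na(vals)][1])
  do.call(default_parameters, c(list(model = model), as.list(setNames(vals, keys))))
}

#' @rdname read_parameter_config
#' @param params a parameter set to write.
#' @export
write_parameter_config <- function(params, path) {
  writeLines(sprintf("%s = %.17g", names(params), unlist(params)), path)
  invisible(path)
}
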