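#' Translate an SBML document into an executable ODE system
#'
#' Supports the SBML subset needed for subcellular reaction-network models:
#' compartments, species, global parameters, reactions with kinetic laws
#' (including local parameters), rate rules, assignment rules and function
#' definitions, for Level 2 and Level 3 documents. Species governed by
#' reactions get `d[S]/dt = sum(stoichiometry x kinetic law) / compartment
#' size`; rate-rule targets take the rule expression; assignment rules are
#' substituted into every use; boundary-condition and constant species
#' become parameters. Events, algebraic rules and delays are outside the
#' subset and fail with an explicit unsupported-construct error.
#'
#' @param document path to an SBML file, or a string of SBML XML.
#' @return An [ode_system()].
#' @export
parse_sbml <- function(document) {
  doc <- xml2::read_xml(document)
  xml2::xml_ns_strip(doc)

  for (bad in c("event", "algebraicRule", "delay", "constraint")) {
    hit <- xml2::xml_find_first(doc, paste0(".//", bad))
    if (!inherits(hit, "xml_missing"))
      stop("unsupported SBML construct: <", bad, ">",
           .sbml_id_hint(hit))
  }

  model <- xml2::xml_find_first(doc, ".//model")
  if (inherits(model, "xml_missing")) stop("no <model> element found")
  name <- xml2::xml_attr(model, "id")
  if (is.na(name)) name <- "model"

  # function definitions (MathML lambda), inlined at use sites
  fundefs <- list()
  for (fd in xml2::xml_find_all(model, ".//functionDefinition")) {
    id <- xml2::xml_attr(fd, "id")
    lam <- xml2::xml_find_first(fd, ".//lambda")
    kids <- xml2::xml_children(lam)
    bvars <- kids[xml2::xml_name(kids) == "bvar"]
    args <- vapply(bvars, function(b)
      trimws(xml2::xml_text(xml2::xml_child(b))), "")
    body_node <- kids[[length(kids)]]
    fundefs[[id]] <- list(args = args,
                          body = .mathml_to_expr(body_node, fundefs))
  }

  compartments <- list()
  for (cp in xml2::xml_find_all(model, ".//compartment")) {
    id <- xml2::xml_attr(cp, "id")
    size <- suppressWarnings(as.numeric(xml2::xml_attr(cp, "size")))
    compartments[[id]] <- if (is.na(size)) 1 else size
  }

  params <- numeric(0)
  for (pr in xml2::xml_find_all(model, "./listOfParameters/parameter")) {
    id <- xml2::xml_attr(pr, "id")
    val <- suppressWarnings(as.numeric(xml2::xml_attr(pr, "value")))
    params[id] <- if (is.na(val)) 0 else val
  }

  species <- list()
  for (sp in xml2::xml_find_all(model, ".//species")) {
    id <- xml2::xml_attr(sp, "id")
    conc <- suppressWarnings(
      as.numeric(xml2::xml_attr(sp, "initialConcentration")))
    amt <- suppressWarnings(
      as.numeric(xml2::xml_attr(sp, "initialAmount")))
    comp <- xml2::xml_attr(sp, "compartment")
    size <- if (!is.na(comp) && !is.null(compartments[[comp]]))
      compartments[[comp]] else 1
    value <- if (!is.na(conc)) conc else if (!is.na(amt)) amt / size else 0
    species[[id]] <- list(
      value = value, size = size,
      boundary = identical(xml2::xml_attr(sp, "boundaryCondition"), "true"),
      constant = identical(xml2::xml_attr(sp, "constant"), "true"))
  }

  assignments <- list()
  rate_rules <- list()
  for (rl in xml2::xml_find_all(model, ".//assignmentRule")) {
    v <- xml2::xml_attr(rl, "variable")
    assignments[[v]] <- .mathml_to_expr(
      xml2::xml_find_first(rl, ".//math"), fundefs)
  }
  for (rl in xml2::xml_find_all(model, ".//rateRule")) {
    v <- xml2::xml_attr(rl, "variable")
    rate_rules[[v]] <- .mathml_to_expr(
      xml2::xml_find_first(rl, ".//math"), fundefs)
  }

  # reaction contributions
  contrib <- list()
  for (rx in xml2::xml_find_all(model, ".//reaction")) {
    rid <- xml2::xml_attr(rx, "id")
    kl <- xml2::xml_find_first(rx, ".//kineticLaw")
    if (inherits(kl, "xml_missing"))
      stop("reaction ", rid, " has no kinetic law")
    kin <- .mathml_to_expr(xml2::xml_find_first(kl, ".//math"), fundefs)
    # local parameters are renamed <reaction>_<id> to avoid collisions
    locals <- xml2::xml_find_all(kl, ".//parameter|.//localParameter")
    subs <- list()
    for (lp in locals) {
      lid <- xml2::xml_attr(lp, "id")
      gid <- paste0(rid, "_", lid)
      params[gid] <- suppressWarnings(as.numeric(xml2::xml_attr(lp, "value")))
      subs[[lid]] <- as.name(gid)
    }
    if (length(subs) > 0) kin <- .substitute_all(kin, subs)
    add <- function(node, sign) {
      sid <- xml2::xml_attr(node, "species")
      st <- suppressWarnings(as.numeric(xml2::xml_attr(node, "stoichiometry")))
      if (is.na(st)) st <- 1
      term <- if (st == 1) kin else call("*", st, kin)
      if (sign < 0) term <- call("-", term)
      contrib[[sid]] <<- c(contrib[[sid]], list(term))
    }
    for (nd in xml2::xml_find_all(rx, "./listOfReactants/speciesReference"))
      add(nd, -1)
    for (nd in xml2::xml_find_all(rx, "./listOfProducts/speciesReference"))
      add(nd, 1)
  }

  # classify: state variables vs parameters
  variables <- character(0)
  initial <- numeric(0)
  rhs <- list()
  for (id in names(species)) {
    sp <- species[[id]]
    if (id %in% names(assignments)) next
    governed <- id %in% names(rate_rules) || !is.null(contrib[[id]])
    if (sp$boundary || sp$constant || !governed) {
      params[id] <- sp$value
      next
    }
    variables <- c(variables, id)
    initial[id] <- sp$value
    rhs[[id]] <- if (id %in% names(rate_rules)) {
      rate_rules[[id]]
    } else {
      total <- .nary("+", contrib[[id]])
      if (sp$size != 1) call("/", total, sp$size) else total
    }
  }
  # rate rules on parameters promote them to state variables
  for (id in setdiff(names(rate_rules), names(species))) {
    variables <- c(variables, id)
    initial[id] <- if (id %in% names(params)) params[[id]] else 0
    params <- params[setdiff(names(params), id)]
    rhs[[id]] <- rate_rules[[id]]
  }

  # substitute assignment rules (iterate for chained definitions)
  if (length(assignments) > 0) {
    for (pass in seq_len(length(assignments) + 1)) {
      subs <- lapply(assignments, identity)
      rhs <- lapply(rhs, .substitute_all, env_list = subs)
      assignments <- lapply(assignments, .substitute_all, env_list = subs)
      used <- unique(unlist(lapply(rhs, .expr_symbols)))
      if (!any(names(assignments) %in% used)) break
    }
  }

  ode_system(variables = variables, initial = initial,
             parameters = params, rhs = rhs, name = name)
}

.sbml_id_hint <- function(node) {
  id <- xml2::xml_attr(node, "id")
  if (!is.na(id)) paste0(" (id '", id, "')") else ""
}

#' Export a built-in subcellular model to SBML
#'
#' Writes an SBML Level 3 document holding the chosen model as one
#' rate-ruled parameter per state variable, all rate constants as global
#' parameters, and the Wnt input `W` and mutation parameter `gamma` as
#' modifiable (non-constant) parameters. Initial values are the healthy
#' full-Wnt steady state. The Tan document carries the conserved ligand
#' totals both as parameters and in the initial condition.
#'
#' @param model `"vl"` or `"tan"`.
#' @param params optional parameter override.
#' @param file optional path; when given the document is written there.
#' @param W,gamma environment encoded in the exported initial state.
#' @return The SBML document as a character string (invisibly when `file`
#'   is given).
#' @export
export_sbml <- function(model, params = NULL, file = NULL, W = 1,
                        gamma = 1) {
  model <- model_id(model)
  if (is.null(params)) params <- default_parameters(model)
  rhs <- .native_rhs_expressions(model)
  env <- cell_environment(W, gamma)
  ss <- if (model == "vl") vl_steady_state(params, env)
  else tan_steady_state(params, env)
  const <- unlist(params)
  vars <- names(rhs)

  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    paste0("<sbml xmlns=\"http://www.sbml.org/sbml/level3/version1/core\" ",
           "level=\"3\" version=\"1\">"),
    sprintf("  <model id=\"%s_wnt_model\" timeUnits=\"hour\">", model),
    "    <listOfCompartments>",
    paste0("      <compartment id=\"cell\" size=\"1\" spatialDimensions=",
           "\"3\" constant=\"true\"/>"),
    "    </listOfCompartments>",
    "    <listOfParameters>"
  )
  for (v in vars) {
    lines <- c(lines, sprintf(
      "      <parameter id=\"%s\" value=\"%.17g\" constant=\"false\"/>",
      v, unname(ss[[v]])))
  }
  for (pn in names(const)) {
    lines <- c(lines, sprintf(
      "      <parameter id=\"%s\" value=\"%.17g\" constant=\"true\"/>",
      pn, const[[pn]]))
  }
  lines <- c(lines,
             sprintf("      <parameter id=\"W\" value=\"%.17g\" constant=\"false\"/>", W),
             sprintf("      <parameter id=\"gamma\" value=\"%.17g\" constant=\"false\"/>", gamma),
             "    </listOfParameters>",
             "    <listOfRules>")
  for (v in vars) {
    lines <- c(lines,
               sprintf("      <rateRule variable=\"%s\">", v),
               paste0("        <math xmlns=\"http://www.w3.org/1998/",
                      "Math/MathML\">"),
               paste0("          ", .expr_to_mathml(rhs[[v]])),
               "        </math>",
               "      </rateRule>")
  }
  lines <- c(lines, "    </listOfRules>", "  </model>", "</sbml>")
  doc <- paste(lines, collapse = "\n")
  if (!is.null(file)) {
    writeLines(doc, file)
    return(invisible(doc))
  }
  doc
}

# symbolic right-hand sides of the built-in models; the SBML round-trip
# test checks these against the compiled kernels, so the two encodings are
# mutually verifying
.native_rhs_expressions <- function(model) {
  if (model == "vl") {
    list(
      D = quote(gamma * s_D * X - ((d_D + xi_D * W) + (d_Dx + xi_Dx * W)) * D),
      X = quote(s_X - gamma * s_D * X - (d_X + xi_X * W) * X +
                  (d_Dx + xi_Dx * W) * D),
      C_u = quote(p_u * D * (C_o + C_c) / ((C_o + C_c) + K_D) - d_u * C_u),
      C_o = quote(s_C + d_CA * C_A + d_CT * C_oT -
                    (s_CA * A + s_CT * T + d_C) * C_o -
                    (p_c + xi_c * W) * C_o / (C_o + K_C) -
                    p_u * D * C_o / ((C_o + C_c) + K_D)),
      C_c = quote((p_c + xi_c * W) * C_o / (C_o + K_C) + d_CT * C_cT -
                    (s_CT * T + d_C) * C_c -
                    p_u * D * C_c / ((C_o + C_c) + K_D)),
      A = quote(s_A + d_CA * C_A - (s_CA * C_o + d_A) * A),
      C_A = quote(s_CA * C_o * A - d_CA * C_A),
      T = quote(s_T + d_CT * (C_oT + C_cT) -
                  (s_CT * (C_o + C_c) + d_T) * T),
      C_oT = quote(s_CT * C_o * T - d_CT * C_oT),
      C_cT = quote(s_CT * C_c * T - d_CT * C_cT),
      Y = quote(s_Y * (C_oT + C_cT) / ((C_oT + C_cT) + K_T) - d_Y * Y)
    )
  } else {
    list(
      B_C = quote(B_synth - k_deg * gamma * (1 - W / 2) * B_C +
                    k_R_C * N_C - k_F_C * B_C * L_C -
                    (k_diff * (B_C - B_N)) / V_C -
                    (k_active_C * B_C - k_active_N * B_N) / V_C),
      B_N = quote(k_R_N * N_N - k_F_N * B_N * L_N +
                    (k_diff * (B_C - B_N)) / V_N +
                    (k_active_C * B_C - k_active_N * B_N) / V_N),
      L_C = quote(k_R_C * N_C - k_F_C * B_C * L_C),
      N_C = quote(-k_R_C * N_C + k_F_C * B_C * L_C),
      L_N = quote(k_R_N * N_N - k_F_N * B_N * L_N),
      N_N = quote(-k_R_N * N_N + k_F_N * B_N * L_N)
    )
  }
}
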