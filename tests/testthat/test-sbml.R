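minimal_sbml <- function(kinetic = "<cn> 2 </cn>", extra = "") {
  paste0('<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">
  <model id="mini">
    <listOfCompartments>
      <compartment id="cell" size="1" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="S" compartment="cell" initialConcentration="0"
               boundaryCondition="false" constant="false"/>
    </listOfSpecies>
    ', extra, '
    <listOfReactions>
      <reaction id="make_S" reversible="false">
        <listOfProducts>
          <speciesReference species="S" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <kineticLaw>
          <math xmlns="http://www.w3.org/1998/Math/MathML">', kinetic, '</math>
        </kineticLaw>
      </reaction>
    </listOfReactions>
  </model>
</sbml>')
}

test_that("a minimal reaction model translates to dS/dt = 2", {
  sys <- parse_sbml(minimal_sbml())
  expect_s3_class(sys, "ode_system")
  expect_equal(sys$variables, "S")
  expect_equal(unname(ode_system_rhs(sys, c(S = 5))), 2)
})

test_that("kinetic laws use global parameters and compartment sizes", {
  doc <- minimal_sbml(
    kinetic = "<apply><times/><ci> k </ci><ci> S </ci></apply>",
    extra = '<listOfParameters>
               <parameter id="k" value="0.5" constant="true"/>
             </listOfParameters>')
  sys <- parse_sbml(doc)
  expect_equal(unname(ode_system_rhs(sys, c(S = 4))), 2)
})

test_that("events and algebraic rules fail with a named error", {
  doc <- minimal_sbml(extra = '<listOfEvents><event id="ev1"/></listOfEvents>')
  expect_error(parse_sbml(doc), "unsupported SBML construct: <event>")
  doc2 <- minimal_sbml(extra = "<listOfRules><algebraicRule/></listOfRules>")
  expect_error(parse_sbml(doc2), "algebraicRule")
})

test_that("exported documents are well-formed with the declared layout", {
  doc <- export_sbml("vl")
  x <- xml2::read_xml(doc)
  xml2::xml_ns_strip(x)
  rules <- xml2::xml_find_all(x, ".//rateRule")
  expect_length(rules, 11)
  pars <- xml2::xml_find_all(x, ".//parameter")
  const <- xml2::xml_attr(pars, "constant")
  ids <- xml2::xml_attr(pars, "id")
  # 27 rate constants + W + gamma as globals, 11 rate-ruled state parameters
  expect_equal(sum(const == "true"), 27)
  expect_equal(sum(const == "false"), 13)
  expect_true(all(c("W", "gamma") %in% ids[const == "false"]))

  tdoc <- export_sbml("tan")
  tx <- xml2::read_xml(tdoc)
  xml2::xml_ns_strip(tx)
  expect_length(xml2::xml_find_all(tx, ".//rateRule"), 6)
  tids <- xml2::xml_attr(xml2::xml_find_all(tx, ".//parameter"), "id")
  expect_true(all(c("L_C_total", "L_N_total") %in% tids))
})

test_that("export/parse round-trip preserves RHS evaluation to 1e-10", {
  set.seed(99)
  for (model in c("vl", "tan")) {
    sys <- parse_sbml(export_sbml(model))
    f <- ode_system_rhs_fn(sys)
    p <- sys$parameters
    nm <- sys$variables
    native <- if (model == "vl") vl_rhs_cpp else tan_rhs_cpp
    pv <- multicrypt:::.param_vector(default_parameters(model))
    for (k in 1:100) {
      y <- runif(length(nm), 0, 500)
      W <- runif(1)
      g <- runif(1)
      p[["W"]] <- W
      p[["gamma"]] <- g
      a <- f(y, p)
      b <- native(y, pv, W, g)
      expect_lt(max(abs(a - b) / pmax(abs(b), 1)), 1e-10)
    }
  }
})

test_that("roundtripped steady states are fixed points", {
  sys <- parse_sbml(export_sbml("vl", W = 0.75, gamma = 1))
  ss <- vl_steady_state(vl_parameters(), cell_environment(0.75, 1))
  expect_equal(unname(sys$initial), as.numeric(ss), tolerance = 1e-12)
  expect_lt(max(abs(ode_system_rhs(sys, sys$initial))), 1e-8)
})

test_that("binding requires a complete interface mapping", {
  sys <- parse_sbml(export_sbml("vl"))
  expect_error(bind_ode_model(sys, transcription = "C_oT"),
               "adhesion variable")
  expect_error(bind_ode_model(sys, adhesion = "C_A"), "transcription")
  expect_error(
    bind_ode_model(sys, transcription = "nope", adhesion = "C_A"),
    "not in the system")

  ad <- bind_ode_model(sys, transcription = "C_oT", adhesion = "C_A",
                       drag_params = drag_parameters("vl"),
                       threshold = 11.667)
  expect_s3_class(ad, "model_adapter")
  expect_equal(ad$mapping$wnt, "W")
  expect_equal(ad$mapping$gamma, "gamma")
})

test_that("W passed through the adapter matches the native rhs", {
  sys <- parse_sbml(export_sbml("tan"))
  ad <- bind_ode_model(sys, transcription = "N_N", adhesion = "N_C",
                       drag_params = drag_parameters("tan"),
                       threshold = 739.949, time_scale = 60)
  y0 <- matrix(as.numeric(tan_state(B_C = 50, B_N = 40, L_C = 400,
                                    N_C = 600, L_N = 300, N_N = 700)),
               nrow = 1, dimnames = list(NULL, sys$variables))
  out <- ad$advance(y0, W = 0.6, gamma = 0.8, dt = 0.5 / 60)
  native <- advance_state("tan", tan_state(B_C = 50, B_N = 40, L_C = 400,
                                           N_C = 600, L_N = 300, N_N = 700),
                          tan_parameters(), cell_environment(0.6, 0.8),
                          dt = 0.5)
  expect_equal(unname(out[1, ]), as.numeric(native), tolerance = 1e-6)
  expect_equal(ad$adhesion_level(out), out[1, "N_C"],
               ignore_attr = TRUE)
})

test_that("function definitions and assignment rules are inlined", {
  doc <- minimal_sbml(
    kinetic = "<apply><ci> rate2 </ci><ci> vmax </ci><ci> Sx </ci></apply>",
    extra = '<listOfFunctionDefinitions>
      <functionDefinition id="rate2">
        <math xmlns="http://www.w3.org/1998/Math/MathML">
          <lambda>
            <bvar><ci> v </ci></bvar>
            <bvar><ci> s </ci></bvar>
            <apply><divide/><ci> v </ci>
              <apply><plus/><ci> s </ci><cn> 1 </cn></apply>
            </apply>
          </lambda>
        </math>
      </functionDefinition>
    </listOfFunctionDefinitions>
    <listOfParameters>
      <parameter id="vmax" value="6" constant="true"/>
      <parameter id="Sx" constant="false"/>
    </listOfParameters>
    <listOfRules>
      <assignmentRule variable="Sx">
        <math xmlns="http://www.w3.org/1998/Math/MathML">
          <apply><times/><cn> 0.5 </cn><ci> S </ci></apply>
        </math>
      </assignmentRule>
    </listOfRules>')
  sys <- parse_sbml(doc)
  # dS/dt = vmax / (0.5 S + 1) = 6 / 2 at S = 2
  expect_equal(unname(ode_system_rhs(sys, c(S = 2))), 3)
})

test_that("a bound SBML adapter drives the crypt like the native model", {
  sys <- parse_sbml(export_sbml("vl"))
  thr <- compute_proliferation_threshold("vl")$threshold
  ad <- bind_ode_model(sys, transcription = "C_oT", adhesion = "C_A",
                       drag_params = drag_parameters("vl"), threshold = thr)
  # the exported C_oT equals the full complex only because C_c = 0 at
  # p_c = 0; use the full complex readout to match the native coupling
  ad$transcription_level <- function(states)
    unname(states[, "C_oT"] + states[, "C_cT"])

  # both runs start from the same initialised population, so any
  # divergence comes from the translated RHS / generic integrator
  mech <- mechanics_config(width = 4, height = 8)
  cfg <- simulation_config(model = "vl", mechanics = mech,
                           equilibration_time = 0, observation_time = 2,
                           seed = 31, threshold = thr,
                           drag_params = drag_parameters("vl"))
  run_from <- function(adapter) {
    set.seed(31)
    pop <- initialize_crypt(mech, "vl")
    pop$adapter <- adapter
    coupling <- multicrypt:::.coupling_constants(pop, cfg)
    for (k in seq_len(round(2 / pop$dt)))
      pop <- crypt_step(pop, cfg, coupling)
    pop
  }
  native <- run_from(as_model_adapter("vl"))
  sbml <- run_from(ad)
  expect_equal(sbml$n, native$n)
  expect_equal(sbml$x, native$x, tolerance = 1e-6)
  expect_equal(sbml$y, native$y, tolerance = 1e-6)
  expect_equal(sbml$proliferative, native$proliferative)
})
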