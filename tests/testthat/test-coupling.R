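test_that("complex readouts project the right components", {
  vs <- vl_state(C_A = 5, C_oT = 3, C_cT = 4)
  expect_equal(adhesion_complex_level("vl", vs), 5)
  expect_equal(transcription_complex_level("vl", vs), 7)
  ts <- tan_state(N_C = 11, N_N = 13)
  expect_equal(adhesion_complex_level("tan", ts), 11)
  expect_equal(transcription_complex_level("tan", ts), 13)
  expect_error(adhesion_complex_level("vl", ts), "vl_state")
  expect_error(transcription_complex_level("tan", vs), "tan_state")
})

test_that("drag law: linear above the offset, floored at 1, no upper clamp", {
  dp <- drag_parameters("vl")
  expect_equal(drag(dp$alpha + dp$beta, dp), 1)
  expect_equal(drag(0, dp), 1)
  expect_equal(drag(dp$alpha + 40 * dp$beta, dp), 40)
  expect_error(drag(-1, dp))
  expect_equal(drag_parameters("tan")$alpha, 697.82302)
  expect_equal(drag_parameters("tan")$beta, 14.45674)
})

test_that("drag at the fully-mutated full-Wnt equilibrium is 20 (3 s.f.)", {
  ss <- vl_steady_state(vl_parameters(), cell_environment(1, 0))
  eta <- drag(adhesion_complex_level("vl", ss), drag_parameters("vl"))
  expect_equal(eta, 20, tolerance = 5e-4)
})

test_that("VL drag calibration reproduces the published constants to 4 s.f.", {
  fit <- fit_drag_parameters("vl")
  expect_equal(fit$alpha, 98.84798, tolerance = 5e-5)
  expect_equal(fit$beta, 3.98617, tolerance = 5e-5)
})

test_that("Tan drag calibration uses the saturated-ligand limit", {
  # analytic gamma -> 0 limit: N_C(1, 0) = L_C_total = 1000, giving
  # beta = (1000 - 712.3746) / 19 and alpha = N_C(1,1) - beta; close to,
  # but not exactly, the published Tan row (which stays canonical at runtime)
  fit <- fit_drag_parameters("tan")
  expect_equal(fit$beta, 15.1382, tolerance = 1e-4)
  expect_equal(fit$alpha, 697.2365, tolerance = 1e-4)
})

test_that("a degenerate drag fit errors", {
  # with p_u = 0 the destruction complex never touches beta-catenin, so the
  # (1,1) and (1,0) equilibria coincide and the 2x2 system is singular
  expect_error(fit_drag_parameters("vl", vl_parameters(p_u = 0)),
               "degenerate")
})

test_that("healthy cells have drag 1 at every Wnt level", {
  dp_vl <- drag_parameters("vl")
  dp_tan <- drag_parameters("tan")
  # the published constants are rounded, so at W = 1 the healthy drag sits a
  # hair above the floor (1.0000013 VL, 1.0066 Tan); below W = 1 the floor
  # binds exactly
  for (W in seq(0, 1, by = 0.1)) {
    svl <- vl_steady_state(vl_parameters(), cell_environment(W, 1))
    stan <- tan_steady_state(tan_parameters(), cell_environment(W, 1))
    expect_equal(drag(adhesion_complex_level("vl", svl), dp_vl), 1,
                 tolerance = 1e-5)
    expect_equal(drag(adhesion_complex_level("tan", stan), dp_tan), 1,
                 tolerance = 0.01)
  }
})

test_that("steady-state drag is non-increasing in gamma at full Wnt", {
  dp <- drag_parameters("vl")
  etas <- vapply(seq(0, 1, by = 0.1), function(g) {
    ss <- vl_steady_state(vl_parameters(), cell_environment(1, g))
    drag(adhesion_complex_level("vl", ss), dp)
  }, 0)
  expect_true(all(diff(etas) <= 1e-9))
  expect_equal(etas[1], 20, tolerance = 5e-4)
  expect_equal(etas[11], 1, tolerance = 1e-5)
})

test_that("proliferation thresholds match the published calibration", {
  expect_equal(compute_proliferation_threshold("vl")$threshold, 11.667,
               tolerance = 1e-4)
  # with the back-solved default L_N_total = 1000 the computed Tan
  # threshold is 740.06, within 0.02% of the published 739.949
  th_tan <- compute_proliferation_threshold("tan")$threshold
  expect_equal(th_tan, 740.0646, tolerance = 1e-6)
  expect_lt(abs(th_tan / 739.949 - 1), 2e-4)
  expect_equal(proliferation_threshold("vl")$threshold, 11.667)
  expect_equal(proliferation_threshold("tan")$threshold, 739.949)
})

test_that("threshold test is a strict inequality and marginal Wnt decides", {
  th <- proliferation_threshold("vl")
  expect_true(is_proliferative(12.0, th))
  expect_false(is_proliferative(11.667, th))
  expect_false(is_proliferative(739.0, proliferation_threshold("tan")))

  p <- vl_parameters()
  thr <- compute_proliferation_threshold("vl", 0.75, p)$threshold
  up <- vl_C_T(vl_steady_state(p, cell_environment(0.76, 1)))
  dn <- vl_C_T(vl_steady_state(p, cell_environment(0.74, 1)))
  expect_true(is_proliferative(up, thr))
  expect_false(is_proliferative(dn, thr))
})
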