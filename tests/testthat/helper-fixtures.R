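# shared fixtures for the test suite

# a small crypt for fast tissue-level tests: 5 CD circumference, 10 CD high
small_mechanics <- function(...) {
  mechanics_config(width = 5, height = 10, ...)
}

small_config <- function(model = "vl", ...) {
  simulation_config(model = model, mechanics = small_mechanics(), ...)
}

# grid of environments used by fixed-point / monotonicity property tests
wg_grid <- expand.grid(W = c(0, 0.25, 0.5, 0.75, 1),
                       gamma = c(0.1, 0.25, 0.5, 0.75, 1))

# relative difference helper
rel_err <- function(a, b) max(abs(a - b) / pmax(abs(b), 1e-8))
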