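---
title: "Methods: multiscale Wnt-driven crypt dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiscale Wnt-driven crypt dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`multicrypt` simulates a colorectal crypt as an unrolled cylinder, 10 cell
diameters (CD, 1 CD = 10 um) in circumference and 20 CD high, with a solid
base at `y = 0` and sloughing removal of any cell reaching `y = 20`. A
static Wnt field decreases linearly from 1 at the base to 0 at the top.
Each cell carries its own subcellular model of beta-catenin regulation,
driven by the Wnt level at the cell's current position and by an APC
mutation parameter `gamma` (1 = healthy, 0 = full knockout). Two readouts
of the subcellular state couple chemistry to tissue behaviour:

* the **transcription complex** (beta-catenin/TCF: `C_T = C_oT + C_cT` in
  the one-compartment "VL" model, nuclear `N_N` in the two-compartment
  "Tan" model) licenses proliferation when it strictly exceeds a
  calibrated threshold;
* the **adhesion complex** (beta-catenin/cadherin: `C_A` or cytosolic
  `N_C`) sets the drag coefficient
  `eta = max((A - alpha)/beta, 1)`.

Cell centres move overdamped, `eta_i dr_i/dt = sum_j F_ij`, with linear
springs `F_ij = mu r_hat_ij (|r_ij| - s_ij)` along the edges of the
periodic Delaunay triangulation (edges above 1.5 CD are discarded). Cell
shapes and areas are the corresponding Voronoi regions clipped to the
crypt rectangle.

## Subcellular models

The VL model tracks eleven species: destruction complexes `D`, axin `X`,
six beta-catenin pools (ubiquitinated, open, closed, adhesion-bound,
open/closed TCF-bound), adhesion molecules `A`, transcription molecules
`T` and a Wnt target `Y`. Wnt raises the turnover of destruction
complexes and axin (`d_D + xi_D W`, `d_Dx + xi_Dx W`, `d_X + xi_X W`);
`gamma` multiplies the destruction-complex formation rate `s_D`. The
phosphorylation rate of open to closed beta-catenin is Wnt-independent
here (`p_c + xi_c W` with `xi_c = 0`); the Wnt-dependent variant is kept
as a parameter but not used. Two print errors in the published equations
are corrected (both are forced by the conservation structure and verified
by the fixed-point tests): the destruction-complex removal term of the
open-pool equation must act on `C_o` (not `C_c`), and the cytosolic
binding term of the two-compartment model must read `k_R^C N_C`.

The Tan model tracks free and bound beta-catenin in two compartments plus
free ligands, with conserved totals `L_C + N_C` and `L_N + N_N`.
Degradation of free cytosolic beta-catenin at rate
`k_deg * gamma * (1 - W/2)` carries both the Wnt input and the mutation.

Both models have closed-form steady states, used for crypt
initialisation, threshold calibration, drag calibration, and as oracles
for the integrator.

## Time units

The VL rate table is in per-hour units. The Tan rate table is in
**per-minute** units: `k_deg = 0.0163` is exactly `ln(2)/42.5`, the
canonical ~42-minute beta-catenin half-life, and the shuttling rate
`k_diff = 39.13` describes sub-minute compartment exchange. The model
adapter therefore advances the Tan system by 60 native time units per
tissue hour. This choice does not move any steady state, threshold or
drag constant; it only sets how fast cells track their local equilibrium.
With per-hour Tan kinetics the tissue-scale phenomenology collapses
entirely (the slowest mode, degradation buffered by the large bound-ligand
pools, is ~440 native units, so cells would inherit their birth state for
life, every cell would stay proliferative, and mutations would have no
visible effect for hundreds of hours) — which contradicts the calibrated
quarter-height proliferative compartment this model family is built
around. Low-level functions (`tan_rhs`, `advance_state`) remain in native
units.

Even in hours units, the VL transcription and adhesion complexes respond
to a mutation over several hours, not minutes: total beta-catenin is
buffered by the bound pools (roughly 9x the free pool), stretching the
effective relaxation time to ~5-10 h. Tissue-level consequences of a
mutation therefore develop over tens of hours, which matches the 50-hour
observation windows used in the experiments.

## Multiscale step

Per timestep, in order: (1) advance every cell's subcellular state by
`dt` at its local Wnt level and own `gamma`; (2) re-evaluate the
proliferation threshold — a cell at or below threshold becomes
differentiated *permanently* (strict inequality: boundary cells
differentiate), an above-threshold cell that was never differentiated is
proliferative; (3) set drag from the adhesion complex (or 1 in the
uniform-drag control mode); (4) age cell cycles and divide due cells —
cycle duration is `M (1 h) + G1 ~ N(2,1) truncated positive + S (5 h) +
G2 (4 h)`, daughters are placed 0.1 CD apart in a uniformly random
direction, inherit `gamma` and a copy of the parent's concentrations (no
halving: concentrations are intensive), and their mutual rest length
grows linearly from 0.1 to 1 CD over the 1-hour M phase; (5) rebuild the
triangulation, accumulate spring forces, and take a forward-Euler
position step with x wrapped and y clamped at the base; (6) slough cells
at `y >= 20`.

Differentiated cells keep ageing (age also clocks sibling-pair rest-length
maturation) but never divide; a proliferative cell that drops below
threshold mid-cycle abandons the cycle immediately.

# Calibration

The proliferation threshold is the steady-state transcription complex of
a healthy cell at `W = 0.75`, so that at equilibrium healthy cells
proliferate only in roughly the bottom quarter of the crypt:
`C_T = 11.667` (VL) and `N_N = 740.06` (Tan, with the ligand totals
below). The published Tan threshold is 739.949; the 0.015% gap traces to
the unpublished `L_N_total` (999.85 back-solves exactly, 1000 is the
package default — a round number a modeller would choose, kept as the
documented approximation). By default the simulation recomputes the
threshold from the active parameter set, so the proliferative boundary
sits exactly at `W = 0.75` even under parameter overrides; the published
constants are available via `proliferation_threshold()`.

The drag constants solve `alpha + beta = A(1,1)` and
`alpha + 20 beta = A(1,0)` at subcellular equilibrium. For VL this
reproduces the published `alpha = 98.84798`, `beta = 3.98617` to four
significant figures. For Tan, the analytic `gamma -> 0` limit saturates
the ligand (`N_C -> L_C_total`), and with `L_C_total = 1000` the fit
gives `alpha = 697.24`, `beta = 15.14` — near, but not equal to, the
published `697.82/14.46`, which likely came from a finite-time numerical
surrogate of the knockout equilibrium. The published values are used at
run time; `fit_drag_parameters()` is the calibration utility.

# Mechanics parameters

The paper states neither the spring constant nor the timestep; its cited
framework conventions for this model family are `mu = 15`, `dt = 1/120` h.
Those values turn out not to support a homeostatic crypt here: the spring
compression needed to drive the sloughing flux densifies the (spatially
fixed) Wnt-defined proliferative zone, which raises the division rate
faster than the flux capacity grows — cell counts increase without bound,
for both models, even with an idealised positional proliferation rule. A
one-dimensional force balance shows the feedback gain exceeds one for
`mu ~ 15-30` and predicts a stable fixed point near 1.3x resting density
for `mu = 50`. The package therefore defaults to `mu = 50` with
`dt = 1/240` h (inside the forward-Euler stability bound
`mu * dt * degree < 2`). The simulated healthy crypt then reaches a
dynamic equilibrium of ~305 cells with mean cell area ~0.66 CD^2 and a
stable proliferative population, matching the qualitative equilibrium the
original reports and the printed area scale. The proliferative compartment
extends to `y ~ 6-7` rather than exactly 5 because cells that cross the
Wnt boundary carry their transcription complex with the hours-scale
memory discussed above; "approximately a quarter of the crypt height"
should be read with that smear in mind.

# Synthetic initial condition

`initialize_crypt()` is the fixture generator: 10 x 20 cells on an offset
lattice at unit spacing, all healthy, subcellular states at the exact
local-Wnt steady state, and cycle ages uniformly random within freshly
drawn durations. This starts the tissue at mechanical near-equilibrium
with immediately desynchronised divisions, so the crypt converges to its
dynamic equilibrium within ~50-60 h (verified by cell-count
stationarity), rather than the 500 h quoted for an arbitrary seed state.
Tests and the scaled acceptance checks exploit this with shorter
equilibration; `simulation_config()` keeps 500 h as the default for
faithful replication. What a green tissue-level test establishes is
therefore: the coupled system reaches and holds the calibrated
equilibrium, and responds to mutations in the direction and rough
magnitude reported — not trajectory-level agreement with the original
C++ implementation, which is out of scope.

The generator does not emulate: crypt curvature (the domain is a
cylinder), cell death other than sloughing, mechanotransductive feedback
onto the chemistry, or separate attraction/repulsion responses to
mutation.

# Numerical choices

* Subcellular ODEs: adaptive Cash-Karp RK4(5), `atol = 1e-8`,
  `rtol = 1e-6`, one independent solve per cell per mechanics step;
  components below 1e-12 in magnitude are clipped to zero. A pure-R
  implementation of the same scheme drives SBML-translated systems and
  doubles as an independent cross-check of the compiled kernel.
* The tessellation computes each cell's Voronoi region by clipping a
  bounding box with perpendicular-bisector half-planes of grid-binned
  neighbour candidates (periodic images included), which yields Delaunay
  adjacency and clipped areas in one sweep. Collinear degenerate input
  yields a valid slab tessellation rather than an error. Region bounding
  boxes are capped at half the circumference so a cell never interacts
  with its own periodic image.
* Random draws (initial ages, cycle durations, division directions,
  mutant selection) come from one seeded R stream consumed in a fixed
  documented order; runs are exactly reproducible given
  `simulation_config(seed = )`.
* Takeover verdicts: "mutant" when no healthy cell remains *or* the cell
  count exceeds twice the equilibrium count (the paper's "large increase
  in the number of cells", unquantified there; configurable via
  `takeover_multiplier`), "healthy" when no mutant remains, otherwise
  censored at the observation horizon.

# Known limitations

* The published Tan drag row and threshold cannot be reproduced exactly
  without the supplementary SBML ligand totals; the package's derived
  defaults land within 0.02% (threshold) and ~0.6% (alpha).
* At the default mechanics the proliferative-zone boundary smears 1-2 CD
  above the nominal quarter height (subcellular memory, see above).
* SBML support covers the declared subset (compartments, species, global
  parameters, reactions with kinetic laws, rate and assignment rules,
  function definitions); events, algebraic rules, delays and hierarchical
  composition are rejected with explicit errors.
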