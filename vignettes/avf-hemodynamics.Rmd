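---
title: "Modeling blood redistribution and low wall shear stress in an idealized radiocephalic fistula"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling blood redistribution and low wall shear stress in an idealized radiocephalic fistula}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(avfwss)
```

## The problem

A radiocephalic arteriovenous fistula (AVF) shunts the radial artery into
the cephalic vein so that a hemodialysis machine can draw several hundred
milliliters of blood per minute. The surgical short circuit redistributes
the arterial inflow between the hand (through the distal radial artery,
DRA) and the low-resistance vein (CV), and the resulting flow disturbances
— impinging jets, peri-anastomotic vortices, and wall shear stress (WSS)
that is low (≤ 1 Pa) or direction-reversing — are the accepted hemodynamic
triggers of neointimal hyperplasia and access failure. Clinically, flow in
the DRA is often observed to *reverse*, feeding the anastomosis from the
hand side.

`avfwss` rebuilds this system as a tested computational pipeline: a
parametric idealized end-to-side AVF lumen, a laminar incompressible
Navier–Stokes solver, WSS post-processing with thresholded-area metrics,
and a parameter sweep over the proximal/distal flow split that quantifies
how redistribution — including retrograde DRA flow — moves the low-WSS
area relative to the clinically measured state.

## Clinical inputs and the stated world

All clinical inputs are measured constants (see `clinical_reference()`):
cycle-averaged velocities of 57.7 cm/s (PRA, 3.0 mm bore) and 34.3 cm/s
(DRA, 1.2 mm), a 5.0 mm cephalic vein, a 45° anastomosis angle, a heart
rate of ~70 bpm, and a venous pressure of 8 mmHg (1064 Pa at the rounded
clinical factor of 133 Pa/mmHg). Blood density (1050 kg/m³) and dynamic
viscosity (4.0 mPa·s) are not part of the record; they are the conventional Newtonian
values consistent with the quoted Reynolds number of ≈ 445 (the defaults
give Re ≈ 454, within 5%). Every WSS threshold in pascals inherits this
choice; both properties are exposed in `fluid_properties()`.

## Geometry

`build_avf()` constructs the lumen implicitly (a signed-distance-like
scalar field whose zero level set is the wall):

* the PRA and DRA are collinear cylinders whose *outer* (floor) edges are
  aligned, so the 1.2 mm DRA axis is offset inside the 3.0 mm PRA bore; a
  smoothstep taper joins them just downstream of the anastomotic opening;
* the vein leaves the artery top at the anastomosis angle and **doubles
  back**: the distal CV runs parallel to the artery, carrying flow back up
  the forearm, as the anatomy of a radiocephalic fistula dictates. Flow
  therefore turns ≈ 135° through a 45° anastomosis, which is what produces
  the strong impingement and the twin vortices flanking the high-velocity
  stream;
* the junction is blended by a smooth-minimum fillet with radius
  `spline_smoothness * d_cv` (default 0.25). The clinical geometry is
  described only as a smooth basis-spline merge without control points, so
  the fillet implements
  the *testable* part of that statement — tangency to both vessel walls
  and no sharp interior corner. The anastomotic opening area, which is
  not part of the clinical record and materially affects absolute WSS values, follows from
  angle, bores and blend radius; it is a known sensitivity, not a fitted
  quantity;
* "infinite" port conditions are replaced by finite development
  extensions, 10 local diameters per port by default (≥ 5 enforced);
* an anastomosis frame is attached: origin at the centre of the opening,
  y-axis along the proximal vein, x-axis toward the outer anastomosis
  edge, right-handed z normal to the symmetry plane.

`build_straight_tube()` provides the benchmark cylinder with
`INLET`/`OUTLET`/`WALL` tags.

## Meshing

`mesh_domain()` voxelizes a solid on a uniform Cartesian grid: cells whose
centre lies inside the lumen are fluid elements; the boundary faces carry
exactly one tag each and close watertightly. Port planes are snapped onto
grid face planes (extensions are rounded *up* by at most one pitch), so
every inlet/outlet patch is planar with an axis-aligned normal. Sub-voxel
wall geometry is kept through the sampled implicit field: wall-crossing
fractions (theta) feed one-sided viscous stencils, implicit-field normals
orient the facets, and a stair-step facet of projected area h² is counted
as a true wall patch of area h²/|n|₁ (exact in the refinement limit; a
meshed cylinder's lateral area is reproduced to ≈ 1% at 10 cells per
diameter).

Levels: `coarse`, `medium`, `fine` place 8, 10, 12 cells across the
reference diameter; `full` (13.4) lands at the grid-independent
scale of ≈ 0.12 million elements for the default AVF. A uniform voxel grid
cannot express boundary-layer grading; near-wall accuracy comes instead
from the theta-corrected stencils and the two-point wall-gradient WSS
reconstruction, validated against the Poiseuille closed form.

## Inlet waveforms

Only the means, the period and the extremal instants of the velocity
waveforms are recorded (maximum at ≈ 1.82 s, mean at ≈ 2.02 s, minimum at
≈ 2.58 s inside the third cycle, with peak/mean ≈ 1.4 and trough/mean
≈ 0.6 adopted as the pulse envelope). A two-harmonic Fourier series cannot
honour those anchors: the recorded upstroke spans only ~11% of the cycle,
and forcing stationary points 0.11 cycle apart at values 1.4 and 0.6
drives any K ≤ 5 least-norm series to spurious global extrema (ranges like
[-9, 11] at K = 2). `synthesize_waveform()` therefore uses a C¹-periodic
piecewise raised-cosine pulse: a fast systolic upstroke from the minimum
to the maximum and a slow diastolic decay back. Each raised-cosine arc
averages to the envelope midpoint analytically, so the time average equals
the prescribed mean *exactly*, and both extremal instants are hit exactly.
A user-specified finite-harmonic mode (`shape = "harmonics"`) is retained
and validates that anterograde signals stay non-negative. The DRA reuses
the PRA pulse shape scaled to its own mean — no independent shape data
exist. The synthesis is deterministic; nothing in the pipeline consumes
random numbers.

What the generator does *not* emulate: the dicrotic notch and beat-to-beat
variability of real Doppler traces, or any independent DRA waveform shape.
A green waveform test therefore establishes calibration against the
measured anchors, not fidelity to the unavailable raw traces; quantities tied
to instantaneous waveform values are reproduced at the level of the
anchored envelope only.

## Flow solver

`solve_steady()`/`solve_transient()` integrate the incompressible
Navier–Stokes equations on the staggered (MAC) voxel grid:

* conservative QUICK advection with first-order upwind fallback where the
  quadratic stencil would reach into the solid; two-stage (Heun) explicit
  integration; explicit diffusion with theta-corrected one-sided wall
  stencils, so the no-slip plane sits on the true wall, not the stair-step
  face;
* Chorin-type pressure projection: the Poisson operator over fluid cells
  is assembled once, Cholesky-factorized (`Matrix`), and reused at every
  sub-step — and across all cases of a sweep; the projection makes each
  cell's divergence vanish to direct-solver precision, so global mass
  balance is exact to rounding;
* boundary conditions through port ghost cells: prescribed axial velocity
  (flat/uniform by default, the clinical protocol's uniform-velocity inlet;
  parabolic as a benchmark option, since at Re ≈ 445 the laminar entrance
  length ≈ 0.06·Re·D ≈ 80 mm exceeds any finite extension), a uniform
  pressure at the CV outlet (gauge and absolute values give bitwise the
  same velocities under the rigid-wall model — tested), and no-slip walls;
* the sub-step is CFL-limited (0.40) and adapts to the velocity extrema;
  the clinical 0.01 s reporting step is treated as the boundary-condition/output
  cadence, not a stability limit;
* steady mode marches pseudo-time from a plug-flow warm start (each branch
  pre-filled with its expected bulk velocity) until the relative L2 change
  per checkpoint falls below `steady_tol` (1.5e-3), then averages over a
  0.04 s window — a no-op for converged fields, a deterministic mean when
  a weak residual oscillation remains.

Solver oracles (run in the test suite): Poiseuille centreline velocity,
pressure drop and wall shear against the closed forms; the analytic
Womersley solution (complex Bessel series, Womersley number ≈ 2.1 at the
clinical period) for pulsatile flow; cycle-to-cycle periodicity;
mirror-symmetry inheritance; mass balance for anterograde and retrograde
splits.

## WSS metrics and diagnostics

`compute_wss()` reconstructs the wall traction per facet from the
tangential velocity at the two cell centres behind the facet, with wall
distances read from the implicit field. The two-point fit
`tau = mu (u₁ d₂² − u₂ d₁²) / (d₁ d₂ (d₂ − d₁))` is exact for quadratic
profiles (machine-exact on a synthetic Poiseuille field); where a cell
centre sits on the wall itself the fit shifts to the second and third
cells. The estimator is anchored to the no-slip wall (u = 0 at the
surface), so it is not applicable to slip fixtures; a fluid at rest gives
exactly zero WSS, and the reconstructed vectors are wall-tangential by
construction.

Thresholded areas follow the analysis conventions: facet-averaged |WSS|
decides membership, ties count as low; low ≤ 1 Pa, high ≥ 10 Pa, maximum
≥ 20 Pa; the metric domain is the *whole* wall (anastomosis, artery and
vein segments — the DRA lumen matters for the starved retrograde cases).
`normalized_low_wss()` divides by the clinical reference case computed
under the identical mesh/mode/instant — never across protocols.

The S1 observation plane (normal along the proximal-vein axis) carries
five evenly spaced velocity probes along the inner-to-outer chord and six
evenly spaced wall WSS probes around the ring. The requested offset from
the anastomosis centre is half a vein diameter; if the section ring at
that offset is still open into the anastomotic mouth (a wall ray escapes
into the artery), the plane slides outward in quarter-diameter steps to
the first closed ring, so every wall probe genuinely sits on the vein
wall of the section. Because the jet leaving the 135° turn splits into
two symmetric near-wall lobes, outer-versus-inner wall comparisons are
made between the outer-half and inner-half ring probes. `detect_reversal()` classifies probe series:
*reciprocating* if the signed along-axis component changes sign within
the cycle, *oscillating* if the peak-to-trough excursion exceeds 50% of
the mean magnitude without a sign change, *none* otherwise. The
oscillatory shear index is reported as a supplementary diagnostic only.

## The redistribution sweep

`case_matrix()` enumerates the 26 scaled conditions plus the reference:
three anterograde families (PRA scaled; DRA scaled; both scaled, ε from
0.7 to 1.3) and the retrograde family (DRA reversed and scaled, ε from 0.1
to 0.5). Scaling acts on waveform means, so volumetric rates scale
linearly and exactly. `run_sweep()` executes the cases on a shared mesh
and solver state, normalizes low-WSS areas against the reference, and
`compare_sensitivity()` summarizes the per-family slopes (the proximal
family dominates the distal one).

The default sweep protocol is the *steady-snapshot surrogate*: a steady
solve at the instant's boundary values (mean-flow values for the headline
metric; the anchored peak/trough values for the extremal instants). The
clinical analysis finds consistent tendencies across cycle intervals, which
is what licenses a single-instant surrogate. The transient protocol
(three cycles at the recorded 0.01 s cadence, snapshot in the third cycle)
is implemented and used for the pulsatile validation; it is an order of
magnitude more expensive per case.

Mesh level of record: the acceptance-grade results are computed at the
`medium` level (10 cells per PRA diameter, ~4–5 minutes per case on one
CPU — the per-case cost envelope the surrogate protocol is designed for).
The `coarse` level halves the resolution of the DRA (3 cells across) and
noticeably coarsens the classification of the near-threshold CV wall, so
it is reserved for the CI-scale trend checks, which also shorten the
development extensions to the minimum 5 diameters.

## Numerical choices and degenerate inputs

* theta clamped to [0.1, 1]; the viscous stability bound accounts for the
  worst-case clamp;
* facets whose adjacent cell centre lies within 0.3 h of the wall use the
  second/third-cell fit (noise control);
* thresholds are inclusive on the low side (deterministic tie-break);
* zero inlet velocity with zero gauge pressure yields the identically
  zero field; a velocity condition on every port is rejected (the
  pressure level would be undefined);
* port extensions are rounded up to the grid pitch, never down;
* all solids are validated against their invariants (positive bores,
  DRA < PRA ≤ CV, 0 < angle ≤ 90°, extensions ≥ 5 D). Equality of the
  PRA and CV bores is allowed (the 90° symmetry case requires it).

## Known limitations

* Rigid walls: no compliance, no circumferential stress, no
  fluid–structure interaction — WSS at diastole/systole extremes is
  correspondingly approximate.
* Stair-step voxel walls: wall position is first-order accurate despite
  the sub-voxel corrections; absolute facet-level WSS carries a few
  percent of geometric noise, which is why near-threshold area metrics
  are quoted at the medium level and as ratios to the reference case.
* Blood is Newtonian; non-Newtonian corrections matter most exactly in
  the low-shear regions the low-WSS metric flags.
* The anastomotic opening area and the true waveform shapes are not
  recorded; both are documented sensitivities of the absolute areas (the
  normalized ratios are much more robust).
* Velocity-probe interpolation treats solid cells as zero velocity, which
  biases samples within one cell of the wall toward zero.
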