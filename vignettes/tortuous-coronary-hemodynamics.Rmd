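---
title: "Pressure loss in idealized tortuous coronary arteries: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pressure loss in idealized tortuous coronary arteries: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

Coronary tortuosity — a winding, serpentine course of an epicardial artery,
most often seen in the left anterior descending artery (LAD) — is a common
angiographic finding whose hemodynamic consequence is debated. The severity
of tortuosity can be summarized by two morphological parameters: the
**tortuosity angle** θ (the interior angle at each bend; smaller = sharper)
and the **tortuosity count** n (how many serpentine units the vessel
carries). `tortuflow` asks the question computationally: how much pressure is
lost between the inlet and the outlet of an idealized 2-D tortuous vessel,
as a function of (θ, n), under steady and pulsatile coronary flow?

The pipeline is: parametric geometry → structured quadrilateral mesh →
finite-volume incompressible Navier–Stokes solve → pressure-drop
post-processing over the 4 × 6 design grid θ ∈ {30°, 60°, 90°, 120°},
n ∈ {0, …, 5}.

## Geometry model

The vessel is a planar channel of axial length L = 130 mm and lumen diameter
d = 3 mm. A tortuous *unit* is a tangent-continuous serpentine of four
circular arcs with bend radii R = 6.318 mm (outer bends) and r = 6 mm (inner
bends), turn directions left–right–right–left, each arc subtending
(180° − θ) so that the interior vertex angle at every bend apex equals θ.
The unit has zero net turning, is point-symmetric about its midpoint, and
degenerates to a straight segment as θ → 180°. A vessel consists of a
straight entry, n repeated units, and a straight exit; the train is centered
so the entry and exit lengths are equal (the placement is not otherwise
constrained, and centering maximizes symmetric flow development on both
sides).

One design choice needs justification. With the fixed radii, the four arcs
of a θ = 30° unit span only 2(R + r)·sin 150° ≈ 12.3 mm axially while each
arc swings the tangent through 150°; the resulting lobes overhang and the
centerline of a pure arc train *crosses itself* — no 3 mm lumen can be
offset from it. The reference unit width w = 20 mm resolves this: the package
treats w as a floor on the unit's axial extent, inserting straight spacers
at the tangent-axial junctions (half a spacer at each end of the unit, one
at its midpoint) whenever the arc train alone is narrower than w. Only
θ = 30° is affected; its wall-to-wall clearance between adjacent lobes
becomes 0.53 mm and the outline is simple (verified by brute-force
segment-intersection tests over the whole design). For θ ≥ 60° the arc
extent already exceeds w and units are pure arc serpentines. The spacers add
identical amounts to the axial extent and to the arc length, so the extra
centerline length contributed per unit is unchanged by this repair.

The lumen is the normal offset of the centerline by ±d/2. Offsetting is
valid because the smallest bend radius minus d/2 (6 − 1.5 = 4.5 mm) is
positive. Centerline length decreases with θ at fixed n ≥ 1 and increases
with n at fixed θ, which is the geometric backbone of the pressure-drop
trends.

## Meshing

The mesh is a structured body-fitted sweep: stations at (near-)uniform
arc-length spacing along the centerline, `round(d/interval)` cells across
the lumen, quadrilateral cells between consecutive stations. At the default
1 mm interval that is 3 cells across — deliberately coarse: this is the
reference resolution of the study design, comparable to what unstructured
all-quadrilateral "pave" meshers produce at the same interval (the swept
mesh of the reference model has 549 cells). A structured sweep is used
instead of paving because paving algorithms are proprietary and not
reproducible. Cells on bends are annular-sector shaped and
stay nearly orthogonal (> 80° orthogonality over the design), so no
non-orthogonal corrector is applied. Cell counts, areas, orthogonality and
patch tiling are validated by the mesh report and the test suite (area
conservation against the outline polygon, closed-boundary normal sums,
4× count growth under 2× refinement).

## Flow solver

Incompressible laminar Navier–Stokes, discretized by a collocated
finite-volume method and iterated with SIMPLE pressure–velocity coupling:

* **Convection**: first-order upwind — the reference scheme of the study
  design; robust, at the cost of numerical diffusion.
* **Diffusion**: central, orthogonal approximation.
* **Pressure interpolation**: standard (linear) face interpolation, with
  momentum-weighted Rhie–Chow face fluxes to suppress checkerboarding on
  the collocated grid.
* **Boundary conditions**: uniform (plug) or parabolic inlet velocity;
  fixed uniform outlet gauge pressure; no-slip rigid walls. The plug inlet
  is the production default (a single inlet speed, 0.156 m/s, is the stated
  condition; the long entry straight lets the profile develop). The
  parabolic option exists for verification, where entrance effects must be
  excluded.
* **Under-relaxation**: 0.7 (momentum) / 0.3 (pressure) for steady solves —
  standard SIMPLE practice. Inside time steps the transient term stabilizes
  the iteration and lighter factors may be supplied.
* **Convergence**: each equation's L1 residual is normalized by its
  first-iteration value (the two momentum components share one reference so
  a vanishing cross-stream residual in an axis-aligned channel is not
  amplified); iteration stops when all scaled residuals fall below 10⁻³.
  Residuals already at machine level (e.g. zero inflow) count as converged.
  Divergence (scaled residual growth past 10⁸) raises an error carrying the
  residual history.
* **Time integration**: first-order implicit with Δt = 0.01 s, which
  resolves the cardiac anchor times (0.26, 0.36, 0.8 s) exactly; three
  cycles are marched and the second is analyzed, with cycle-2 vs cycle-3
  agreement serving as the periodicity check. The initial condition is the
  steady solution at the t = 0 boundary values, making runs deterministic.
* **Initial conditions (steady)**: zero velocity, outlet-gauge pressure.
  The converged state is checked to be independent of the pressure gauge
  (adding a constant to the outlet pressure shifts the whole field).

The inlet Reynolds number ρUd/μ is 140 at the steady inflow — far below the
2300 laminar limit, which the solver guards with a warning. Blood is treated
as Newtonian (μ = 0.0035 Pa·s, ρ = 1050 kg/m³); the Newtonian assumption is
conventionally justified for vessels over 6 mm while this lumen is 3 mm —
the model is retained as stated rather than corrected, and this is a known
limitation.

## Verification oracles

Two independent references validate the solver on the straight channel:

* `poiseuille_drop()` — the plane-Poiseuille closed form 12μUL/h². On a
  fine mesh (0.1 mm, 30 cells across) with a parabolic inlet the solved
  drop must approach this (the acceptance suite requires 2%).
* `coarse_channel_drop()` — the *discrete* fully developed momentum balance
  at the production resolution: n cells across, central diffusion,
  half-cell wall fluxes, solved for the pressure gradient consistent with
  the prescribed mean velocity. At 3 cells across the discrete gradient is
  exactly 9/11 of the continuum one; the solver's developed gradient must
  match it (5%). The oracle increases monotonically to the closed form as
  the cell count grows, which the tests assert. Both oracles are derived
  and frozen independently of the solver path.

## Pulsatile boundary waveform

The cardiac cycle is represented by periodic cubic splines (period 1 s — a
resting heart beat; the largest known time is 0.8 s) through anchor points
for inlet velocity and outlet pressure. Three anchors are known exactly:
peak diastole (t₁ = 0.26 s: 0.51 m/s, 17850 Pa), maximum pressure
(t₂ = 0.36 s: 0.42 m/s, 20206 Pa) and late systole (t₃ = 0.8 s: 0.318 m/s,
10869 Pa). They are contractual: the waveform interpolates them exactly,
repeats periodically, and must stay non-negative in velocity.

A periodic cubic through *only* those three points, however, is forced to
climb from t₃ straight back up to the next cycle's diastolic peak — flow
accelerating through late systole, the wrong phase behaviour for a
diastolic-dominant coronary waveform. The default anchor set therefore
appends one shaping anchor at t = 0.95 s (0.28 m/s, 10200 Pa): the
end-systolic minimum of the cycle. Its placement encodes only the phase
fact that the cycle minimum falls between late systole and the next
diastolic acceleration; its magnitude is a modest dip below the known
late-systolic value. The true inter-anchor shape of the underlying
physiological waveform is not determined by three values, so pulsatile
pressure-drop magnitudes
carry waveform-shape uncertainty and are treated as rank/trend quantities
(phase ordering of the snapshot drops, growth with tortuosity count, order
of magnitude at the reference point), not exact targets. The steady limit —
a constant waveform reproducing the steady solution — closes the loop.

## Analysis definitions

* **Pressure drop**: length-weighted mean cell pressure over the
  inlet-adjacent cells minus the same over the outlet-adjacent cells.
  Inlet-to-outlet is the measurement section pair (a straight vessel also
  shows a nonzero drop, which only makes sense vessel-wide); section
  averaging is used rather than centerline sampling.
* **Developed gradient**: least-squares slope of section-averaged pressure
  over the central 25–85% of the arc length.
* **Design sweep**: one converged run per design point; the straight vessel
  is identical for every angle so it is solved once and replicated, making
  the n = 0 rows bitwise equal by construction. A non-converged point is
  recorded with its failure reason and the sweep continues. The steady
  sweep attaches an ordinary least-squares fit of drop against centerline
  length pooled across the grid.

## What the synthetic conditions do and do not show

Everything here is an idealized 2-D planar model: rigid smooth walls, plug
inflow, Newtonian blood, a perfectly periodic cycle, and a geometry reduced
to arcs and straights. Passing tests demonstrate internal consistency —
discretization correctness against closed-form and discrete oracles,
conservation, symmetry, determinism and the direction of the
tortuosity-severity trends. They do not demonstrate patient-level accuracy:
real coronary arteries are 3-D, compliant, move with the myocardium, taper,
and branch; none of that is modelled. The absolute tortuous-vessel drops
are also sensitive to the exact unit construction: the dimensional
parameters (L, d, R, r, w, θ) do not uniquely determine a tangent-continuous
arc arrangement, and different arrangements with the same radii differ in
their bend losses, most strongly at θ = 30°. The package's arrangement
reproduces the qualitative serpentine shape and all ordering trends; its
sharply-angled units carry comparatively strong bend losses. The
straight-vessel drop is free of that geometric ambiguity.

## Problem sizes

The production mesh interval is 1 mm (390 cells for the straight vessel up
to ~1200 for the longest serpentine), the reference resolution of the
study design. Verification uses a 0.1 mm straight-channel mesh (39 000
cells). Pulsatile runs march 3 cycles at Δt = 0.01 s (300 steps) per design
point. The full steady 24-point sweep, the pulsatile 20-point sweep and the
fine verification run together form the acceptance suite.
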