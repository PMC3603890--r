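---
title: "A reduced-order model of neutrophil transit through a constricted microchannel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A reduced-order model of neutrophil transit through a constricted microchannel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(celltransit)
```

## The physical problem

A neutrophil (resting radius 4 µm) is carried by plasma through a
microchannel that narrows smoothly to a throat smaller than the cell.
Two channel families are modelled:

* an **axisymmetric capillary** — a straight pipe of radius 6 µm with an
  arc-shaped constriction (curvature radius 27.525 µm) narrowing to a
  2.85 µm throat radius;
* a **rectangular channel** — 22.36 µm wide and `H` µm high, whose two side
  walls each carry an arc of curvature radius `R_con`, leaving a throat of
  width `W_con` (control: `H` = 8.2, `R_con` = 27.525, `W_con` = 4.368 µm).
  When `H` < 8.2 µm, the height ramps from 8.2 µm down to `H` upstream of
  the constriction.

A constant pressure difference (default 40 Pa) drives the flow.  The cell
must deform to pass; the quantity of interest is the **transit time** `T`,
defined as the time between the two peaks of the cell's axial-velocity
trace — the first just before the cell meets the constriction side walls,
the second at its expulsion through the throat.

The cell interior is a **Maxwell liquid** (viscosity 31 Pa·s, shear
modulus 186 Pa, relaxation time 31/186 ≈ 0.167 s) wrapped in a surface
under constant **cortical tension** (31 pN/µm).  The tension sets the
law-of-Laplace critical pressure for entering a narrow opening,
`2 T_c (1/r − 1/R)`; at the control throat's effective radius of 2.75 µm
this is 7.045 Pa (`critical_pressure(cell_model(), 2.75)`), well below the
40 Pa drive, so the cell always passes eventually; the question is how
slowly.

All walls carry an **imaginary wall** offset 0.1 µm into the lumen: the
surface on which the cell slides without friction, while plasma may still
penetrate the offset gap.

## The reduced-order model

Instead of a finite-element fluid–structure computation, the package
advances a two-degree-of-freedom quasi-static model.  The cell is a
capsule: a prismatic body whose cross-section is a rounded rectangle with
half-extents `w` (lateral) and `h` (vertical) and corner radius
`min(w, h)`, closed by half-spheroidal caps; the body length follows from
exact conservation of the resting sphere's volume (`cell_shape()`).  The
two half-extents are the degrees of freedom; each is backed by a scalar
Maxwell element.

Each step of `simulate_transit()`:

1. **Geometry.** The capsule must clear the imaginary-wall lumen along its
   whole length (`.req_extent` samples the caps and sweeps the body over
   the step so a fast cell cannot tunnel past the throat).  Contact flags
   follow, plus an occlusion flag: the cell is a plug when a contacting
   dimension is inside the constriction or the wall requirement shrinks
   just ahead.
2. **Hydraulics.** When occluded, the channel is a series–parallel
   network: open duct upstream and downstream (integrated laminar
   resistance, Hagen–Poiseuille or a Fanning-friction rectangular-duct
   correlation checked against the exact series solution), bypassed at the
   cell by the **corner gutters** — the clearances between the cell's
   rounded flanks and the rectangular corners — each a straight duct of
   conductance `k A³/(µ P² L)` with `k = 0.5` (exact for a circular
   section).  `pressure_partition()` yields the pressure drop `dP_cell`
   actually loading the cell.  A free (non-occluded) cell rides the plasma
   near the centreline velocity.
3. **Driving stress.** The pressure force in excess of the local critical
   pressure, reduced by the **seal fraction** `φ = A_cell/A_lumen` (only
   the blocked share of the lumen loads the cell), spread over a contact
   band of fixed tangency-band width (1.5 µm), gives the wall reaction
   stress.  Laterally it is weighted by the angular efficiency
   `(1 − cos θ)` of the contact angle `θ`; vertically it acts only where
   the ceiling profile actually descends (a flat frictionless ceiling
   cannot retard the advance).
4. **Advance.** The step velocity is the largest value, up to the
   hydraulic velocity, for which the end-of-step Maxwell stress implied by
   the squeezing the walls demand stays below the applied stress at the
   destination configuration (32-step bisection).  Walls are rigid: the
   committed shape is clamped to the lumen by a fixed-point projection
   that re-balances the body length as the cross-section shrinks.
5. **Recovery.** Out of contact, cortical tension alone drives the
   half-extents back toward the resting radius through the same Maxwell
   elements.  (During contact the tension's resistance to entry is already
   inside the critical pressure; adding it again would double-count.)

Lateral squeezing splits between vertical bulge and axial elongation with
partition exponent `chi = 0.5`, chosen a priori from the isotropy of the
incompressible interior.  It predicts a maximum deformed cell height of
`2 × 4 × (4/2.084)^0.5` ≈ 11.1 µm in the control channel, close to the
reference finite-element value of 10.86 µm — recorded, not fitted.

## A worked transit

```{r control, fig.width = 6, fig.height = 4}
rec <- simulate_transit(rect_channel())
summary(rec)
plot(rec)
```

The velocity trace shows the reference two-peak structure: free flight,
a long creeping crawl while the side walls squeeze the cell (nearly all
of the transit time is spent upstream of the throat), and a sharp
expulsion peak.  `transit_time(rec)` is the time between the peaks.

## Sweeps and scaling

`scenario_grid()` encodes the study's parameter grids (throat width,
channel height, curvature radius, equal-hydraulic-diameter aspect-ratio
set, axisymmetric reference); `run_sweep()` simulates a grid and
collates transit times with the throat hydraulic diameter
`D_h = 2HW/(H + W)` of each configuration.

```{r sweep, eval = FALSE}
sw <- run_sweep(scenario_grid("radius"))
fit <- fit_power_law(sw$value, sw$T)
fit          # negative exponent: transit faster for gentler curvature
```

`fit_power_law()` is ordinary least squares in log–log space;
`crossing_radius()` locates the intersection of two fitted laws.  With
the published fit constants (coefficient 6.10, exponent −0.615 for the
rectangular channel; 4.02, −0.5 for the capillary) the two laws evaluate
to 0.79 s and 0.77 s at the control curvature radius and cross at
37.6 µm.

`dh_collapse()` groups sweep rows by throat hydraulic diameter: the three
equal-`D_h` aspect-ratio configurations (H, W_con) = (7.2, 4.717),
(8.2, 4.368), (10.2, 3.955) µm collapse to within a few percent of their
group mean, supporting the claim that the throat hydraulic diameter
dominates the transit time.

## Known limitations

* The model is quasi-static and one-degree-of-freedom per direction: it
  reproduces trends and mechanisms, not exact finite-element transit
  times (its control transit is of the right order but not 0.79 s).
* The descending branch of `T(H)` (shallow channels) is **shallower**
  than the ascending branch, opposite to the reference study, where very
  shallow channels slow the cell near-lytically.  A capsule with two
  half-extents cannot represent that deformation amplification; the
  model's descending branch exists but spans only a factor of ~1.7.
  This is asserted honestly (and fails) in the acceptance test suite.
* Gutter ducts are straight and locally uniform; the shape factor
  `k = 0.5` is a closure, exact only in the circular limit.
* Inertia, wall friction, membrane bending and nucleus are neglected
  throughout, matching the reference assumptions.

## Synthetic fixtures

`synthetic_velocity_trace()` and `synthetic_powerlaw_samples()` generate
traces and data sets with known structure (peak locations, power-law
constants, reproducible noise) used by the test suite to validate peak
detection and fitting independently of the simulator.
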