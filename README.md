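# celltransit

A reduced-order model of a neutrophil squeezing through a constricted
microchannel, with the geometry, rheology and hydraulics machinery needed
to study how the transit time depends on the channel design.

## The science

A neutrophil (resting radius 4 µm) behaves mechanically as a **Maxwell
liquid drop**: a viscous interior (31 Pa·s) in series with an elastic
element (186 Pa), wrapped in a cortex under constant tension (31 pN/µm).
Driven by a constant 40 Pa pressure difference, the cell is carried along
a microchannel whose walls narrow smoothly — an arc of curvature radius
`R_con` on each side wall leaving a throat of width `W_con`, in a channel
of height `H` (control design: `H` = 8.2 µm, `W_con` = 4.368 µm,
`R_con` = 27.525 µm; throat hydraulic diameter 5.70 µm).  An
axisymmetric capillary with the same constriction style is the reference
geometry.  All walls carry an *imaginary wall* offset 0.1 µm into the
lumen: the frictionless surface the cell actually slides on, while plasma
still penetrates the gap.

Because the throat is smaller than the cell, the cell must deform to
pass.  Its axial-velocity trace has a characteristic **two-peak
structure**: a first peak as the free-flying cell reaches the
constriction, a long slow crawl while the walls squeeze it (the cortical
tension sets a law-of-Laplace entry barrier, `2 T_c (1/r − 1/R)`,
7.045 Pa at the control throat), and a second sharp peak at expulsion.
The **transit time** `T` is the time between the two peaks.

The package replaces a full fluid–structure computation with a
quasi-static two-degree-of-freedom capsule model: the cell is a
volume-conserving rounded-rectangular capsule whose lateral and vertical
half-extents are each backed by a scalar Maxwell element, advanced with
an exact exponential stress update.  While the cell plugs the
constriction, the channel becomes a series–parallel hydraulic network —
open duct upstream and downstream, bypassed at the cell by the corner
**gutters** — and the pressure drop actually loading the cell comes from
solving that network, self-consistently with the cell's own piston flux.
The model reproduces the reference phenomenology: the two-peak trace
with the transit dominated by the upstream crawl, transit times
decreasing in throat width and in wall curvature radius, a non-monotonic
dependence on channel height with an interior minimum (tight channels
squeeze harder; tall channels leak more past the cell), and the collapse
of equal-hydraulic-diameter designs of different aspect ratio onto a
common transit time.  See `vignette("transit-model")` for the model's
closures and known limitations.

## Worked example

Simulate the control transit:

```r
library(celltransit)
rect_channel()
#> Rectangular channel model
#>   W = 22.360 um, H = 8.200 um, L = 150.0 um
#>   constriction R_con = 27.525 um, W_con = 4.368 um
#>   imaginary-wall offset 0.10 um
#>   throat D_h (nominal) 5.700 um

rec <- simulate_transit(rect_channel())   # dt = 0.001 s, dP = 40 Pa
summary(rec)
#> Transit of a 4.0 um cell, dP = 40 Pa
#> Transit record
#>   342 steps of 0.001 s (0.342 s simulated)
#>   completed; transit time T = 0.309 s (2 velocity peaks)
#>   straight-region velocity 3961 um/s; minimum velocity 4.88 um/s
#>   max |volume error| 2.12e-16 (relative); min wall clearance 0.00e+00 um
#>   tightest half-extents: w = 2.084 um, h = 3.885 um

transit_time(rec)
#> [1] 0.309

plot(rec)   # two-peak velocity trace with the detected peaks marked
```

Geometry and rheology analytics:

```r
squeeze_length(rect_channel(W_con = 3.112))   # sphere--arc tangency span
#> [1] 12.4  (rounded)
critical_pressure(cell_model(), 2.75)         # Laplace entry barrier, Pa
#> [1] 7.045 (rounded)
```

Power-law scaling of the transit time with the constriction curvature
radius, using the study's published fit constants:

```r
f_rect <- powerlaw_fit(6.10, -0.615)   # rectangular channel fit
f_axi  <- powerlaw_fit(4.02, -0.5)     # axisymmetric capillary fit
f_rect
#> Power law: y = 6.1 * x^(-0.615)
eval_power_law(f_rect, 27.525)   # 0.79 s at the control radius
eval_power_law(f_axi, 27.525)    # 0.77 s
crossing_radius(f_rect, f_axi)   # the two laws cross at 37.6 um
```

Parameter sweeps over the study's designs:

```r
sw <- run_sweep(scenario_grid("aspect"))   # equal-D_h aspect-ratio trio
dh_collapse(sw)                            # collapse within +-10%
```

## Package layout

| Module | Files | Contents |
|---|---|---|
| geometry | `R/geometry.R` | channel constructors, wall profiles, squeeze length, first contact, equal-area / equal-`D_h` throat widths |
| rheology | `R/rheology.R` | Maxwell cell model, exact stress update, creep inversion, Laplace critical pressure, reaction stress |
| hydraulics | `R/hydraulics.R` | rectangular-duct conductance (correlation + exact series), gutter conductance, pressure partition |
| simulator | `R/transit.R` | `simulate_transit()`, peak detection, transit time, S3 methods |
| sweeps | `R/sweeps.R`, `R/powerlaw.R` | `run_sweep()`, `dh_collapse()`, power-law fitting and crossing |
| scenarios | `R/scenarios.R` | reference and random scenario grids, synthetic traces and samples, YAML run configs |
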