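---
title: "From TLS point clouds to tree carbon: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From TLS point clouds to tree carbon: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tlscarbon)
```

`tlscarbon` estimates the structure, biomass and carbon of individual trees
from terrestrial laser scanning (TLS) point clouds. This vignette explains
the models behind each stage, the assumptions they make, the tunable
parameters and their defaults, and what the synthetic-data validation does
and does not demonstrate about real data.

## The measurement model

The input is a segmented, leaf-off point cloud of one tree, in metres,
z-up. All heights are measured **relative to the lowest point of the
cloud**, so georeferencing is irrelevant; all slice intervals are
half-open, `[low, high)`, which makes results deterministic when points sit
exactly on a boundary.

**Height** is `max(z) − min(z)`. This assumes the cloud reaches both the
ground and the tree top; missing crowns or floating noise points bias it
directly, and nothing in the estimator can detect that.

**Stem diameters.** A cross-section is cut ([`slice_cloud()`]), flattened
to the x–y plane, and a circle fitted. The fit is the *geometric*
least-squares circle: it minimises the sum of squared orthogonal distances
`Σ(dᵢ − r)²`, which, unlike the algebraic (Kåsa) fit, is unbiased on
partial arcs — essential because occlusion routinely leaves only part of
the stem circumference. Numerically we centre the coordinates (for
conditioning and exact translation invariance), take the Kåsa solution as
the starting point, and run Gauss–Newton with the analytic Jacobian and a
step-halving safeguard until the parameter step is below 1e-10 m or 100
iterations. On exact circles this recovers centre and radius to better
than 1e-9; on 180° arcs with 5 mm noise the radius is recovered within 2%
(both properties are pinned by Monte-Carlo-backed tests).

Three diameters serve different purposes:

| metric | slice (m above lowest point) | definition |
|---|---|---|
| DBH  | 1.2–1.4 | 2r of the least-squares circle |
| DTB  | 4.0–4.5 | same, above any basal buttress flare |
| fDBH | 1.2–1.4 | `2√(A/π)`, A = convex-hull area of the section |

DTB exists because buttressed bases make the breast-height circle
unrepresentative; fDBH is the diameter of the circle with the same area as
the (possibly non-circular) section, computed from the convex hull exactly
(the `α → 0` limit of an alpha-shape; we deliberately avoid introducing an
unstated α parameter). A slice must contain at least 20 points for any
diameter fit — a guard against meaningless fits, chosen as a floor well
below what any realistic scan density produces.

**Crown volume** is the volume of the 3-D convex hull of all points at or
above the crown base. No R package in our dependency set provides 3-D
hulls, so the package ships a compiled incremental (quickhull-style)
implementation; hull volume follows from the divergence theorem over
outward-oriented facets. Convex hulls of sampled points always
*underestimate* the hull of the underlying solid; the bias vanishes as
point density grows (the test suite pins convergence to the closed-form
volume of a prolate spheroid within 1%). When `crown_base = "auto"`, the
crown base is the lowest 0.5 m slice whose 95th-percentile horizontal
radius about the slice centroid exceeds 1.5× the DTB stem radius; scanning
starts above the buttress region (4.5 m, or a quarter of tree height for
short trees) so basal flare is never mistaken for crown. This rule is a
package design choice — field definitions of crown base vary — and it is
always overridable with an explicit height.

## Woody volume: the slice-stack estimator

Full cylinder-graph QSM reconstruction is out of scope; volume comes from
a transparent slice-stack model that is accurate on the geometry it
assumes (a single dominant stem with branches):

1. Cut the cloud into horizontal slices (default `slice_height = 0.5` m).
2. In each slice, isolate the stem: grid-based connected components
   (0.15 m cells, 8-neighbourhood), keep the component containing the
   point nearest the tracked stem centre, then — once a stem radius is
   known from below — keep only points within `max(1.5r, r + 0.1 m)` of
   the tracked centre, since branch points radiate well beyond the stem
   surface.
3. Fit the geometric circle with iterated residual trimming (up to 3
   passes, band `max(2 cm, 3×median |residual|)`); the 2 cm floor keeps
   genuine within-slice taper and range noise untrimmed.
4. Reject a slice whose radius jumps by more than 1.3× the previous
   slice's (branch contamination); bridge rejected or unfittable slices by
   linear interpolation of the radius profile, extend the lowest fitted
   radius to the ground, and taper linearly to zero at the apex.
5. Sum conical frusta between slice midpoints (exact for linear taper),
   plus the basal segment and apex cone.
6. Add branch volume as a fixed multiplier of trunk volume
   (`branch_allowance`, default 0.15). This is calibrated once against the
   synthetic generator, whose branch cylinders hold exactly 15% of trunk
   volume by construction, and then frozen; for real trees it is an
   assumption, not an estimate, and externally computed volumes (e.g. from
   QSM tools) can be supplied through the metrics table instead.
7. Repeat the whole fit `n_repeats = 10` times under seeded jitter — a
   uniform slice-phase offset in `[0, slice_height)` plus 90% random
   subsampling — and report the mean and SD, mirroring the repeat-model
   mean/SD convention of QSM optimisation.

If fewer than 60% of slices yield a direct fit on the reference pass, the
estimator refuses and lists the empty slice heights rather than
extrapolating through them.

Accuracy pinned by tests: < 1% on analytic cones and curved tapers, < 5%
on full synthetic trees including branches, noise and buttress flare;
halving the slice height never worsens noiseless error (the discretisation
error of frusta scales with slice height on curved profiles and is zero on
exact cones).

## Biomass, carbon and growth rates

`AGB = V·ρ` with ρ = 0.34 Mg m⁻³ by default — the adopted whole-tree value
for *S. giganteum*, within the published 0.3–0.4 range; component
densities span ~0.2 (bark) to ~0.45 (branch wood), so a single ρ
overestimates slightly when bark fraction is high. Carbon is `CF × AGB`
with CF = 0.54, the measured *S. giganteum* carbon fraction (among the
highest for North American species). Both parameters are validated to
plausible ranges ((0.2, 0.6) and (0.4, 0.6)) and configurable.

Annual rates assume **constant lifetime growth**: `H/age` (m yr⁻¹),
`100·DBH/age` (cm yr⁻¹), `1000·AGB/age` (kg yr⁻¹), carbon rate =
CF × AGB rate. Real growth varies with age and survivorship, so these are
lifetime averages, not current increments. Site/cohort summaries report
rates under two conventions — cohort-mean metric over cohort-mean age, and
the mean of per-tree rates — because the two differ for mixed-age cohorts
and neither is canonical; they coincide exactly when ages are uniform.
Site comparisons use the two-sided Welch (unequal-variance) t-test on
per-tree AGB accumulation rates: cohorts of different age and management
have visibly unequal variances, so the pooled-variance test would be
wrong more often than it would be sharp.

## Allometric models

The registry (`allometric_models()`) carries five published models with
their printed coefficients and **declared units**, because the source
calibrations disagree: Parks and the two Sillett models predict volume
(m³) from metric diameters and are converted to AGB with ρ = 0.34 where
the source does not print a density; Jenkins is declared in its native
calibration units (DBH in cm, AGB in kg) and converted at the interface;
the Chojnacky-style two-term form is declared in m/Mg. These declarations
are documented choices — unit conventions are the single largest risk when
transplanting allometries, which is part of the motivation for fitting
local models at all.

New models use the two-parameter power law `AGB = a·xᵇ` with
x ∈ {DBH²H, DTB²H, DBH, H}, fitted by **nonlinear least squares in
arithmetic space** (Levenberg–Marquardt via `minpack.lm`, initialised at
`a = ȳ/x̄`, `b = 1`, tolerances 1e-12, 200 iterations). Fitting in
arithmetic space avoids the log-transform and its retransformation bias
correction; the cost is heteroscedastic leverage of large trees, which is
the standard trade-off. Reported statistics: r², RMSE (Mg), and bias
defined as the mean of `(predicted − observed)/observed` in percent
(alternative definitions would change the number, so the definition is
fixed and stated). Noiseless data generated from any implemented form are
recovered to 1e-6 with r² = 1; at 5% noise and n = 97 the median
coefficient error is below 5% (200-seed Monte Carlo).

Model-vs-TLS agreement (`evaluate_model()`) is the OLS line of predicted
on observed — gradient, intercept, gradient SE, r² — plus
`RMSE = √mean((pred − obs)²)`.

Uncertainty comes from a **parametric bootstrap**: `n_boot = 100` synthetic
datasets drawn from the fitted curve plus Gaussian residuals (sd = residual
sd of the fit), each refitted, and the refit predictions summarised per
abscissa. The default band is the min–max of refits, with 2.5/97.5
percentiles also reported, since the band summary is otherwise
underdetermined. Zero residual sd collapses the band to the fitted curve
exactly, which the tests assert.

## The synthetic generator: what it emulates, and what it does not

`tree_spec()` / `generate_tree_cloud()` build tall open-grown conifers
with every target quantity known in closed form:

- trunk: surface of revolution, radius
  `r(h) = r_bh·((H−h)/(H−1.3))^taper` plus a basal flare
  `b·(1 − h/flare_height)²`, sampled as rings at the point spacing; trunk
  volume truth is the exact integral of the squared profile (adaptive
  quadrature, 1e-11 relative tolerance — the taper×flare cross term has no
  elementary antiderivative for general exponents, and the quadrature is
  asserted against the closed-form cone in tests);
- branches: explicit cylinders whose summed volume is exactly 15% of trunk
  volume (so "woody volume truth" stays analytic while crown hulls remain
  non-trivial);
- crown: conoid, paraboloid or prolate spheroid, surface-sampled with
  sparse interior fill; crown volume truth is the solid's closed form;
- nuisance processes: per-coordinate Gaussian range noise (default 5 mm,
  the scale of survey-grade TLS at tens of metres), an azimuthal occlusion
  sector removed from the trunk, and whole-tree lean.

Defaults describe a mature open-grown sequoia-like conifer (H = 45 m,
DBH = 1.5 m, 25 cm basal flare vanishing at 2.5 m, crown base 8 m, crown
radius 4 m); `generate_site()` jitters the template multiplicatively
(default 10% relative sd) to make cohorts with known planting dates. Point
spacing defaults to 5 cm — a deliberate desk-scale thinning of real TLS
density chosen so a full multi-site pipeline run stays in seconds-per-tree;
the estimators only get more accurate as spacing shrinks, so this choice is
conservative for validation. One seeded RNG stream drives each generation
call, so identical specs and seeds give byte-identical clouds.

Deliberately *not* modelled: beam divergence and range-dependent footprint,
leaf/wood misclassification, multi-scan registration error, non-circular
stem sections, hollow stems and bark fraction. Passing the synthetic suite
therefore demonstrates the estimators' correctness on clouds whose
geometry matches the assumed model with realistic density, noise and
occlusion — it does not certify accuracy on trees whose form violates
those assumptions (fluted or multi-stemmed trunks, heavily occluded
crowns), and real-data biases of TLS itself (registration, wind movement)
are out of scope.

## Numerical and design choices, in one place

- Half-open slices, heights relative to the lowest point; boundary points
  excluded at the top of a slice.
- Circle fit: centred coordinates, Kåsa init, Gauss–Newton, step < 1e-10 m
  or 100 iterations; the algebraic fit is retained and the tests assert
  the geometric fit never has a worse objective.
- Convex hulls: scale-relative epsilon (1e-10 × bounding-box diagonal) for
  facet visibility; coplanar/collinear inputs are rejected as degenerate
  rather than perturbed.
- Power-law NLS: `a = ȳ/x̄, b = 1` start, 1e-12 tolerances; degenerate
  predictor variance and non-positive responses are errors, not warnings.
- Failure policy everywhere: per-tree skip-and-record. A failed metric is
  `NA` with a reason in the issue ledger; the pipeline never imputes.
- Rounding for reports follows printing conventions (rates to 2 d.p. in
  m yr⁻¹ / cm yr⁻¹, 1 d.p. in kg yr⁻¹); internal values are never rounded.
- Test and acceptance problem sizes (trees of 20–50 m at 6–10 cm spacing,
  sites of 5–28 trees, 100-seed and 200-seed Monte-Carlo loops) are the
  package's chosen validation scale: large enough for the stated
  tolerances to be meaningful, small enough to run routinely.

## Known limitations

- The branch allowance is an assumption calibrated on the generator's
  15% branch fraction; real branch fractions vary with age and
  competition. Import QSM volumes when fidelity matters.
- Constant-growth rates are lifetime averages; they understate current
  uptake of accelerating trees and overstate it for senescent ones.
- The slice-stack estimator assumes one dominant stem; forked trees will
  be under-measured above the fork.
- LAS support is read-only and minimal (formats 0–3, coordinates only);
  PLY/XYZ are the first-class formats.
- Published-model unit declarations for the generalized conifer models are
  documented choices, not facts recoverable from the comparison context.
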