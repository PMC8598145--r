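---
title: "Predicting electron insert factors with an equivalent-ellipse spline model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting electron insert factors with an equivalent-ellipse spline model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(insertfactor)
```

## The clinical problem

Electron treatments shape the beam with a square applicator (cone) plus a
patient-specific Cerrobend insert (cutout). The insert changes the machine
output at the depth of maximum dose: narrow cutouts lose lateral scatter
equilibrium and the insert edge contributes its own scatter, so the output
with the insert differs from the open cone by the *insert factor*

$$IF = \frac{\text{output, insert, treatment SSD}}
           {\text{output, open cone, treatment SSD}},$$

which enters the monitor-unit calculation

$$MU = \frac{D\ \mathrm{(cGy)}}
  {(1\ \mathrm{cGy/MU}) \cdot \mathrm{isodose\ fraction} \cdot CF \cdot IF},$$

with $CF$ the cone factor (open cone at treatment SSD over the reference
15×15 cone at 100 cm SSD), a commissioning input this package takes as
given. Measuring $IF$ for every new cutout is accurate but slow; this
package implements the alternative of fitting a small spline model to a
handful of measured factors and interpolating all other shapes.

## Equivalent-ellipse parameterization

A cutout is an arbitrary simple polygon, drawn in the beam's-eye view at
100 cm source distance (treatment SSD never rescales the polygon; it only
selects which model is used). Two numbers summarize it:

* **width** — the diameter of the largest circle fully enclosed by the
  shape, which tracks loss of lateral scatter equilibrium;
* **length** — defined so that the ellipse with these axes has the same
  area as the shape, $\ell = 4A/(\pi w)$.

The spline's second coordinate is the perimeter-to-area ratio $P/A$ of
that equivalent ellipse, a measure of how much insert edge the beam sees
per unit open area. There is no closed form for an ellipse perimeter; the
package always uses Ramanujan's first approximation
$P \approx \pi\,[\,3(a+b) - \sqrt{(3a+b)(a+3b)}\,]$ (error below 0.05%
for clinical aspect ratios), so the $P/A$ axis is reproducible
bit-for-bit. At fixed area convention, (width, length) and (width,
$P/A$) are in bijection, so either pair describes a shape; the model is
fitted over (width, $P/A$).

The largest inscribed circle has no closed form for irregular shapes. It
is computed by iterative grid refinement: score a coarse grid of cell
centers by signed distance to the boundary, discard cells whose center
distance plus circumradius cannot beat the current best, subdivide the
rest, and stop when the cell size guarantees the requested accuracy
(default `tol = 0.005` cm on the diameter). This is robust for
non-convex cutouts and requires no solver. The unit tests check it
against a brute-force dense-grid oracle on random convex polygons.
Parameterization is translation- and rotation-invariant; off-axis
inserts are deliberately not recentered (off-center placement is a known
error source of the underlying measurements, not of the geometry).
Multiply-connected cutouts (island blocks) are rejected.

## Measurement design

One model is fitted per (machine, energy MeV, applicator, SSD)
combination, and a model requires **at least eight measured shapes** —
a hard floor enforced regardless of spline configuration.
`design_measurement_shapes()` generates the recommended set: ellipses at
the cone's practical maximum length (7, 13, 19, 21 cm for the 6, 10, 15,
20 cm cones) with varying widths, plus circles spanning the same width
range — together these bound the reachable (width, $P/A$) region — and,
for cones of 10 cm and larger, interior shapes (a mid-size square and,
for the 15/20 cm cones, mid-space rectangles). Interior augmentation
exists because bounding shapes alone leave the middle of the parameter
space unsampled, where predictions were observed to degrade; the
package's `recovery_experiment()` quantifies exactly this effect on
synthetic data. Defaults produce 8 shapes for the 6 cm cone and 11 for
the 10 cm cone.

Note the reachable region is not a rectangle: for a given width the
largest possible $P/A$ is the circle's $4/w$. The convex hull of
training points can therefore contain coordinates no physical shape
maps to; coverage diagnostics (`coverage_report()`) and the recovery
experiment's probe shapes respect this by working with realizable
ellipses.

## The spline model

`fit_insert_model()` fits a tensor-product polynomial spline to the
measured factors by penalized least squares:

* Width and $P/A$ are standardized to unit ranges before fitting (they
  differ in scale by roughly 10×), and records are canonically sorted by
  (width, $P/A$, shape id), making the fit independent of input order.
* Default degrees are **cubic along width, linear along $P/A$**. The
  small-field output drop is strongly curved in width, while the edge
  penalty in $P/A$ is gentle; the resulting basis has exactly
  $(3+1)(1+1) = 8$ coefficients — the same number as the model's minimum
  data requirement, so the smallest legal data set determines the
  surface completely.
* Default smoothing is a mild second-difference penalty on the
  coefficient grid (`smoothing = 1e-3`). Constants and planes are never
  penalized (directions with two coefficients contribute no penalty
  rows). The penalty matters because bounding designs concentrate along
  two curves of the parameter plane: an unpenalized fit is poorly
  constrained in the corners between them, and leave-one-out
  predictions of corner shapes become erratic. The default was selected
  with the package's own synthetic recovery experiment: it keeps
  interior prediction errors of noisy (σ = 0.002) 11-shape designs
  below 1%, keeps leave-one-out mean absolute error at the 0.5%
  scale expected for this technique, and preserves the benefit of
  interior augmentation. With `smoothing = 0` the fit is exact least
  squares and, at 8 points, interpolation.
* Interior knots are placed at coordinate quantiles when the group has
  enough points to support the extra coefficients; at the 8–13
  measurements typical here the automatic choice is no interior knots,
  so the surface is a single polynomial patch.
* Queries outside the convex hull of the training points are evaluated
  by continuing the boundary polynomial (a Taylor expansion of the edge
  piece — exact for piecewise polynomials) and **flagged as
  extrapolation**, never silently clamped: the caller must see the
  flag, and reports carry a warning banner.

Exactness properties are tested: any surface polynomial of degree at
most the spline degrees is reproduced to 1e-6 at unpenalized settings,
fits are permutation-invariant to 1e-12, and a model refuses to fit
fewer than eight records or a rank-deficient design (for example, all
shapes the same width).

`loo_errors()` provides the uncertainty diagnostic: refit with each
record held out and predict it. It requires nine records so every fold
keeps the eight-point floor. Models serialize to versioned JSON
(`save_model()`/`load_model()`) with exact round-trip.

## SSD interpolation

Factors are modeled per SSD (clinically 100, 105, 110 cm). For
intermediate SSDs, `interpolate_ssd()` evaluates the unique quadratic
through the three modeled factors — predicted factors follow a quadratic
trend in SSD — and reproduces each node exactly. This technique is
preliminary (reports label it as such) and targets outside the node
range are flagged extrapolations.

## DICOM RT Plan extraction

`read_rtplan()` pulls the machine, nominal energy, applicator ID and
planned SSD of one electron beam plus its block outline from an RT Plan
(explicit-VR little-endian), converting mm to cm. When a
source-to-block-tray distance is present, block coordinates are rescaled
from the tray plane to the 100 cm plane; without it they are assumed to
be at 100 cm already. Treatment planning systems differ in which
convention they export, so **this projection must be validated against
an export of the local planning system before any clinical use**; the
package's own fixtures (written by `write_rtplan_fixture()`) are
round-trip consistent by construction and are additionally checked
against an independent DICOM implementation in the test suite. Photon
beams, plans without block data, and multi-beam plans without an
explicit beam index are classed errors.

## The synthetic surface

Real model-input factors are commissioning data and are not shipped.
`synthetic_surface()` provides a ground truth with the structure the
model assumes:

$$f(w, r) = \mathrm{plateau} - a\,e^{-w/w_0} - b\,(r - r_0)_+$$

with defaults plateau 1.0, $a = 0.25$, $w_0 = 2.5$ cm, $b = 0.05$ cm,
$r_0 = 0.6$ cm⁻¹, bounded in (0.5, 1.1) over width 2–20 cm and $P/A$
0.2–2.0 cm⁻¹. The exponential emulates the small-field output drop and
the hinge a mild edge-scatter penalty; the defaults order factors the
way measured tables do (small narrow inserts ≈ 0.86–0.95, large inserts
≈ 1.00). Measurement noise is homoscedastic Gaussian with σ = 0.002 on
the factor — the scale of averaged-chamber-reading repeatability —
drawn from R's Mersenne–Twister generator under a fixed seed, so every
experiment is exactly reproducible.

What the generator does **not** emulate — and hence what passing
recovery tests cannot show about real data: energy/cone/SSD dependence
of the surface shape (the same $f$ is used for every group), correlated
or heteroscedastic measurement error, off-axis insert placement, and
any machine-specific scatter detail. The synthetic database written by
`simulate_database()` is labeled synthetic in its machine id and
documentation.

`recovery_experiment()` runs the full pipeline (parameterize → sample →
fit → predict) for a boundary-only 8-shape design versus the augmented
design over paired noise replicates (default 20) and reports bias, RMSE
and maximum absolute error at ~50 probe shapes inside both training
hulls. On the default surface the augmented design's interior error is
never worse at the design level (mean and worst replicate), mirroring
the accuracy gain that motivated augmenting the larger cones.

## Validation fixtures

Two CSV tables of measured-versus-predicted insert factors for clinical
inserts (22 patient cutouts and 26 standard cutouts, spanning 6–20 MeV,
6–20 cm cones and 100–110 cm SSD) ship with the package, transcribed
from a published validation of this technique. `summarize_validation()`
reproduces their printed aggregate statistics: patient mean absolute
difference 0.9%, overall maximum 2.1%, overall signed mean 0.4%
(a slight bias toward predictions exceeding measurements), patient
signed SD 0.8%, overall SD of absolute differences 0.6%. Percent
differences use the convention $100\,( \mathrm{calculated} -
\mathrm{measured})/\mathrm{measured}$ and are taken from the tables as
printed by default — recomputing from 3-decimal factor columns can
shift individual rows by up to 0.1 points. Both the signed and the
absolute-difference standard deviations are computed and labeled, since
neither bounds the other in general. `fit_gaussian_histogram()` fits a
count-scaled normal density to the binned signed differences (default
bin width 0.5%), the customary histogram summary for such comparisons.

## Numerical choices and limitations

* Inscribed-circle tolerance 0.005 cm; predictions of highly concave
  shapes could differ at the third decimal of width between
  implementations with different tolerances.
* Polygon cleanup tolerance 1e-9 cm (duplicate merging); report
  rounding is round-half-even, 3 decimals for factors, 1 for MU, with
  full precision kept internally.
* Test and experiment sizes (20 recovery replicates, 50 probes, 100
  round-trip fixtures, 12–15 random polygons per property) were chosen
  to exercise each property well while keeping the default suite fast.
* Out of scope: cone-factor modeling, water-tank scan processing,
  depth-dose conversion protocols, stopping-power corrections, island
  blocks, bolus/skin collimation, and any Monte Carlo dose engine.
* The SSD quadratic interpolation and the DICOM tray-plane projection
  are the two components most in need of site-specific validation
  before clinical deployment.

## A worked example

```{r example, eval = FALSE}
# build a synthetic measurement database and fit one model
db_file <- tempfile(fileext = ".csv")
db <- simulate_database(synthetic_surface(seed = 3), db_file, seed = 3)
g <- db_group(db, "synthetic", 12, 10, 100)
model <- fit_insert_model(g)

# parameterize a new cutout and predict its factor
cutout <- ellipse_polygon(4, 8)
ee <- parameterize_shape(cutout)
p <- predict_factor(model, ee)
compute_mu(200, insert_factor = p$insert_factor,
           prescribed_isodose_fraction = 0.9)
```
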