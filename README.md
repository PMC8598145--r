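# insertfactor

Electron insert (cutout) factor prediction for clinical linear
accelerators, using equivalent-ellipse shape parameterization and
bivariate spline interpolation of a small set of measured output factors.

## The problem

Electron fields are shaped by a square applicator (cone) plus a
patient-specific Cerrobend insert. The insert changes the machine output
at d_max by the **insert factor**

    IF = output(insert, treatment SSD) / output(open cone, treatment SSD),

which enters the monitor-unit calculation

    MU = Dose (cGy) / [ (1 cGy/MU) × isodose fraction × CF × IF ],

where CF is the measured cone factor. Measuring IF for every new cutout
is accurate but laborious. This package instead:

1. **parameterizes** an arbitrary cutout polygon into its *equivalent
   ellipse* — width = diameter of the largest circle fully enclosed by
   the shape, length chosen so the ellipse area equals the shape area —
   summarized as (width, perimeter-to-area ratio of the ellipse);
2. **fits** a tensor-product spline to measured insert factors over that
   (w, P/A) plane, one model per (machine, energy, cone, SSD), from as
   few as eight bounding-shape measurements;
3. **predicts** the factor of any new shape by spline evaluation, with
   extrapolation and hull-coverage diagnostics, monitor-unit
   calculation, quadratic SSD interpolation, and plain-text/PDF reports.

It also ships a DICOM RT Plan reader/writer for extracting insert
outlines from planning-system exports, a measurement-database CSV
format, recommended per-cone measurement designs, validation statistics
for measured-versus-predicted comparisons (with fixture tables from a
published clinical validation of the technique), and a synthetic
output-factor simulator so the full pipeline is testable without
measurements. A thin CLI lives at `exec/cutoutcalc`
(`parameterize`, `design-shapes`, `fit`, `predict`, `report`,
`validate`, `simulate`).

## Worked example

```r
library(insertfactor)

# a measurement database (here synthetic; normally measured factors)
db_file <- tempfile(fileext = ".csv")
db <- simulate_database(synthetic_surface(seed = 3), db_file, seed = 3)
g  <- db_group(db, "synthetic", 12, 10, 100)   # 12 MeV, A10, SSD 100

model <- fit_insert_model(g)
#> <insert_spline: group synthetic|12|10|100, 11 training shapes,
#>                 degrees (3, 1), smoothing 0.001>
#>   width 2.50-9.50 cm, P/A 0.421-1.600 /cm

cutout <- ellipse_polygon(4, 8)                # a 4 x 8 cm cutout
parameterize_shape(cutout)
#> <equivalent_ellipse: width 4.000 cm, length 7.997 cm,
#>                      area 25.123 cm^2, P/A 0.7711 /cm>

p <- predict_factor(model, parameterize_shape(cutout))
p$insert_factor                                # 0.939 (not extrapolated)

compute_mu(200, insert_factor = p$insert_factor,
           prescribed_isodose_fraction = 0.9)  # 236.6 MU
```

The predicted factor 0.939 says this 4 × 8 cm cutout delivers 93.9% of
the open-cone output, so 236.6 MU are needed for 200 cGy prescribed to
the 90% line (cone factor 1 here). The shipped validation tables
summarize the technique's clinical accuracy:

```r
summarize_validation(validation_fixture("patients"))
#> <validation_summary: n = 22>
#>   mean |diff|   0.93 %
#>   max  |diff|   2.10 %
#>   mean signed   0.87 %
#>   SD signed     0.76 % (n-1)
#>   SD |diff|     0.67 % (n-1)
```

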