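# auriclesym

High-precision, surface-based morphometry of the human auricle (external
ear) from triangulated 3D head meshes, with bilateral-symmetry statistics.

## The problem

In ear reconstruction (microtia repair, otoplasty) the contralateral ear is
the de-facto reference, which silently assumes the two ears of an individual
are symmetric. Whether a left-right difference can be *detected* at all
depends on measurement precision: a bilateral difference smaller than the
measurement error is indistinguishable from noise, so imprecise methods make
ears look symmetric. This package implements, end to end:

1. an automatic surface-based measurement pipeline that derives seven
   geometric auricle parameters from a labeled head mesh —
   **length**, **width**, **protrusion distance**, **auriculocephalic
   angle**, **inclination angle**, and the **superoinferior** and
   **posteroanterior** bilateral position differences;
2. a landmark-based "manual" measurement emulator (classic anthropometric
   points plus observer placement noise) for the four parameters a human
   operator can realistically measure;
3. bilateral-symmetry statistics built on reliable-change thresholds;
4. a parametric synthetic head/ear generator with exactly known ground
   truth, so every stage is validated without any external data.

## The method

**Head frame.** The midsagittal plane is found by mirror registration: the
head surface is reflected across a candidate plane and rigidly registered
back onto itself (ICP with area-weighted vertex subsampling); the invariant
plane of the composite reflection-plus-rigid map is the symmetry plane, and
its normal defines the lateral **x** axis. A least-squares cylinder fitted
to the cranial vault supplies the vertical **y** axis; **z = x × y** points
anterior; the origin is the head surface centroid projected onto the
midsagittal plane.

**Parameters.** A total-least-squares plane is fitted to the auricle points,
the points are projected into it, and principal-component axes give length
and width as peak-to-peak extents. A plane fitted to the mastoid region
behind the ear provides the reference for protrusion (maximum perpendicular
distance of the auricle from the mastoid plane) and for the
auriculocephalic angle (angle between the auricle-plane and mastoid-plane
normals). Inclination is the signed angle between the long axis of the
midsagittally projected auricle and +y. Auricle positions are area-weighted
surface centroids; their left-minus-right differences along y and z give
the positional parameters.

**Symmetry statistics.** For a parameter with test-retest precision SD and
left-right correlation r across the cohort, the reliability threshold is
the reliable-change form

```
T_rel = 1.96 * SD * sqrt(2 * (1 - r))
```

and a subject is flagged asymmetric when |L − R| exceeds T_rel (5%
two-sided level). Positional parameters are already bilateral differences
and use `T_rel = 1.96 * SD`. Group-level symmetry is assessed with paired
t-tests plus Shapiro-Wilk normality per side.

## Worked example

```r
library(auriclesym)

gh <- generate_head(head_spec(
  left  = auricle_side_spec(length = 63.5, width = 30, protrusion = 22,
                            acangle = 33, inclination = 27, y_offset = -8.5),
  right = auricle_side_spec(length = 60.2, width = 33, protrusion = 19,
                            acangle = 28, inclination = 23, y_offset = -11),
  noise_sd = 0.1, seed = 42))

m <- measure_all(gh$head)
print(m)
#> <auricle_measurement> (mm / degrees)
#>   Left  length  63.65  width  30.12  protrusion  22.02  acangle  32.85  inclination  26.67
#>   Right length  60.44  width  33.11  protrusion  19.10  acangle  28.05  inclination  22.67
#>   position diff (L-R): SI +2.49  PA +2.21
```

Every measured value sits within a few tenths of a millimetre / degree of
the generator's ground truth (left length 63.5, right 60.2, ...), including
the 0.1 mm scan noise. The superoinferior position difference (+2.49 mm)
recovers the injected 2.5 mm attachment offset.

The full study workflow is the script sequence under `analysis/`:

```sh
Rscript analysis/01_simulate_cohort.R    # 42 synthetic heads + ground truth
Rscript analysis/02_precision.R          # repeated-scan + landmark precision SDs
Rscript analysis/03_measure_cohort.R     # automatic + manual measurements
Rscript analysis/04_symmetry_report.R    # thresholds, flags, group tests, figure
Rscript analysis/05_null_calibration.R   # 5% null calibration check
```

Outputs land in `results/`. On the default cohort the automatic precision
SDs are ~0.02–0.23 (mm or degrees) against ~2.1–4.6 for the landmark
method, so the automatic thresholds are ~20–100 times lower, and the
per-subject detection fractions are 90–100% (automatic scoring) versus
2–29% (manual scoring) — while every group-level paired t-test stays above
p = 0.05: individual ears differ even when group means do not.

## Package layout

- `R/` — mesh I/O (PLY/STL/OBJ), geometry primitives, registration and
  symmetry plane, cylinder fit, head frame, auricle metrics, manual
  emulator, symmetry statistics, synthetic generator.
- `analysis/` — the numbered study workflow above.
- `tests/testthat/` — unit, property and end-to-end validation suites.
- `vignettes/auricle-symmetry-methods.Rmd` — the methods vignette: model
  assumptions, parameter choices, numerical decisions, limitations.
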