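---
title: "Surface-based auricle morphometry: models, parameters, and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface-based auricle morphometry: models, parameters, and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its science: what is modelled,
which knobs exist and why their defaults are what they are, where the design
was genuinely open and what we chose, and what the synthetic validation does
and does not demonstrate about real data.

## The measurement model

The pipeline consumes a triangulated head surface (vertices in mm) with
vertex labels for the left and right auricle regions, and optionally mastoid
labels and named landmarks. Everything else is derived.

### Head-centric coordinate frame

* **Midsagittal plane.** Candidate planes are the principal planes of the
  area-weighted vertex covariance; when the two smallest principal spreads
  are within a factor 1.5 (heads are nearly rotationally symmetric about
  their long axis, making those eigenvectors unstable mixtures) the
  degenerate subspace is swept in 7.5 degree steps. Each candidate is scored
  by the mean squared nearest-neighbour distance of the mirrored subsample
  to the full vertex set; the best candidate is refined by mirror ICP:
  reflect an area-weighted vertex subsample, register it rigidly back onto
  the full vertex set, and extract the invariant plane of the composite
  reflection-then-rigid map (the eigenvector of its improper orthogonal part
  with eigenvalue closest to -1).
* **Cranial axis.** A circular cylinder is fitted by Levenberg-Marquardt
  least squares (residual: distance-to-axis minus radius) to a band of head
  vertices starting 5 mm above the auricle top and extending 45 mm upward.
  The band is re-selected along the fitted axis and the fit repeated three
  times, so a tilted initial axis (e.g. from principal axes bent by the
  nose) cannot leave the band an oblique slab.
* **Orientation conventions** (nowhere standardized, so fixed here and
  documented): +y points superior, identified as the head extreme along the
  cranial axis farther from the mean auricle centroid; +z points anterior,
  identified as the direction in which the head surface extends farther
  from the origin (the face/nose side protrudes beyond the occiput; an
  explicit `anterior_override` exists for unusual geometries); +x completes
  the right-handed frame. The origin is the area-weighted head surface
  centroid projected onto the midsagittal plane.

Two decisions here deserve emphasis because they were made *against*
plausible alternatives after those alternatives failed quantitatively:

1. **The symmetry plane is estimated from the head with the auricle regions
   removed.** The frame is the reference the ears are measured against.
   If the mirror registration sees the ears, a bilaterally asymmetric pair
   drags the plane toward the asymmetry being quantified: a plane rotation
   of only 1 degree projects the ~180 mm lateral centroid separation into
   millimetres of spurious positional difference. Trimmed ICP was tried as
   a label-free alternative and made things worse (trimming licenses the
   rotated solution by discarding the protesting surface); a `trim`
   argument remains available but defaults to 0.
2. **Vertex subsampling is area-weighted.** Mesh density is an artifact of
   processing, not anatomy; a densely meshed feature must not outvote the
   rest of the surface. The same reasoning makes the auricle centroid the
   area-weighted surface centroid rather than the vertex mean.

### The seven parameters

* **Length, width**: total-least-squares plane fit to the (optionally
  lateral-quantile-selected) auricle points, orthogonal projection into that
  plane, principal axes of the projected cloud; length and width are the
  peak-to-peak extents along the first two axes. Extents use outermost
  points, not eigenvalue spreads, because the clinical quantities are
  caliper-like distances.
* **Mastoid plane**: least-squares plane through the labeled mastoid
  vertices, or, without labels, through head vertices in a 5-20 mm annulus
  around the auricle centroid's projection onto the head surface. Its
  normal is canonicalized to point away from the head interior.
* **Protrusion**: maximum perpendicular distance of any auricle point from
  the mastoid plane, on the outward side; inward distances are clamped.
* **Auriculocephalic angle**: `acos(|n1 . n2|)` between the auricle-plane
  and mastoid-plane normals, in [0, 90] degrees. A configuration switch
  (`reference_plane = "midsagittal"`) substitutes the midsagittal plane,
  because the two descriptions of this angle in circulation disagree on the
  reference; the mastoid plane is the default and both choices are recorded
  in the output.
* **Inclination**: project the auricle onto the midsagittal plane, take the
  first principal axis of the flattened shape, and report its signed angle
  to +y in (-90, 90], positive when the superior tip leans posterior. If
  the flattened shape is near-circular (extent ratio < 1.05) the axis is
  declared ill-defined and an error is raised rather than returning an
  arbitrary angle.
* **Positions**: signed left-minus-right differences of the auricle surface
  centroids along +y (superoinferior) and +z (posteroanterior).

### Landmark-based manual emulation

The manual path computes length (superaurale-subaurale), width
(preaurale-postaurale), protrusion (lateral helix to mastoid base) and a
3-point auriculocephalic angle at the tragus, from operator-placed
landmarks perturbed with isotropic Gaussian observer noise (default SD
1.5 mm, a typical reported placement variability for 3D landmarking).
Inclination and positions are deliberately not produced: placing landmarks
that define them reliably is impractical, which is precisely the manual
method's limitation the comparison illustrates. The 3-point angle is not
numerically identical to the surface-based plane angle — real manual and
surface methods disagree in the same way — but left-right *differences*
cancel the shared bias.

## Symmetry statistics

For the five paired parameters the reliability threshold is the
reliable-change form `T_rel = 1.96 * SD * sqrt(2(1 - r))`; the positional
parameters, being differences already, use `1.96 * SD`. The radical is a
deliberate reading: the reliable-change index of the measurement-error
literature carries it, and without it the expression is not even
dimensionally a measurement SD; a `variant = "literal"` switch implements
the no-radical form for sensitivity analysis.

What to plug in for SD matters more than it looks:

* In cohort scoring (`summarize_cohort`) SD is the **precision SD** from
  repeated measurements of one specimen, and r is the left-right
  correlation of the cohort being analyzed — the combination the original
  workflow uses. Its thresholds are the right scale for judging *which
  individuals* exceed measurement noise, but the 5% level is nominal, not
  exact, because r mixes between-subject variance into a formula whose
  reliable-change derivation expects SD to be the cohort SD.
* In the null-calibration simulator (`simulate_null_flag_rate`) SD is the
  **cohort sample SD** and r the left-right correlation of the same
  simulated data. Then `SD * sqrt(2(1-r))` equals `sqrt(2) * sigma_noise`
  up to sampling error for *any* between-subject truth distribution, and
  the false-positive rate is exactly the nominal 5%. The package's
  calibration tests and the acceptance script use this form; the analysis
  scripts demonstrate it across noise and truth spreads.

Group-level analysis is a paired t-test per parameter plus Shapiro-Wilk
normality per side (one-sample t against zero for the positional
parameters). Non-normality is reported, never acted on, and no
multiple-testing correction is applied across the seven parameters — both
choices mirror how such tables are conventionally reported.

## The synthetic generator

The generator is the package's ground-truth engine; its defaults *are* the
study conditions of every validation below.

* **Cranium**: superellipsoid `(x/a)^2 + (z/c(y))^2 + (y/b)^4 = 1` with
  a = 80, b = 108 mm, and an anteroposterior semi-axis blending from
  c = 92 mm below ear level to 80 mm (circular section) in the vault; a
  compact nose bump low on the front face breaks front-back symmetry. The
  quartic vertical profile gives near-vertical parietal walls. This exact
  shape is load-bearing: a fully circular cranium is rotationally
  symmetric, leaving the midsagittal plane anchored only by ears and nose
  (we observed spurious planes and multi-degree registration stalls), while
  an elliptical vault section rewards a *tilted* cylinder axis, whose
  foreshortening rounds the section (we measured 8-24 degree tilts). The
  mixed profile removes both degeneracies and is anatomically the more
  defensible description of a cranial vault anyway.
* **Mastoid patches** are flattened onto their tangent planes (radius
  25 mm), so the mastoid plane, protrusion and hinge angle have exact
  ground truth.
* **Auricles** are flat elliptical shells (length x width), long axis in
  the tangent plane at the inclination angle from vertical, hinged off the
  plane by the auriculocephalic angle, stood off along the normal by
  `h = protrusion - width*sin(acangle)` so protrusion is a free parameter,
  and attached at configurable (y, z) offsets. Landmarks sit at the true
  geometric extremes. The ellipse boundary is sampled exactly at its four
  apexes so peak-to-peak extents can reach the true values.
* **Noise**: i.i.d. Gaussian vertex displacement, default SD 0.1 mm —
  sub-voxel surface localization for CT at 0.34-0.46 mm pixels. Real CT
  noise is spatially correlated; modelling it i.i.d. makes repeated-scan
  SDs a best case, which is why the manual/automatic contrast is driven by
  the landmark-level observer noise (1.5 mm), not by scan noise.
* **Cohorts**: between-subject parameter variation is normal
  (length 62 +/- 4, width 32 +/- 3, protrusion 20 +/- 2.5 mm, angles
  30 +/- 4 and 25 +/- 4 degrees); true asymmetry is half-normal per
  parameter with scales (2.2, 3.0, 3.5 mm, 4.2, 3.0 degrees, 2.0 mm
  positions) chosen so that a few-dozen-subject cohort spans maxima of
  several millimetres / degrees, the order of magnitude clinical reports
  print. One global seed expands to per-subject and per-repeat seeds, so
  partial re-runs reproduce exactly.

What passing the synthetic validation shows: the pipeline's geometry is
correct (rigid-motion invariant to < 0.05 mm/degree, exact on mirrored
heads, parameter recovery within 0.5 mm / 1 degree at the default
resolution) and its statistics are calibrated. What it does not show:
robustness to real segmentation artifacts, helix/lobule substructure,
correlated scanner noise, or genuinely non-planar auricle shapes — flat
shells make the plane-fit step easier than a curved pinna would.

## Numerical choices

* Plane fits use the SVD of centered coordinates; degeneracy (collinear
  points) raises a classed error rather than returning an arbitrary plane.
* Principal-axis signs are fixed against caller-supplied reference
  directions (head-frame +y, ties toward +z): eigenvectors have arbitrary
  sign and downstream signed angles need determinism.
* ICP: moving subsample 5000 points (area-weighted, seeded), fixed set all
  vertices, 100 iterations maximum, relative RMS improvement tolerance
  1e-8. The closest-point kernel is a brute-force Rcpp scan — at these
  sizes it beats tree construction and has no approximation error.
* Cylinder fit: 5 parameters (2 axis tilts against the initialization,
  2 in-plane axis offsets, radius), Levenberg-Marquardt with up to 500
  iterations; solver non-convergence raises a fit error with the solver's
  diagnostic rather than returning the last iterate.
* Geometric identities are asserted to 1e-9 (orthonormality, plane
  membership); mesh-resolution-level checks use 0.1 mm; recovery tolerances
  at default resolution are 0.5 mm and 1 degree.
* Problem sizes used in the shipped validation: cranium at icosphere
  subdivision 4 (2562 vertices) with ~1.2 mm auricle meshing (~6000
  vertices per head), 20-head cohorts for recovery and method-contrast
  checks, 8-10 repeats for precision estimation, 2000-4000 subjects for
  threshold calibration. These sizes put every full-pipeline check within
  a few minutes on one CPU while keeping recovery tolerances comfortably
  resolved.

## Known limitations

* The auricle model is a shell, not a folded pinna; substructure
  morphometry (helix, antihelix, lobule) is out of scope.
* The mastoid auto-annulus assumes the region behind the ear is reasonably
  planar; on strongly curved or poorly segmented surfaces, explicit mastoid
  labels are the safer input.
* The anterior-direction rule (larger extent from the origin) presumes a
  face-side protrusion; for decapitated or heavily cropped scans use
  `anterior_override`.
* Manual-method emulation models placement noise only; it does not model
  systematic operator bias or landmark definition drift between observers.
* The reliability threshold inherits the usual reliable-change caveats:
  it tests each parameter marginally at 5% and the seven parameters are
  correlated through the shared frame.
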