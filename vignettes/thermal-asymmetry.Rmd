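---
title: "Thermal asymmetry analysis of facial infrared thermograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermal asymmetry analysis of facial infrared thermograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irtasym)
```

## The problem and the model

A healthy face is thermally near-symmetric: the difference between
corresponding left and right regions of a facial thermogram is on the
order of 0.2 °C. Focal pathology in the orofacial/maxillofacial region —
a tumor in particular — perturbs local perfusion and typically appears
as a unilateral warm zone. `irtasym` turns that observation into an
automated screen. The pipeline is:

1. **Edge detection.** Prewitt 3×3 gradient convolution of the
   temperature grid; pixels whose gradient magnitude reaches a fraction
   (default 0.2) of the region-of-interest maximum are edge pixels. The
   skin/background contrast (~11 °C between a 33 °C face and a 22 °C
   room) makes this boundary unambiguous.
2. **Symmetry axis.** The convex hull of the edge points describes the
   external face contour; the major axis of the ellipse fitted to the
   hull vertices by direct constrained least squares is taken as the
   facial symmetry axis. The open-mouth cavity gets the same treatment
   after restricting edge detection to the warm-cavity ROI (pixels at or
   above 34.5 °C).
3. **Field splitting.** Every pixel strictly inside the hull is assigned
   to one side of the axis by the sign of a 2-D cross product; on-axis
   pixels are discarded so the sides stay disjoint.
4. **Features.** Eight side-difference statistics per patient: for each
   view (face f, mouth m) the absolute difference of side means
   (ΔT_f, ΔT_m), of side maxima (ΔT_fmax, ΔT_mmax), of side mean
   absolute deviations (ΔDEV_f, ΔDEV_m), and the count of warmer-side
   pixels exceeding the cooler side's maximum by more than 0.4 °C
   (n_f, n_m). The 0.4 °C value is the conventional boundary between
   normal bilateral variation and abnormality; asymmetry of exactly
   0.4 °C still counts as normal, which `is_asymmetric()` implements as
   a strict inequality.
5. **Classification.** A 1-nearest-neighbor classifier on the
   eight-dimensional feature vector (Euclidean distance), evaluated by
   repeatedly drawing 12 training members per class and testing on the
   rest, 12 times, pooling the confusion counts, and summarizing with
   sensitivity, specificity, accuracy and a ROC/AUC built from the
   signed nearest-neighbor margin.

## Tunable parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `delta_t_threshold_c` | 0.4 | °C | asymmetry/abnormality boundary and exceedance margin of n_f, n_m |
| `edge_threshold_frac` | 0.2 | – | edge pixel cut as a fraction of the max gradient magnitude |
| `mouth_temp_floor_c` | 34.5 | °C | warm-cavity ROI floor for the open-mouth view |
| `n_estimates` | 5 | – | contour re-estimates averaged per feature vector |
| `jitter_px` | 1 | px | hull-vertex perturbation for re-estimates |
| `k_neighbors` | 1 | – | neighbors in the classifier (only 1 supported) |
| `standardize_features` | TRUE | – | z-score features with training statistics |
| `n_train_per_class`, `n_repeats` | 12, 12 | – | evaluation protocol |

Two of these deserve comment. The *relative* edge threshold makes the
edge map invariant to constant temperature offsets and to the overall
scaling of the gradient kernels, so only the shape of the boundary
matters. Feature standardization is on by default because the raw
features live on wildly different scales — a mouth exceedance count in
the tens versus mean differences of a few hundredths of a degree — and
an unstandardized Euclidean distance would be dominated by the count
features alone; a configuration flag restores raw distances.

## What the phantom generator emulates

No clinical thermograms can ship with the package, so validation runs on
synthetic phantoms with exact ground truth (`phantom_spec()`,
`make_face_phantom()`, `make_mouth_phantom()`, `make_cohort()`). A
phantom emulates the acquisition conditions of a standardized clinical
protocol: a 240×320 temperature grid, a controlled 22 °C background, a
warm elliptical face (33 °C at the center with a 1.5 °C quadratic
falloff to the rim, mirror-symmetric about a known, tiltable axis),
i.i.d. Gaussian sensor noise with sd 0.06 °C (the thermal sensitivity of
a clinical long-wave camera), and — in the open-mouth view — a smaller
interior ellipse at 35.5 °C elongated along the facial axis. Lesions are
isotropic Gaussian hot spots of configurable peak amplitude and radius
(read as twice the Gaussian sd), placed strictly on one side of the
axis; the class label is 1 exactly when a lesion is present.
`make_cohort()` additionally records the *group* label separately from
the lesion-derived truth label, so that null cohorts (both groups
lesion-free) can be built for negative controls.

The phantoms deliberately do **not** model hair, glasses, scars,
blushing, asymmetric adipose tissue, pose variation or non-elliptical
face outlines — all known confounders of clinical thermography. Passing
phantom tests therefore demonstrates that the geometry, feature and
classifier stages are implemented correctly and recover known ground
truth; it does not demonstrate clinical performance on real faces.

Default phantom parameters were fixed once, before any evaluation, at
values a thermographer would call typical (face semiaxes 90×65 px in a
240×320 frame, axis tilts within ±10°, cohort size 23 per class,
discrimination lesions of 1.0 °C peak and 8 px radius); the evaluation
cohorts in `scripts/acceptance.R` and the test suite use exactly these
conditions.

## Numerical choices and degenerate inputs

- **Coordinates** are 1-based `(row, col)` with row 1 at the top and
  pixel centers at integer coordinates, the natural convention for R
  matrices.
- **Ellipse fitting** uses the direct constrained least-squares conic
  fit in its numerically stabilized block formulation, after centering
  and scaling the coordinates; the conic coefficient vector's arbitrary
  sign is normalized so the quadratic form is positive definite before
  the eigendecomposition that orders the axes. The fit is unique and
  non-iterative, so no initialization or convergence choices exist.
  Near-circular fits (axis ratio < 1.02) carry an `ambiguous_axis` flag
  because a circle has no preferred major axis; degenerate scatters
  (collinear points, non-elliptical conics) are errors.
- **Hull jitter.** The manual step of re-drawing a few contour points
  between repeated estimates of the same image is emulated by
  perturbing each hull vertex with an independent uniform offset in
  ±1 px, re-hulling, re-fitting and re-splitting; the five resulting
  vectors are averaged componentwise, which is why the count features
  can be fractional. Estimates that degenerate are discarded; only a
  full failure is an error.
- **Ties.** Pixels exactly on the axis are discarded (cross product
  within 1e-9), preserving side disjointness. Equal nearest-neighbor
  distances resolve to the lowest training-row index. Tied ROC scores
  are handled by sweeping distinct thresholds, making the trapezoidal
  AUC equal the tie-corrected Mann–Whitney statistic.
- **t-test.** The per-feature two-group comparison uses the Welch
  (unequal-variance) form: asymmetry-feature spreads differ between
  groups by up to an order of magnitude, which invalidates the pooled
  form.
- **Evaluation pooling.** Confusion counts and scores are pooled over
  the 12 repetitions rather than averaging per-repeat metrics: pooling
  keeps counts integral and yields one well-defined ROC.

## Design choices that were genuinely open

- **ROC for a discrete classifier.** A 1-NN label has no intrinsic
  score; the signed margin `d(nearest NT) − d(nearest T)` is used
  because its sign reproduces the 1-NN decision and its magnitude
  orders test cases by confidence.
- **Mouth-cavity isolation.** How the mouth region is separated from
  the rest of the face before hull computation is under-determined;
  since the open cavity is reliably the warmest area, a temperature
  floor (34.5 °C) defines the ROI and the face procedure is reused
  unchanged inside it.
- **Side labels are geometric**, not anatomical: all eight features are
  absolute differences, hence invariant to swapping sides, so no
  left/right registration is needed.
- **Exceedance counts** read the shared 0.4 °C threshold as the margin
  above the cooler side's maximum, applied to the warmer (larger-mean)
  side, with a strict inequality.

## Problem sizes used in the shipped studies

The acceptance script and the end-to-end tests run: a discrimination
cohort of 23 + 23 members at full 240×320 resolution (lesion 1.0 °C /
8 px), a null cohort of the same shape with lesion amplitude 0, and an
axis-recovery study of 100 noisy phantoms with tilts spanning ±15°.
Unit tests use 80×100 phantoms with proportionally scaled faces where
full frames would add nothing.

## Known limitations

- The 1-NN classifier is the only supported scheme (`k_neighbors` must
  be 1); voting or margin-based alternatives are out of scope.
- The phantom face is a perfect ellipse, so hull-based axis estimation
  is easier than on real jaw/hairline contours; expect larger axis
  errors on clinical images.
- Sensitivity/specificity on phantom cohorts reflect the chosen lesion
  amplitude and noise level, not clinical prevalence or difficulty.
- Emissivity and ambient-radiation corrections are assumed to have been
  applied by the camera before export; the package validates only a
  physical plausibility window (−20 to 250 °C).
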