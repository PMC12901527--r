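---
title: "Craniocaudal VAT profiles and age-independent single-slice volume estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Craniocaudal VAT profiles and age-independent single-slice volume estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vatslice)
```

## The problem

Visceral adipose tissue (VAT) — fat stored around the organs of the
abdominal and pelvic cavities — is a key driver of cardiometabolic risk,
and its volumetric quantification from whole-trunk Dixon MRI is the
reference method. Because whole-trunk acquisition and segmentation are
expensive, a common surrogate is the VAT cross-sectional area of a single
axial slice at a standard anatomical level (L3 is the textbook choice),
scaled to a volume estimate. How good that surrogate is depends on where
the slice is taken, and the best location is not universal: the
craniocaudal distribution of VAT differs between sexes, shifts with BMI,
and changes with age within every BMI stratum.

`vatslice` implements the full analysis chain behind this question:

1. **Profile extraction.** A binary VAT mask (axial slices, caudal to
   cranial) becomes a per-slice area sequence; dividing by the total
   gives each slice's percentage of total VAT.
2. **Anatomical standardization.** Profiles are indexed not by absolute
   position but by a 40-location grid: the vertebral-body centers L5-Th10
   and the discs between them (values read from the axial slice nearest
   each landmark), plus 26 equidistant points from the femoral heads (FH)
   to L5 (values obtained by linear interpolation of per-slice VAT
   amounts at the individual's own equidistant positions). Indexing by
   label removes the direct influence of body height: a tall and a short
   person are compared at "L3", not at "z = 310 mm".
3. **Stratification.** Participants are grouped by sex, five BMI groups
   (boundaries 18.5, 25, 30, 35, 40 kg/m²) and five age decades
   (20-29 ... 60+, with the few participants over 70 merged into the last
   group). An exclusion cascade (imaging artifacts, corrupted data,
   missing anthropometry, underweight, undersized subgroups) runs first.
4. **Age-independent reference slices.** Within each sex x BMI group, the
   grid location where the age-group mean profiles differ least — their
   intersection — is selected. Reading the slice there makes the
   estimate insensitive to age.
5. **Scaling factors and validation.** The factor
   `f = 1000 * mean(VAT volume) / mean(slice area at the reference location)`
   (pooled over the sex x BMI group) converts an area in cm² to liters
   via `V_hat = A * f / 1000`; equivalently `f` is the slice thickness
   divided by the group-mean per-slice VAT fraction — the reciprocal of
   the single-slice percentage. Validation reports Pearson's r and
   regression per group, mean signed errors, a relative error, and
   boxplot statistics of the errors.

The cohort data such an analysis was designed for are access-restricted,
so the package ships a synthetic-cohort generator that emulates the
inputs end to end; every stage is exercised and validated on data with
known ground truth.

## The synthetic cohort

`generate_participants()` draws sex, BMI group, BMI, height, age and
total VAT from a calibration table (`default_calibration()`) holding, per
sex x BMI group, the subgroup size and the mean/sd of every covariate of
the emulated population (11,036 participants, 5,681 men; men carry about
73 % more VAT than women in every BMI group). Within a group, BMI is
truncated normal on the group's interval; weight is derived from BMI and
height so the BMI identity holds exactly; age is drawn by discretizing
the group's Normal age distribution onto the five decade bins and then
uniformly within the bin (the table reports only means and sds, not a
joint distribution, so decade membership is matched only approximately —
a deliberate modeling choice); VAT is log-normal with moments matched to
the group mean/sd, since VAT is positive and right-skewed. Covariates
are drawn independently within a stratum: the source table carries no
age x BMI x VAT covariance, so any such structure would be invented.

`generate_geometry()` builds the spine: the FH-to-L5 distance is
Normal(12.9, 1.1) cm truncated to 9-17 cm (truncation avoids
non-physical geometries), vertebral spacings are typical lumbar/thoracic
values scaled linearly with body height and jittered a few percent, and
disc centers sit midway between vertebral centers.

### The profile model

The continuous VAT density (fraction of total VAT per cm) is a minimal
two-component family reproducing the qualitative shape of observed
profiles:

* a **pelvic plateau** — a logistic shoulder of height `pelvic_plateau`
  (fraction/cm) ending at the pelvic/abdominal boundary 3 cm below L5
  (`boundary_offset_cm`), shoulder width 1.2 cm;
* an **abdominal Gaussian** of height `abdominal_peak_height` centered at
  `abdominal_peak_location` (L3 for men in every BMI group; shifting
  L5/4 -> L3 with BMI in women), sd 5 cm in men and 4 cm in women;
* a small uniform **background** (0.002 fraction/cm) for the
  mediastinal/retroperitoneal fat present on every covered slice.

Defaults per sex x BMI group make the abdominal peak grow and the pelvic
plateau shrink as BMI increases. Coverage runs from the femoral heads to
5 cm above Th10 (the cardiac apex); slices are 0.3 cm thick. Slice
fractions are normalized over this coverage and scaled so that
`sum(area * thickness)` reproduces the participant's ground-truth volume
exactly.

### Planted age structure

The age effect is built so that the estimator's target — the
age-independent intersection — exists by construction and is known:

* A **redistribution direction** `h`: deep-pelvic shape minus the base
  profile, with younger decades weighted toward the deep pelvis
  (`age_slope_pelvic = -0.04` of total VAT per decade; the implied
  abdominal change has the opposite sign). The deep-pelvic shoulder ends
  `deep_fraction` (0.5, jittered ±0.08 per individual) of the way from
  FH to the boundary.
* A **broadening direction** `h2`: a wider abdominal Gaussian (ratio
  1.3) minus the base one, weighted by a quadratic age score
  (`age_curvature = 0.015`), representing growing dispersion of
  abdominal VAT toward the age extremes.

Both directions sum to zero over the slices (total VAT is conserved) and
are pinned to zero at the planted grid location by a sum-zero pair of
concentric Gaussian bumps centered there — a construction that is
well-conditioned for any location on the grid. Consequently every
age-group curve passes through the same standardized value at the
planted location *exactly*, including slice discretization. Because the
linear and quadratic age weights are linearly independent across the
five decades, no other location is exactly age-independent: the planted
crossing is unique and recoverable. The per-individual
`deep_fraction` jitter additionally prevents the incidental second zero
of `h` from aligning across a stratum. If a short-pelvis geometry would
drive any slice fraction negative, the age effect is scaled down for
that individual only — harmless for the crossing, which holds at any
magnitude.

Per-slice noise is additive Gaussian with sd proportional to the local
slice fraction, equal to `noise_sd` (default 0.012 fraction/cm, about
20 % relative) at the profile peak. Between-subject variability scales
with the amount of fat present — homoscedastic noise would be dominated
by clamping in the fat-free tail. With these defaults the synthetic
Pearson correlations between single-slice estimates and reference
volumes land in the high 0.7s to mid 0.9s per stratum, the order
reported for real cohorts.

`render_mask()` voxelizes a profile into a NIfTI phantom (1.4 x 1.4 x
3 mm): one filled ellipse per slice — per-slice area is the only
quantity downstream stages consume, so no organ anatomy is modeled —
with the voxel count matched to the requested area within half a voxel
(voxels are ranked once by elliptical radius and the closest
`round(area/voxel_area)` are filled), plus a spine label volume with a
2 x 2-voxel block per landmark. What the generator does *not* emulate:
Dixon signal formation, fat-water swap artifacts (only the flag),
segmentation errors, realistic organ shapes, or covariate dependence of
profile shape beyond the sex/BMI/age structure above. Tests passing on
synthetic data therefore validate the *pipeline's* correctness and the
estimator's statistical behavior under known structure — not the
segmentation model or the anatomical realism of real cohorts.

## Numerical and design choices

* **Landmark values use the nearest axial slice** (no sub-slice
  interpolation): profiles are matched to landmark slices, and at 3 mm
  slices the sub-slice correction is negligible there. Caudal values are
  linearly interpolated at the individual's 26 equidistant positions;
  interpolation operates on per-slice VAT amounts (areas and pixel
  counts differ by a constant, so the normalized result is identical).
* **Axial convention:** positions in mm from the most caudal acquired
  slice, 0-based slice indices, caudal -> cranial increasing.
* **Grid labels** use the cohort-level 0.5 cm step ("L5-2.5 cm") while
  evaluation uses each individual's own step (distance/25) — the grid is
  per-individual equidistant with cohort-level labels.
* **Spread metric:** the "smallest difference between all age groups" is
  implemented as the range (max - min) of the age-group means;
  `metric = "variance"` is available as the alternative reading.
* **Intersection search floor:** locations whose pooled mean percentage
  is below 10 % of the stratum maximum are excluded from the search
  (`min_pooled_frac`, settable to 0). In the fat-free cranial tail every
  age curve is trivially near zero, so an unrestricted argmin degenerates
  to whichever tail location happens to have the least sampling noise —
  meaningless for estimation, which needs a slice that carries VAT.
  Whether the original analysis restricted its search is unknown; this
  package restricts it and documents the switch.
* **Ties** in the spread are broken toward the location with the largest
  pooled (size-weighted) mean percentage.
* **Factor averaging:** ratio of means (`mean(V)/mean(A)`), reading "the
  reciprocal of the single-slice percentage from the cohort data" as a
  group-level quantity; `mean_of_ratios` is available for sensitivity
  analyses.
* **Relative mean absolute error:** `|mean signed error| / mean
  reference * 100`. Applied to the reference cohort's rounded
  headline inputs (-0.07 l against 4.8 l; -0.06 l against 2.5 l) this
  definition reproduces the reported 1.44 % (men) and 2.37 % (women)
  within rounding, whereas `mean(|error|)/mean(V)` would be an order of
  magnitude larger given the error sds; the alternative remains
  available behind `method = "mean_of_abs"`.
* **Age 60 exactly** goes to group v (the printed group labels leave it
  formally unassigned); everyone over 70 is merged into v.
* **Exclusions** run in the order: fat-water swap, corrupted, missing
  anthropometry, underweight, undersized strata — matching the reported
  per-criterion counts; totals are conserved
  (`n_in - n_out = sum(counts)`).
* **Regression orientation:** reference on estimate is primary; the
  reverse is reported alongside (the orientation is not standardized in
  the field).
* **Boxplot outliers** use the 1.5 x IQR convention.
* **Degenerate inputs:** empty masks give a valid zero-volume profile
  with NA fractions; zero variance makes correlations NA with a flag;
  constant distances make the KDE error out (zero bandwidth); a single
  age group makes the intersection undefined (error).
* **Height independence** holds for *locations* exactly and for *values*
  up to the trunk-coverage scale: per-slice percentages carry an
  inverse-length factor (a longer trunk spreads 100 % over more slices),
  so profiles of geometrically scaled participants agree after
  rescaling by the covered length. The tests assert exactly that.

## Validation design and problem sizes

The test suite builds all of its data in code. Sizes were chosen so the
statistical assertions have comfortable margins at desk scale: cohort
composition and geometry calibration use 10,000 draws (Monte-Carlo
standard errors ~0.01 cm on the mean FH-L5 distance); noise-free
planted-structure recovery uses 1,000 participants per age group in a
stratum and recovers the planted location exactly in all ten sex x BMI
strata; recovery under calibrated noise uses 2,000 per age group and is
asserted to within one grid step. The estimator-exactness check holds
anatomy fixed (one geometry, equal heights, no noise, no shape jitter)
so that voxelization is the only error source — under full study
conditions the per-individual slice fraction at the reference location
varies a few percent across individuals by design, which is exactly the
scatter the correlation analysis measures. The exclusion worked example
runs at the full 11,191.

At the emulated cohort's own (unbalanced) stratum sizes — e.g. only a
few dozen participants in the youngest age cell of many BMI groups —
the selected reference locations recover the planted ones in the
well-populated strata and scatter within the flat pelvic plateau in the
sparse ones, where the spread statistic is dominated by the smallest
cell's sampling noise. The estimation quality is essentially unaffected
(any plateau slice carries a stable share of total VAT), which is
precisely why single-slice estimation tolerates moderate uncertainty in
the reference location: mean signed errors stay at zero by construction
of the ratio-of-means factor, and the error sd is set by between-subject
profile variability.

## Limitations

The generator's profile family is a three-shape caricature: real
profiles have multimodal detail, left-right asymmetry is invisible in
per-slice areas, and the age structure of real cohorts is not literally
a two-direction perturbation. Factors derived from synthetic cohorts are
internally consistent but not transferable to real data; the reference
cohort's factor vocabulary (e.g. men group I at L5/4 with factor 103) is
used as label conventions and arithmetic cross-checks only. The pipeline
consumes masks and landmarks — segmentation itself, vertebra
identification, and fat-water swap correction are out of scope.
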