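---
title: "Nulla-anchored choroidal morphometry: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nulla-anchored choroidal morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(choroidref)
```

This vignette is the package's own account of what it computes and why the
defaults are what they are. It covers the measurement model, the synthetic
cohort generator that stands in for animal data, the statistical layer, and
the numerical conventions that an implementer has to fix but an anatomical
description leaves open.

## The measurement model

The pipeline operates on *segmented* OCT volumes: per-pixel compartment
labels (vitreous, retina, choroid, background/sclera) for each B-scan of a
macular volume scan. Segmentation itself — in the hybrid design, a CNN — is
out of scope here; masks are the input contract.

**Boundary extraction.** In every A-scan column the compartments must form
one contiguous run each, in the fixed vertical order vitreous → retina →
choroid → background. The ILM is the vitreous/retina border, the inner
choroid boundary sits just above the choriocapillaris (retina/choroid
border), and the outer boundary is the choroid–sclera junction. Boundaries
are stored as 0-based axial pixel depths under a half-open convention:
`choroid_outer − choroid_inner` is exactly the column's choroid pixel count,
so no pixel is counted twice and none is lost. Columns that lack retina or
choroid, or contain split runs, are hard errors rather than silently skipped
— every landmark of the ±2000 µm grid must be defined, so a gap anywhere in
the measured span invalidates the eye rather than one number.

**Nulla detection.** The raw ILM profile extracted from masks is quantized
and jittery, so it is smoothed with a two-dimensional moving average over
the (B-scan × lateral pixel) grid before taking the global depth maximum,
the *nulla*. The window shrinks at grid borders (the mean is taken over the
window ∩ grid), which avoids inventing padded values; a `(1, 1)` window is
the identity. The default window is **3 B-scans × 31 lateral pixels**
(≈ 0.32 mm laterally at the default geometry): wide lateral smoothing
suppresses segmentation jitter along the densely sampled axis, while the
B-scan span covers only the immediate neighbors because slices are a coarse
221 µm apart. Smoothing within single B-scans only is available as
`window = c(1, w)`. Exactly tied deepest points — typical on integer-valued
raw surfaces and on flat pit bottoms — are resolved to their unweighted
center of mass; the tie tolerance is 10⁻⁹ axial pixels, i.e. exact-equality
semantics made robust to floating-point accumulation. Fractional nulla
coordinates are kept, not rounded; downstream offsets are measured from the
fractional lateral position via interpolation. "Deepest" means *maximum*
depth under the row-1-at-top image convention — stated explicitly because a
sign error here silently measures the shallowest point.

**The landmark grid.** Measurements are confined to the single B-scan
containing the nulla (nearest integer B-scan for a fractional coordinate,
half-integer ties resolved toward the volume center); no cross-B-scan
averaging is attempted, since at 221 µm spacing interpolating between
slices would manufacture data. T5 is the axial choroidal thickness at the
nulla; T4..T1 step nasally and T6..T9 temporally in 500 µm increments, so
the axis is ordered nasal → temporal with T5 central and areas A1..A8
left-to-right in that frame (A4 and A5 flank the nulla). Thickness is
strictly axial — along image columns — not along the local normal to the
RPE; the rectangular grid is a deliberate simplification and a known
limitation of this family of protocols. Thickness at arbitrary lateral
positions linearly interpolates the boundary depths between pixel nodes;
areas integrate that interpolated thickness with the trapezoid rule over
all pixel nodes in the interval plus fractional end segments, which is
*exact* for the piecewise-linear interpolant and keeps areas consistent
with thicknesses to sub-pixel precision (an alternative — counting mask
pixels — quantizes areas to whole pixels and disagrees with interpolated
thickness at the edges). The umbo sub-analysis takes thicknesses at
±100 µm and the areas of the two 100 µm half-spans adjoining the nulla.

The measured band is the segmented choroid from its inner to its outer
boundary. Descriptions of this measurement sometimes reference the RPE as
the projection target; the RPE line proper is not part of the segmentation
contract here, and the inner choroid boundary (just above the
choriocapillaris) is the reproducible surrogate this package measures from.

**Laterality.** Nasal/temporal labeling depends on eye side: under the
default `nasal_positive_od` convention, nasal is +x for right eyes (OD) and
−x for left eyes (OS). Image orientation is not recoverable from the pixels
alone, so the convention is explicit and testable: an OS volume that is the
lateral mirror of an OD volume yields identical T/A values.

## The synthetic cohort generator

The generator emulates the scan protocol the pipeline targets — 25 B-scans
of 512 × 496 px covering 5.3 mm × 1.9 mm at 221 µm spacing — and a cohort
structure with sex, geographic origin and eye side as covariates, plus a
manufacturer-style integer quality score used by the inclusion filter
(≥ 25).

Design choices, each made once:

* **Pit shape**: an inverted-Gaussian ILM pit (default depth 120 µm, lateral
  σ 350 µm, across-B-scan σ 500 µm over a 550 µm base depth). Anatomy does
  not prescribe a functional form; a Gaussian gives a unique smooth deepest
  point, and an optional flattened bottom (`plateau_halfwidth_um`) produces
  exact ties for exercising the center-of-mass rule.
* **Choroid profile**: piecewise linear through the nine landmark targets,
  constant beyond ±2000 µm — the simplest profile whose 21 landmark truths
  are exact by construction (areas are trapezoids, umbo values linear
  interpolations).
* **Retina**: constant thickness (190 µm). Foveal retinal thinning is real
  but irrelevant to choroidal landmarks, and modeling it would only move
  both choroid boundaries by the same ILM-anchored offset.
* **Population**: per-landmark thickness ~ Normal(mean, sd), with 70% of the
  variance carried by a shared per-eye effect — this reproduces the strong
  adjacent-landmark correlations (~0.7) seen in real choroids while keeping
  each landmark's marginal mean and sd exact. The `paper_cohort` preset sets
  every landmark mean to 192.83 µm with sd 15.04 µm (CV 7.8%), female
  fraction 0.393, origins Mauritius/Asia/unknown at 0.532/0.425/0.043, and
  near-balanced eye sides. Sex and origin have zero effect on thickness by
  default, so the ANOVA layer can be calibrated under a true null.
* **Quality score**: integers on [15, 40], a discretized normal peaking at
  31, so roughly 7% of eyes fall below the ≥ 25 inclusion threshold and the
  filter is actually exercised; the manufacturer's metric is proprietary and
  not modeled.
* **Noise**: multiplicative log-normal speckle on the intensity image only.
  Masks stay noise-free because segmentation is out of scope — which is
  also the generator's main idealization (below).
* **Rasterization**: boundary depths round to the nearest axial pixel, so
  rasterized boundaries sit within half a pixel of the parametric truth and
  measured thicknesses within one pixel (≈ 3.8 µm at default geometry).
* **OS eyes** are generated as lateral mirror images of the OD layout, so
  the laterality convention is testable end to end.

All population randomness is drawn before any rasterization, so the truth
table for a given (model, seed) is bit-identical whether or not masks are
rendered, and `simulate_and_measure()` can stream eyes one at a time
(a full 374-eye volume stack would not fit in memory at once).

What passing the parameter-recovery tests shows — and does not. Recovery of
the configured mean and CV through the full pipeline verifies the geometry,
rounding, smoothing, anchoring and integration chain at realistic scales.
It does not validate performance on real segmentations: real masks carry
CNN errors that are spatially correlated and anatomy-dependent, choroid
texture, vessel shadows and motion artifacts, none of which are simulated.
The generator validates the deterministic stage, not the hybrid system.

## The statistics layer

Subgroup summaries (mean, sample sd, min, max) are computed per sex ×
origin × eye side; the CV uses the *sample* (n−1) standard deviation —
dispersion definitions rarely state the denominator, so it is fixed here
once. Left and right eyes are never pooled into one model: fellow eyes of
one animal are correlated, and rather than model that dependence the two
sides are analyzed as separate tables throughout.

Each thickness coefficient is tested with a two-way ANOVA (sex + origin,
no interaction) using **type-II sums of squares**: each factor's SS is the
residual-SS reduction from adding it to the model already containing the
other, which in unbalanced cohorts (and these cohorts are unbalanced) makes
the result invariant to factor order. The implementation delegates the fit
to `stats::lm` + `car::Anova(type = 2)`; the test suite checks it against
an explicit nested least-squares oracle to 10⁻⁸. Rows of unknown origin are
retained in summaries and correlations but excluded from the ANOVA, where
an inestimable level would otherwise contaminate the design. With nine
tests per eye side, p-values are banded against Bonferroni-corrected
thresholds 0.01/9 ≈ 0.00111 and 0.05/9 ≈ 0.00556 ("significant" / "weakly
significant" / "not significant").

Boxplot descriptors use linear interpolation between order statistics
(`quantile` type 7) and 1.5 × IQR whiskers (whiskers end at the last datum
inside the fences); the quantile rule is fixed so figures and the
`boxplot_spec()` numbers are stable across environments.

## Numerical conventions and degenerate inputs

* 1-based B-scan and lateral pixel indices in the R API; lateral pixel *i*
  sits at (i−1)·(width_µm/width_px); boundary depths are 0-based axial pixel
  counts from the image top.
* Landmarks outside the scanned lateral extent, inverted area intervals,
  even or oversized smoothing windows, masks with unknown labels or split
  compartment runs, and profiles overflowing the scan depth are all
  explicit errors naming the offending eye/B-scan/column — never silent
  repairs.
* Zero-variance variables yield `NA` correlations with a warning, not 0.
* A single-observation summary group reports sd 0 (no dispersion), min =
  mean = max.
* Cohort-level per-eye speckle seeds derive from the cohort seed, so any
  subset of eyes is reproducible without regenerating the rest.

## Problem sizes used in the checks

The test suite runs the geometry-sensitive checks on a reduced raster
(128 × 200 px, 3–7 B-scans) that keeps the physical extents of the default
protocol, so all ±2000 µm landmarks remain in range while each eye costs
milliseconds; pipeline parameter recovery runs at the full 512 × 496 × 25
raster with a 50-eye cohort and Monte-Carlo (3 standard error) tolerances;
ANOVA null calibration uses 1000 replicate 100-eye truth tables. The
acceptance script runs the full-size cohort (374 eyes, full raster) and
takes a few minutes on one CPU.

## Known limitations

* Thickness is axial, not normal to the RPE; on tilted scans this
  overestimates true perpendicular thickness by 1/cos(tilt).
* No ocular magnification correction (axial length is not an input), no
  diurnal-variation modeling, no motion/registration correction.
* The nulla's across-B-scan localization is limited by the 221 µm slice
  spacing; the centroid-of-ties rule does not interpolate between B-scans.
* The generator does not simulate segmentation failure modes, choroidal
  vasculature texture, or pathology; conclusions from synthetic recovery
  transfer to real data only insofar as the masks are accurate.
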