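---
title: "Quantifying meisosome morphology and cuticle mechanics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying meisosome morphology and cuticle mechanics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meisoquant)
```

## What the package measures

Meisosomes are stacked, regularly spaced folds of the apical plasma membrane
of the *C. elegans* epidermis, lying directly beneath the collagen-rich
cuticle. In fluorescence micrographs of the V-ATPase reporter VHA-5::GFP they
appear as a reticulated pattern of irregular bright objects on an
autofluorescent background. When furrow-collagen genes are inactivated this
pattern fragments: objects become smaller (lower mean area and Feret's
diameter) and more numerous per unit area (higher density), and the cuticle
loses stiffness. `meisoquant` implements the measurement machinery behind
those statements:

1. an automatic, background-normalised blob segmentation with per-object
   morphometrics (area, Feret's diameter, centroid) and per-image summaries
   (mean area, mean Feret, object density);
2. object-based two-channel co-localisation by centroid containment;
3. AFM force-curve processing (baseline zeroing, contact-point detection,
   cantilever-bending subtraction) and Hertz spherical-indenter fits of
   Young's modulus;
4. the two-group test-selection rule used for all pairwise comparisons;
5. a synthetic-data module that generates ground-truth-labelled stand-ins
   for every input, so each stage is validated by parameter recovery rather
   than by eye.

## The segmentation procedure

`run_pipeline()` composes five stages, in order:

1. **Bright-outlier removal** (`remove_bright_outliers()`, radius 30 px,
   threshold 30): each pixel is compared with the median of the disc of
   radius 30 centred on it and replaced by that median only when it exceeds
   it by more than 30 intensity units. Bright organelles are much smaller
   than the disc, so they are flattened to the local background level; the
   output is the *background image*. The filter is exact: integer-valued
   images (the 8/16-bit case) go through a sliding two-level histogram,
   anything else through a direct per-pixel median, and both agree with a
   brute-force oracle in the tests.
2. **Foreground isolation** (`foreground_image()`): `max(raw - background,
   0)` pixelwise.
3. **Gaussian blur** (`gaussian_smooth()`, sigma 1 px): separable
   convolution, reflective boundary, kernel truncated at 3 sigma and
   renormalised so total intensity is conserved away from the border.
4. **Threshold** (`compute_threshold()`): mean intensity of the background
   image over the ROI, times a constant `background_coefficient`. Averaging
   over the ROI only mirrors analyses restricted to manually drawn regions;
   normalising by the background level makes the segmentation robust to
   expression-level differences between animals. A zero background mean is
   flagged as degenerate rather than silently producing threshold 0.
5. **Labelling and filtering** (`segment_blobs()`): pixels above threshold
   inside the ROI, 8-connected components, objects with area *strictly*
   below `min_area_um2 = 0.15` removed (equality survives). Objects touching
   the ROI border are kept by default, since density is the headline metric
   and border exclusion would bias counts; a flag reverses this.

Parameter notes:

* `background_coefficient` is the one free parameter of the method; there is
  no published value. The package default is **2.0**, chosen so that, for an
  object whose plateau amplitude is twice the threshold, the half-maximum
  contour of the blurred object falls on its true boundary; area is then
  unbiased to first order. The coefficient is logged in every result object
  and output file.
* Because the outlier threshold (30) is an absolute intensity, the pipeline
  is **not invariant to intensity rescaling**; inputs are expected on their
  native 8/16-bit count scale.
* Feret's diameter (`feret_diameter()`) is the maximum caliper distance over
  the convex hull of the pixel *corner* points. The corner (outline)
  convention gives a single pixel of side *s* a diameter of *s*·sqrt(2)
  rather than 0 and matches the usual practice of measuring the longest axis
  on object outlines. An independent all-pairs brute force checks it exactly
  in the tests.
* Coordinates are 0-based pixel indices; a pixel centre sits at
  `(index + 0.5) * pixel_size_um`, corners on the integer grid. Density is
  reported per µm² of ROI area, together with `n_objects` and
  `roi_area_um2`, so any other normalisation is recoverable.
* With no objects, the per-image means are returned as `NA` with
  `defined = FALSE`, never as silent `NaN`.

## The synthetic scenes

`generate_reticulated_image()` plants `n_objects` rotated ellipses with
uniformly drawn area (default 0.3–1.5 µm², inside the observed size range of
these organelles), aspect ratio (1–6) and orientation, placed without
overlap (circumscribed-circle clearance plus 1 µm separation) in a
40 × 25 µm field — 1000 µm², about the scale of a lateral-epidermis ROI —
sampled at 0.05 µm/px, typical of Airyscan-processed confocal data.
Intensities are integer counts: background mean 30, object plateau 150,
additive Gaussian noise of sd 6 clipped at zero. These values are synthetic
choices (no SNR statistics are available for the original acquisitions),
calibrated once so that the *default* segmentation parameters sit in the
regime the procedure assumes: the threshold (background mean 30 × 2 = 60) is
half the foreground amplitude (120), ten noise sd away from the background,
and far below the object plateau.

The ground truth records the **rasterised** geometry — area as pixel count ×
pixel-size², Feret by the same corner convention as the measurement path but
recomputed independently in the tests — so recovery statements are about the
pipeline, not about rasterisation error.

`fragment_scene()` emulates the fragmented mutant phenotype by cutting every
planted object into `k` slabs perpendicular to its principal axis and
erasing all pixels within `gap_um` of a slab boundary along that axis.
Equal-extent slabs (not equal pixel counts) are used because they remain
non-empty for convex objects down to very small sizes. The default gap of
0.15 µm is the smallest separation that both disconnects pieces on the pixel
grid (it exceeds one pixel diagonal, 0.071 µm) and survives the sigma-1
blur: at 3 px the summed tails of the two blurred edges stay well below the
half-maximum threshold, so pieces do not re-merge. Pieces smaller than the
0.15 µm² area filter are *intended* to be lost by the measurement pipeline —
exactly as real sub-resolution fragments would be — which is why measured
density increases by roughly +100% rather than the bookkeeping +200% when
`k = 3`; the direction and the >25% magnitude bound are what the fragmented
phenotype asserts. A hard minimum piece size can be requested
(`min_piece_area_um2`), in which case infeasible objects raise an error
naming the object rather than being silently dropped.

What the generator does **not** emulate: true reticulation (objects are
convex, not branched), Poisson photon statistics (the procedure is
threshold-based and insensitive to the noise family at these SNRs), uneven
illumination, and out-of-focus haze. Passing recovery tests therefore
demonstrate correctness of the measurement chain under the stated imaging
model, not segmentation performance on arbitrary real micrographs.

## Co-localisation

`centroid_in_mask_pct()` computes, per image, the percentage of channel-A
objects whose centroid lies on a labelled pixel of channel B, and
symmetrically. The centroid is the unweighted mean of pixel indices rounded
to the nearest pixel; membership is mask membership, so a centroid inside
B's convex hull but off its mask is a miss, and an object of a non-convex
channel is never tested against itself. Zero-object channels give a flagged
`NA`, not 0. `coloc_summary()` averages per-image percentages unweighted
across images (one image per animal, n = 10 by convention).
`generate_coloc_pair()` plants `round(f·n_A)` A-objects concentric with
distinct B-objects and the rest decisively clear of every B-object, so the
per-image value equals the planted fraction exactly and study-level code
paths can be asserted without tolerance.

## AFM force curves and the Hertz fit

The forward model (`generate_force_curve()`) mirrors the acquisition
geometry: a 10 µm borosilicate bead (R = 5 µm) on a 7.5 N/m tipless
cantilever driven at constant piezo speed to roughly 800 nm indentation at a
force near the 450 nN setpoint. For piezo height z past the contact point
z₀, the indentation solves the self-consistency
delta = (z − z₀) − F(delta)/k (cantilever bending subtracted), by
fixed-point iteration to 10⁻⁶ nm; the force is the spherical Hertz law

F = (4/3) · E/(1 − nu²) · sqrt(R) · delta^(3/2)

with nu = 0.5 (incompressible tissue; no published value, configurable) —
in package units, F in nN for E in Pa and lengths in nm. Processing
(`process_force_curve()`) runs:

1. `zero_baseline()` — straight line fitted to the far 30% of the approach
   and subtracted, removing offset and drift exactly;
2. `find_contact_point()` — first sample whose force exceeds 3× the
   baseline noise sd and stays above it for 5 consecutive samples; the
   reported z₀ is the last sub-threshold height, within one sample spacing
   of truth on noiseless curves;
3. `to_indentation()` — delta = (z − z₀) − F/k past contact; slightly
   negative indentations produced by noise at contact are dropped;
4. `fit_hertz_sphere()` — linear least squares of F on delta^(3/2) over a
   fit window of 10–90% of maximum indentation, with the contact point
   co-fitted: the amplitude is profiled in closed form and a 1-D search
   moves the contact offset within −40%…+30% of the maximum indentation.
   The wide bracket matters: on noisy curves the 3-sigma detector
   necessarily fires *late* (at ~27 nN for 9 nN noise, i.e. ~130 nm past
   true contact at these moduli), and the co-fit recovers that bias. The
   modulus estimate is order-invariant and linear in the force scale;
   degenerate input (e.g. all-zero force) yields a flagged non-converged
   fit, never a silent number.

Self-consistency across the chain, checked in the tests: noiseless recovery
of E to better than 0.1% (machine precision in practice) with residuals
below 10⁻⁶ of the maximum force, and a median error within 10% over 50
curves at 2%-of-setpoint noise. Retract segments, adhesion, conical tips
and instrument calibration are out of scope.

## Two-group comparisons

`choose_test()` screens each group with Shapiro–Wilk and the pair with the
two-sided F-ratio (Fisher) variance test, all at alpha = 0.05 (the
screening level is not published; 0.05 is the conventional choice). The
unpaired **Student** t-test — equal-variance form, since homogeneity was
just screened — is used iff all three p-values exceed alpha; otherwise the
Mann–Whitney rank-sum test (normal approximation with continuity
correction, so ties from discrete readouts are handled). The decision is a
pure function of the three p-values, exposed as `decision_from_pvalues()`
and property-tested against its one-line restatement. A constant sample
fails the normality screen by convention (Shapiro–Wilk is undefined on it).
`compare_groups()` reports the statistic, the two-sided p-value and the
star tier (**** p<0.0001, *** p<0.001, ** p<0.01, * p<0.05). The tests
document that the *combined* select-then-test procedure holds its type-I
error within [0.035, 0.065] at n = 20/group under a Gaussian null over
10,000 replicates — a property of the rule, not a claim from the original
study.

## Problem sizes and reproducibility

The shipped studies use 40 objects per 1000 µm² scene (10 images per
condition in the full study), 100 small scenes for the Feret oracle sweep,
601-sample force curves (5 nm spacing, 50 noisy replicates), and 10,000
null replicates for the type-I calibration; these sizes make every result
reproducible on a laptop in seconds to a couple of minutes while keeping
the Monte-Carlo error far below the asserted tolerances. Every stochastic
entry point takes an explicit seed; per-image and per-curve seeds are
derived deterministically from a master seed (`study_config()`), and
`run_study()` reruns byte-identically, writing the resolved configuration
next to its outputs.

## Known limitations

* The background coefficient is a declared configuration value, not a
  recovered constant; real datasets need it calibrated against a reference
  annotation.
* Segmentation is strictly 2D, single-channel, threshold-based; no
  time-lapse, spectral unmixing or learned models.
* The contact-point detector and fit window are standard but necessarily
  substitutes for an instrument vendor's unpublished algorithm; they are
  validated by self-consistency on the forward model, not against
  instrument output.
* The density readout treats the full ROI as observable; occlusion or
  vignetting in real images would bias it.
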