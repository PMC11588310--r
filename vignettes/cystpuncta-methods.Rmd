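---
title: "Quantifying autophagosome puncta and PLVAC co-occurrence in 3D cyst volumes"
author: "cystpuncta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying autophagosome puncta and PLVAC co-occurrence in 3D cyst volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The measurement problem

Chronic-stage *Toxoplasma gondii* lives inside tissue cysts packed with
slow-growing bradyzoites. Autophagy in these parasites can be followed live
with three fluorescent markers: TgATG9 (mNeonGreen, 488 nm), the
autophagosome membrane marker TgATG8 (tdTomato, 561 nm), and TgFYVE
(HaloTag, 640 nm), which labels the plant-like vacuolar compartment (PLVAC),
the parasite's lysosome-equivalent. Lattice light sheet microscopy images a
whole cyst volume every 20 s for 5 min with low phototoxicity, at the price
of an obliquely sheared acquisition geometry and, because tdTomato's
emission tail reaches into the 488-nm detection band, spectral bleed-through
into the TgATG9 channel.

The quantity of interest is object-based: per cyst, what fraction of the
puncta detected in one channel co-occurs with objects of another channel?
Four ordered ratios are computed — ATG9 against ATG8, ATG8 against ATG9,
and each autophagosome marker against FYVE — by counting query puncta whose
voxel volume overlaps the target channel by more than 90% and dividing by
the total number of query puncta in the cyst. Mean object volumes per
channel complete the per-cyst readout. Conditional depletion of TgATG9
(auxin-inducible degron) should reduce ATG9 puncta, shrink autophagic
objects, and lower the flux of autophagosomes into the PLVAC — i.e. lower
the FYVE co-occurrence ratios.

`cystpuncta` implements this pipeline as open, tested code, together with a
synthetic volume generator that provides exact ground truth for every stage.

## The processing model, stage by stage

### Deskewing

The detection objective sits at 60° to the coverslip, so Z planes are
laterally offset. `deskew_volume()` shears each Z slice along Y by
`z * dz * cos(angle) / dy` voxels. The default mode rounds the shift to the
nearest voxel: intensity is moved, never rescaled, so the total intensity is
conserved exactly — a property the tests assert bit-for-bit. An
interpolating mode exists for users who prefer smooth output over exact
conservation. Deconvolution is deliberately not implemented; the pipeline
accepts deconvolved or raw volumes identically.

### Background and bleed-through correction

The background of the contaminated 488-nm channel is estimated from control
acquisitions of strains that lack mNeonGreen. The control channel is
particle-enhanced and segmented *exactly like experimental data*: every
segment found in a control is, by construction, an artifact — shot noise,
autofluorescence, or a bleed-through ghost of a tdTomato punctum. The mean
raw intensity over all retained control-segment voxels becomes the
timepoint's scalar background, which `subtract_background()` removes
voxelwise with a clamp at zero (detection assumes non-negative
intensities). Because the averaged voxels sit near ghost peaks, this
estimate deliberately exceeds the uniform background level; that is what
makes the residual ghost amplitude fall below the detection threshold. The
background-estimation pass uses a tighter `growth_fraction` (0.6) and a
smaller volume filter (0.05 µm³) than the analysis pass, so the averaged
voxels concentrate at ghost cores; both choices are exposed as parameters.
If a timepoint yields no control segments, the estimator falls back to the
mean intensity of the cyst region (flagged in the provenance table).

### Particle enhancement and blob segmentation

The commercial operators used in the original analysis are proprietary and
unparameterized, so the package defines open equivalents with testable
semantics:

* `enhance_particles()` is a spacing-aware center-surround (difference of
  Gaussians) band-pass: for a blob diameter `D` (default 0.8 µm), the inner
  Gaussian has σ = D/4 and the surround σ = D/2, both specified in µm and
  converted per axis, so anisotropic voxels are handled correctly. A
  constant image gives exactly zero response (border kernels are
  renormalized), and a linear ramp is suppressed in the interior — both are
  unit tests.
* `segment_blobs()` finds 26-neighborhood local maxima above a threshold,
  suppresses seeds closer than `min_separation` (0.5 µm; stronger response
  wins), and grows each seed into the 6-connected region with response at
  least `growth_fraction` (0.3) of the seed's own peak. Voxels claimed by
  several seeds go to the physically nearer peak, exact ties to the lower
  seed id. 6-connectivity was chosen as the conservative option for
  separating adjacent puncta on anisotropic grids.

The default threshold is *relative*: 8 times the MAD of the enhanced
response over the region under consideration, which makes detection
intensity-scale equivariant (multiplying the volume by any k > 0 leaves the
segment voxel sets unchanged — a property test). One subtlety matters in
production use: after clamped background subtraction, a channel with little
true signal is mostly censored at zero and the MAD of its own response
collapses, which would make the threshold meaningless exactly where false
positives are most harmful. The pipeline therefore computes the robust
scale on the enhanced *uncorrected* acquisition (`scale_reference` /
`scale_stack` arguments); the corrected volume is still what is thresholded
and segmented.

### Cyst segmentation

The original study used a machine-learning segmenter whose training data
are not published. Downstream statistics only need a per-cyst restriction,
not a particular segmentation style, so the package substitutes an
intensity-based segmenter: channels are summed, smoothed at 0.5 µm,
thresholded by a global-histogram criterion, the largest 6-connected
component kept, holes filled, and the mask closed morphologically. The
threshold is Otsu's split on the tail-clipped histogram, recentred a fixed
fraction (0.25) of the way from the background-class median to the
foreground-class median: the foreground class mixes the diffuse cyst fill
with much brighter organelles, and the recentring places the cut near the
half-height of the diffuse rim, which is what makes the mask meet a Dice
overlap of at least 0.9 against the generator's ground-truth ellipsoid.

### Volume filter, overlap, ratios

Pipelines 3–4 are exact set arithmetic and are tested against a brute-force
voxel-enumeration oracle:

* `filter_by_volume()` eliminates segments strictly smaller than 0.2 µm³.
  The default voxel spacing (0.2 × 0.1 × 0.1 µm) makes the voxel volume
  exactly 0.002 µm³, so the threshold corresponds to exactly 100 voxels: a
  99-voxel segment is removed, a 100-voxel segment retained.
* `overlap_fraction()` measures the fraction of the *query* punctum's
  voxels inside the union of the target channel's segments. The overlap
  direction is a genuine ambiguity; query-relative was adopted because the
  PLVAC is far larger than a punctum, so ">90%" is only attainable measured
  against the query. The alternative ("smaller of the two") is exposed as a
  configuration switch but is not the default.
* `cooccurrence_ratios()` counts query puncta with overlap strictly above
  0.9, once each regardless of how many target segments they touch, pools
  segments across the 5-min series (overlap is evaluated within each
  timepoint; counts are summed), and divides by the total query count.
  Zero-denominator ratios are reported as `NA`, never as zero: under strong
  knockdown "no ATG9 puncta" is an absence of measurement, not a measured
  co-occurrence of zero.

### Replicate aggregation and testing

`aggregate_replicates()` computes replicate means per condition (ignoring
`NA` per-cyst values; a replicate with no defined values for a metric is
excluded for that metric with a warning) and compares conditions with a
two-sided paired Student's t-test on replicate means — n is the number of
biological replicates, not the number of cysts, matching how such
experiments are powered. Cyst-level rows are exported for plotting. If the
paired differences are (numerically) constant, the test reports the
degenerate limit explicitly (t = 0, p = 1 for zero differences; ±Inf, p = 0
otherwise) instead of erroring. Automated outlier removal is out of scope;
undefined per-cyst ratios are excluded from replicate means, which is
logged.

## The synthetic data generator

No imaging data are deposited with the original study, so the generator is
the package's ground-truth instrument. `simulate_cyst_volume()` builds an
ellipsoidal cyst (default semi-axes 3.4 × 5.0 × 5.0 µm) on a 40 × 112 × 112
grid at 0.2 × 0.1 × 0.1 µm spacing and fills it with:

* 30 puncta per channel — uniform spheres with radii drawn from
  N(0.45, 0.05²) µm (clamped to [0.2, 0.58]) rendered at `peak_intensity`
  200 and blurred with an isotropic 0.15 µm Gaussian;
* up to three large FYVE bodies (radius 1.4 µm, intensity 150) modeling the
  PLVAC;
* diffuse cyst fill (12 counts) in the expressed channels 2–3;
* uniform autofluorescent background (30 counts) plus
  `bleed_coefficient` × the noise-free channel-2 signal in channel 1;
* Poisson shot noise followed by Gaussian read noise (σ = 3), clamped at
  zero, drawn per timepoint with channels ordered 2, 3, 1 so control
  volumes share bit-identical channel-2/3 planes with their experimental
  counterparts.

Co-occurrence is generated by construction: `round(f · n)` query puncta are
placed at partner objects — at a distinct ATG8 partner's center (copying
its radius, so both channels image the same object and >90% mutual voxel
overlap is achievable) or uniformly inside a FYVE body. All other puncta
keep at least 1.1 µm from every object, so they never co-occur by accident;
the generator records realized fractions for all four ordered pairs by
brute-force center-in-object testing, including the emergent ATG8→ATG9
direction. Placement is rejection sampling with bounded retries and bounded
whole-layout restarts; infeasible requests raise an explicit
placement-failure error.

Two geometric separations deserve a note. Free puncta keep 1.1 µm apart
because two grown regions (radius ≈ 0.46 µm at the default configuration)
must not touch: if they connect, the contested voxels are split by
nearest-peak assignment and both segments are truncated. Inside a FYVE
body, same-channel puncta keep 0.95 µm apart for the same reason, while
puncta of *different* channels only need 0.6 µm — they are segmented
independently and cannot truncate each other, and 0.6 µm exceeds the
largest punctum radius, so no accidental center-in-object co-occurrence can
arise.

`apply_knockdown()` models TgATG9 depletion as three multipliers: the
channel-1 punctum count ×0.3 (rounded), the global punctum radius ×0.7
(shrinking objects in every channel, as depleted autophagy shrinks
autophagosomes), and the FYVE-pair fractions ×0.5 (reduced flux into the
PLVAC).

The defaults were chosen once to be realistic for this system — sub-micron
autophagic puncta at high signal-to-noise (peak 200 over background 30
gives SNR ≈ 13 at punctum centers), dozens of puncta per cyst, a 15-volume
time series at one volume per 20 s — and the punctum radius was placed so
that detected object volumes (≈ 0.4 µm³) sit well above the 0.2 µm³ filter
even after knockdown shrinkage. What the generator does *not* emulate:
realistic optics (no PSF model, no scattering, no depth-dependent
aberrations), parasite-level substructure (the source imaging itself lacked
single-cell resolution), punctum motion (static by default; a linear drift
option exists but dynamics are not part of the quantification), or
intensity heterogeneity between puncta. Passing the recovery tests
therefore demonstrates that the *pipeline arithmetic and detection logic*
are correct under a faithful noise and bleed-through model — not that the
detector is robust to every real-world imaging pathology.

## The analytic object-volume model

For an isolated punctum the whole imaging-plus-segmentation chain is
radially symmetric, which yields a closed-form prediction of the segmented
volume. A uniform ball of radius R convolved with an isotropic Gaussian σ
has the profile

$$C(d) = \tfrac12\!\left[\operatorname{erf}\frac{R-d}{\sigma\sqrt2} +
\operatorname{erf}\frac{R+d}{\sigma\sqrt2}\right] +
\frac{\sigma}{d\sqrt{2\pi}}\left[e^{-(R+d)^2/2\sigma^2} -
e^{-(R-d)^2/2\sigma^2}\right],$$

implemented in `blurred_ball_profile()` and verified in the tests against
independent numeric quadrature and against a voxel-grid rendering blurred
by the pipeline's own separable filter. The enhancer's response to the
punctum is the difference of two such profiles (blur and enhancement
Gaussians compose), and the segmented region is the ball where the response
exceeds `growth_fraction` of its center value; `expected_blob_volume()`
root-finds that radius. Measured mean volumes land within a few percent of
this prediction for the unsubtracted channels; the background-subtracted
channel runs ~10–15% smaller because the clamp at zero truncates the
punctum skirt, which is also why the ATG8→ATG9 ratio (large query against
the systematically smaller subtracted-channel segments) underestimates its
truth — a documented asymmetry of the correction, not of the overlap
arithmetic.

## Numerical choices and degenerate inputs

* Coordinates are 0-based voxel indices; physical position = index ×
  spacing at voxel centers.
* The volume filter compares with a 10⁻¹² absolute guard so that exact
  boundary volumes (100 voxels × 0.002 µm³) are retained regardless of
  floating-point composition order.
* Local-maximum plateaus resolve to the lowest linear index; region-growing
  ties resolve nearer-peak-then-lower-seed-id; both make segmentation
  deterministic.
* Empty results are valid everywhere: an all-zero volume yields an empty
  segment table, an empty channel yields `NA` ratios and volumes, a
  zero-cyst pipeline run exits cleanly with an empty table.
* All randomness flows from explicit integer seeds; `run_pipeline()`
  derives per-cyst seeds from one master seed and reruns are byte-identical
  including the exported CSVs.

## Problem sizes used in the validation suite

The packaged tests and the acceptance script run the full study geometry —
30 puncta per channel in a whole-cyst volume, 10 cysts per condition or per
true-fraction level, 3 biological replicates for the knockdown comparison —
with a single timepoint per cyst rather than the 15-volume series, since
puncta are static by default and the per-timepoint pooling logic is
exercised separately on small grids. Unit tests use a reduced cyst
(28 × 64 × 64 voxels, 5 puncta per channel) for speed. These sizes are the
package's validation design; all of them are parameters, and nothing in the
implementation depends on them.

## Known limitations

* The correspondence with the original commercial operators is semantic
  ("suppress local background, enhance puncta, grow blobs"), not numeric;
  their parameters are unpublished and equivalence is not claimed.
* The background model is one scalar per timepoint. Spatially structured
  autofluorescence would require a field-valued model.
* Puncta are not tracked across timepoints; the statistics pool detections,
  as the per-cyst ratios require.
* The ATG8→ATG9 ratio inherits a downward bias from the subtracted
  channel's truncated segments (see above); the three ratios used for
  between-condition comparisons are unaffected in direction.
* Flat-field correction, drift registration and deconvolution are out of
  scope.

```{r example}
library(cystpuncta)

p <- simulation_params(n_timepoints = 1L)
res <- run_pipeline(params = p, n_cysts = 4, n_replicates = 2, seed = 1)
res$summary[, c("metric", "mean_vehicle", "mean_treated", "p")]
```
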