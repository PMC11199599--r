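---
title: "Methods: focus proximity scoring and stripe recruitment kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: focus proximity scoring and stripe recruitment kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsbfoci)
```

# What the package computes

DNA double-strand-break (DSB) repair is routinely read out by fluorescence
microscopy in two ways, and `dsbfoci` implements both as reproducible,
parameterized pipelines:

1. **Object-based colocalization of nuclear foci.** Repair proteins and
   chromatin marks (53BP1, γH2AX) accumulate in diffraction-limited subnuclear
   puncta ("foci"). Rather than correlating pixel intensities, foci are
   detected as point objects per channel and each focus in a source channel is
   scored by the Euclidean distance to its nearest neighbour in a comparator
   channel, then binned as *overlapping* (≤ 5 px, i.e. ≤ 0.36 µm), *proximal*
   (5–15 px, 0.36–1.07 µm) or *distant* (> 15 px, > 1.07 µm).
2. **Recruitment kinetics at laser microirradiation stripes.** A 405-nm laser
   draws a 6.5 µm × 1 µm damage stripe inside a nucleus; an 80-frame
   time-lapse at 15 s per frame (damage initiated after frame 5) tracks
   EGFP-tagged protein accumulation. The damage-ROI trace is
   double-normalized against a control ROI in the same cell:
   $$R(t) = \frac{F_{\mathrm{bleach}}(t) / F_{\mathrm{bleach}}(-)}
                 {F_{\mathrm{control}}(t) / F_{\mathrm{control}}(-)},$$
   with $F(-)$ the pre-damage baseline mean of each ROI. Active recruitment
   gives $R > 1$; no or passive recruitment gives $R \le 1$. Whole-cell
   photobleaching and global intensity drift appear in both numerator and
   denominator and cancel.

Because the microscopy the pipelines were designed for is not bundled with
the package, a synthetic-imaging module renders ground-truthed stills and
movies; every stage is validated against that truth and against brute-force
oracles.

# Foci pipeline

## Nuclear segmentation

The Hoechst channel is thresholded with **Huang's fuzzy-entropy method**
(dark background: foreground = pixels above the threshold). For each
candidate threshold the histogram is split in two; each side's membership is
$u(g) = 1/(1 + |g - \mu_{\mathrm{side}}|/C)$ with $C$ the occupied intensity
range, and the count-weighted Shannon entropy of $u$ is minimized.
Implementation notes:

* Images are histogrammed into 256 equal-width bins spanning their range (as
  an 8-bit acquisition would be), which makes the resulting mask exactly
  invariant under positive rescaling of the image.
* When several thresholds tie exactly — e.g. a cleanly separable two-mode
  histogram, where the measure is flat anywhere between the modes — the
  midpoint of the tied run is returned rather than its lowest member, so the
  threshold lands between the modes.

Touching nuclei are split by a **watershed on the Euclidean distance
transform** with h-depth seed suppression (`watershed_h`, default 2 px, the
depth a basin must have to count as a separate nucleus). Each final label is
enforced to be a single 4-connected component; components smaller than
`min_nucleus_area` (default 750 px², half the area of the smallest default
simulated nucleus) are dropped, and border-touching nuclei are excluded by
default since partial nuclei bias per-cell focus counts. No hole-filling or
mask smoothing is applied.

## Focus detection

Channels are pre-blurred with a mild Gaussian (σ = 0.8 px, separable
convolution, reflective boundary, kernel truncated at 4σ and renormalized;
σ = 0 is the identity). Foci are then found per nucleus with a
**prominence-based local-maxima search**: a candidate peak is a
constant-value plateau with no higher 8-neighbour, and it is reported only if
it cannot be reached from any higher-ranked peak without descending more than
`prominence` below its own value (peaks ranked by value, ties by smallest
linear pixel index, so exactly one of two equal peaks joined by a shallow
saddle is kept). The highest peak of each connected region is always reported
unless the region is constant — a flat image yields nothing. This is the
persistence formulation of the flood-fill rule used by interactive maxima
finders; the implementation is a single union-find sweep over pixels in
decreasing intensity order, and the test suite checks it against an
independent brute-force path-search oracle on 1000 random images.

The prominence defaults to `prominence_k` (5) times the MAD-based noise SD of
the **raw** background (pixels outside all nuclei). Estimating noise before
the blur is deliberate: blurring shrinks pixel noise by ~3× but barely
reduces a 6-px focus's prominence, so the margin over noise maxima is wide.
Two caveats are documented rather than hidden: (i) under strongly
Poisson-dominated noise the background underestimates the noise inside
bright nuclei, and an explicit `prominence` should be supplied (mirroring the
per-experiment adjustment such analyses normally make); (ii) with a
noiseless background (MAD = 0) the fallback is 5% of the channel's dynamic
range.

A focus's **area** is the set of pixels 8-connected to its peak above
(peak − p/2), where p is the measured prominence capped at peak minus the
cell's median intensity (the cell median acting as local background). For an
isolated Gaussian focus this is its FWHM disk: a 6-px-FWHM spot covers
~28 px². The size filter (defaults 2–50 px²) then removes single-pixel
residues and large structures — in particular the per-cell top "peak" that a
structureless channel necessarily produces spans most of the cell and is
discarded by `size_max`.

Analysis is **gated to EGFP-expressing cells**: a nucleus passes if its mean
EGFP intensity exceeds the Huang threshold of the whole EGFP channel
(fluorescence above background as set by the auto-threshold). Per-cell focus
counts average over gated cells, counting zero-focus cells; with no gated
cells the mean is reported as missing, not 0.

## Proximity classification

Nearest-neighbour records are **directional** (source → comparator, default
EGFP → marker), computed within each nucleus; a source focus in a cell with
no comparator foci is *unmatched* (excluded from class fractions, reported in
its own column). Distances are continuous Euclidean distances between
centroids in pixels, so the integer bin edges are read as half-open real
intervals $d \le 5 < d \le 15 < d$; the three classes partition $[0,\infty)$.
The default reporting pixel scale, 1.07/15 ≈ 0.0713 µm/px, derives from the
bins' own 15 px ↔ 1.07 µm correspondence; the acquisition-level ~0.11 µm/px
figure is inconsistent with it, so the scale is an explicit parameter rather
than a hidden constant, and conversions are reported to 2 decimals
(5 px → 0.36 µm).

# Stripe pipeline

Traces are per-frame means over the damage and control ROIs, with no
registration or interpolation (frames are assumed aligned). The control ROI
can be auto-placed as the largest axis-aligned rectangle inscribed in the
nucleus mask after removing the damage ROI dilated by 5 px — "same cell,
away from the damage site" made concrete. The baseline is frames 1–5 (damage
is initiated after frame 5); using the mean of all five pre-damage frames
rather than the single last one halves the baseline estimation noise and is
configurable. Aggregation across cells is the pointwise mean with SEM =
sample SD/√n (n−1 denominator); a single cell reports SEM as missing.

**Classification**: a batch is *active* when the mean ratio over the last 10
frames exceeds 1 + 2·SEM of that window mean. The SEM used is the mean of
the aggregate's between-cell SEMs over the window when available: per-cell
baseline normalization leaves each cell's curve with a small persistent
offset (the baseline is itself estimated from 5 noisy frames), which
frame-to-frame scatter inside the window cannot see. A curve identically 1
is *none*.

**Kinetic fit**: $R(t) = 1 + A\,(1 - e^{-(t - t_{\mathrm{dmg}})/\tau})$ is
fitted to the post-damage frames by Levenberg–Marquardt least squares,
multi-started over τ ∈ {15, 60, 150, 400, 1000} s with the best RSS kept;
fewer than 4 post-damage frames is an error, and a flat curve degenerates to
$\hat A \approx 0$ with no time constant. This fit is package
instrumentation for parameter-recovery validation — the biological readout
is the curve itself and the > 1 criterion.

# Synthetic data: what it emulates and what it does not

The generator renders what the pipelines need to be testable, no more:

* **Nuclei** are filled ellipses (semi-axes 22–32 px at 0.11 µm/px by
  default) with a flat interior and a sharp 5% edge falloff, optionally
  touching. Real chromatin texture, 3D structure and stage drift are out of
  scope.
* **Foci** are isotropic Gaussians with σ = FWHM/2.355 ≈ 2.55 px, matching a
  6-px focus diameter; pairs are planted at exact cross-channel separations
  (the stored truth distance agrees with the rendered positions to 1e-9 px).
  Pair anchors stay at normalized elliptical radius ≤ 0.75, on the flat part
  of the fill, and same-channel anchors keep ≥ `min_separation` (16 px
  default) so spots remain individually resolvable.
* **Noise** is Poisson (photon) noise followed by Gaussian read noise and an
  offset; defaults (1 photon/intensity unit, SD 1) are a plausible confocal
  regime, not a calibration. Spectral bleed-through is not modelled.
* **Stripe movies** follow the acquisition protocol (80 frames, 15 s,
  damage after frame 5; 6.5 × 1 µm stripe at 0.10 µm/px) with the stripe ROI
  scaled by the recruitment factor and the whole frame by
  $e^{-k_{\mathrm{bleach}} t}$ — multiplicative, gain-like bleaching, so the
  double ratio cancels it *exactly* on noiseless data, which the tests
  exploit. `snr = 10` sets the read-noise SD to a tenth of the baseline
  stripe intensity.

Passing tests on these scenes therefore demonstrate algorithmic correctness
(detection, distances, classes, normalization, fitting) under controlled
conditions; they do not certify performance on real images with textured
chromatin, overlapping same-channel foci, or drifting stages.

# Numerical choices and degenerate inputs

* Coordinates are 1-based (row, col), pixel-center; distances are computed in
  pixels and converted to µm only for reporting.
* Determinism: every stochastic step derives its stream from a single scene
  seed; identical spec + seed gives bit-identical images, and pipeline reruns
  write byte-identical CSVs.
* Degenerate inputs fail loudly and specifically: single-level histograms
  (degenerate threshold), non-positive baselines (empty ROI/saturation),
  ROIs outside the frame, unequal trace lengths, stripes that fit no nucleus,
  impossible non-touching nucleus densities. A constant EGFP channel gates
  zero cells with a warning rather than an error.
* Plateau maxima are reported at the plateau centroid; nearest-neighbour
  ties go to the first comparator focus.

# Validation sizes

The shipped test suite runs the validations at these sizes: the maxima
finder against the brute-force oracle on 1000 random 16×16 images (plus 120
8×8 images with masks), nearest neighbours against the O(n²) oracle on 1000
random cells, the Huang threshold against exhaustive minimization on 200
random bimodal histograms (plus 60 in the unit tests); end-to-end class
recovery on 125 noiseless pairs at 1–25 px across 5 scenes of 25 nuclei;
kinetic parameter recovery on a 3×3 (A, τ) grid — noiseless within 1%, and
at SNR 10 with n = 20 cells per condition median relative error ≤ 15%; and
the > 1 recruitment criterion on 20-cell batches at A = 1 versus A = 0.

# Known limitations

* The maxima search and segmentation are pure-R/EBImage; very large tiles
  (≫ 1000² px) will be slow compared to compiled implementations.
* The background-MAD prominence default assumes the background noise level
  is representative of intra-nuclear noise (see above).
* Focus *area* is a half-prominence region, not a fitted spot model; areas
  of closely spaced same-channel foci can overlap.
* Only 2D inputs are supported; z-stacks must be projected upstream.
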