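---
title: "Measuring rod-shaped bacteria from segmentation masks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring rod-shaped bacteria from segmentation masks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

rodmorph turns 2D instance-label masks of rod-shaped bacteria into per-cell
size estimates, corrects the systematic size bias that automatic segmenters
introduce, and benchmarks instance segmentations against ground truth. This
vignette explains the underlying models, the numerical choices, and what the
built-in simulator does and does not emulate.

## The spherocylinder measurement model

Rod-shaped bacteria are modelled as spherocylinders: a cylinder of diameter
$w$ capped by two hemispheres, imaged at its medial focal plane so that the
mask is the 2D capsule footprint. The pipeline for one instance is:

1. **Radius field.** The exact Euclidean distance transform assigns every
   mask pixel its distance to the nearest background pixel. Along the
   midline this value is the local cell radius. Values are used raw: no
   half-pixel boundary adjustment is applied, because the remaining
   systematic offset of real segmenters is the business of the measurement
   transformation (below), not of the geometry code.
2. **Skeleton.** Morphological thinning (the two-subiteration scheme of
   Lam, Lee and Suen) reduces the mask to an 8-connected, one-pixel-wide
   centerline. The topological medial axis is deliberately avoided; it
   over-branches on realistic masks. Classic Zhang–Suen thinning was also
   rejected: it erases diagonal strokes in one of the two diagonal
   directions, which destroys the skeleton of rods oriented near 135°.
3. **Skeleton graph.** Every skeleton pixel is a node; edges join pixel
   pairs closer than 1.5 px (horizontal/vertical and diagonal neighbours).
   Degree-1 nodes are endpoints. Cycles, which occur on noisy masks, are
   broken by a spanning tree with a warning. If there are more than 12
   endpoints, only the 12 most eccentric are kept, again with a warning, so
   pathological masks cannot make the candidate enumeration explode.
4. **Candidate paths.** An unbranched skeleton is itself the single
   candidate path. A branched skeleton yields one simple path per endpoint
   pair; each cell metric is then the median over candidates (mean of the
   two middle values for even counts), which makes the result robust to
   spurious branches without choosing a "best" branch heuristically.
5. **Path metrics.** On a centerline with points $i = 1..n$, per-point
   radii $r_{c,i}$, cap radii $r_{s1}, r_{s2}$, steps $d(i, i+1)$ and slab
   height $h$ of one pixel:
   $$L = r_{s1} + r_{s2} + \sum_i d(i, i+1)$$
   $$\bar w = \frac{2}{n} \sum_i r_{c,i}$$
   $$S = 2\pi \left(r_{s1}^2 + r_{s2}^2 + h \sum_i r_{c,i}\right)$$
   $$V = \pi \left(\tfrac{2}{3} r_{s1}^3 + \tfrac{2}{3} r_{s2}^3 +
         h \sum_i r_{c,i}^2\right)$$
   Lengths scale with the pixel size, areas with its square, volumes with
   its cube. `measure_path()` computes these sums verbatim on any path.

## How the centerline is constructed

Applying the sums to the raw pixel path would make the estimates depend
strongly on cell orientation, because digital geometry interferes in three
ways. Chain-code steps (1 or $\sqrt2$) overestimate the length of a digital
straight line by up to 8% (worst near 22.5°). Thinning stops short of the
cap junction by an orientation-dependent amount, which the endpoint's
distance-transform value cannot recover. And a single terminal
distance-transform sample carries up to half a pixel of lattice noise that
the squared and cubed cap terms amplify to 10–15% errors in $S$ and $V$.

`measure_cell()` therefore builds each candidate's `centerline_path` with
five standard estimation steps, and then evaluates the formulas above on
that path (so the reported metrics are exactly `measure_path()` of the
constructed path):

* **Smoothing and resampling.** The raw pixel path is smoothed with a
  moving average whose window matches the local diameter (shrinking
  symmetrically near the ends so endpoints stay fixed) and resampled at
  unit arc-length spacing. This removes the staircase length inflation;
  radii are sampled from the distance transform by bilinear interpolation.
* **Robust cap radii.** $r_{s1}, r_{s2}$ are medians of the radius profile
  over a window of about 1.5 local radii at each end, instead of single
  terminal samples.
* **Tip extents.** The axial extent of the mask beyond each endpoint is the
  largest projection of any instance pixel onto the end tangent, restricted
  to a forward cone so strongly curved cells cannot contribute their far
  side. The cap junction is then `tip extent − cap radius` beyond the
  endpoint, and the radius profile is trimmed or extended to span exactly
  the cylindrical part. This recovers the length the thinning lost and
  keeps the capped-by-hemispheres reading of the tip distance.
* **Footprint calibration.** The whole radius profile is rescaled by a
  single factor $\gamma$ (typically 1.00–1.05, solved by Newton iteration)
  so that the model footprint $2h\sum r + \tfrac{\pi}{2}(r_{s1}^2 +
  r_{s2}^2)$ equals the instance's exact pixel area. The pixel count is by
  far the most digitization-robust observable of a mask (±0.5% in
  practice), so anchoring the profile to it suppresses the lattice noise of
  the distance transform without touching the profile's shape.
* **Slab-consistent point count.** The final path carries one point per
  unit slab (midpoint convention). With $n$ points spanning $n$ slabs the
  $n$-term sums in $S$ and $V$ are midpoint Riemann sums of the lateral
  integrals; with one point per *node* they would overcount a full slab,
  which is negligible for long cells but worth 6–12% of the volume of a
  2 µm cell.

On 50 simulated ideal spherocylinders spanning widths 0.53–1.04 µm and
tip-to-tip lengths 2–8 µm at 65 nm/px (the package's acceptance suite),
this construction recovers width within ±0.5 px, length within ±1.5 px, and
surface/volume within 5% of the closed forms per cell.

Two caveats are inherent to binary masks and worth knowing. First, an
axis-aligned digital rod with an unlucky sub-pixel offset genuinely is one
pixel wider than its generating width; no estimator can undo that, so
volume errors of ~10% are possible for individual near-axis-aligned cells,
while the estimator stays unbiased on average. For the same reason the
rotation-robustness test compares per-angle *means* over 24 sub-pixel
placements rather than single placements. Second, degenerate instances
whose skeleton has two pixels or fewer report only a width (twice the
maximum radius) and are flagged; instances split into several connected
components are measured on the largest component and flagged.

## Shape descriptors and intensity profiles

Cross-sectional area, convex hull area, eccentricity and solidity come
directly from the mask region: area is the pixel count, the hull area
counts pixels whose centers fall in the convex hull of the region's pixel
centers (so solidity is exactly 1 for convex regions), and eccentricity is
that of the ellipse with the region's second central moments.
`extract_intensity_profile()` reads bilinearly interpolated samples along a
line (by default 24 samples, the length used for membrane cross-profiles)
with optional joint normalization.

## The Bayesian measurement transformation

Automatic segmenters systematically over- or underestimate cell size, and
the relation to ground truth is linear to good approximation. Per size
metric, rodmorph fits

$$\text{truth}_i \sim \mathrm{Normal}(m \cdot \text{auto}_i + n,\ \sigma)$$

with priors $m, n \sim \mathrm{Normal}(0, 20)$ and a Half-Cauchy prior on
$\sigma$. The regression is fit with truth as the response, because the
model's purpose is to predict the true size from an automatic measurement.
Sampling uses JAGS with four chains of 3000 retained draws (12000 total).
Internally the sampler works on centered regressors with the exactly
equivalent prior $q \mid m \sim \mathrm{Normal}(m\bar x, 20)$ for
$q = n + m\bar x$, which decorrelates slope and intercept and mixes well;
$\sigma$ is truncated at $10^{-9}$ only to keep the likelihood finite on
perfectly noiseless inputs. Convergence is checked with split-$\hat R$
(warn above 1.05). The Half-Cauchy scale (10) is weakly informative for
µm-scale residuals and configurable.

To transform a measurement, 250 $(m, n)$ pairs per cell are drawn jointly
(rows of the posterior draw table, preserving posterior correlation —
drawing the parameters independently would discard it) and the per-cell
summary is the median of the transformed values. No Normal$(0, \sigma)$
observation noise is added: the transformation propagates parameter
uncertainty, not measurement noise; $\sigma$ is kept for diagnostics.

Distribution agreement before/after correction is quantified with a
histogram Kullback–Leibler divergence: shared bins over the pooled range,
Freedman–Diaconis bin count on the pooled sample (at least 10 bins), and
$\varepsilon = 10^{-10}$ smoothing before normalization so disjoint
supports give a large but finite value. Group comparisons follow the
variance-gated flow: Brown–Forsythe (median-centered Levene) first; one-way
ANOVA if its p-value exceeds 0.05, Kruskal–Wallis otherwise.

## Benchmarking instance segmentations

`instance_iou_matrix()` computes pairwise intersection-over-union between
ground-truth and predicted instances (background excluded).
`match_at_threshold()` finds the one-to-one assignment maximizing total
matched IoU (maximum-weight bipartite matching; a greedy variant is
available for comparison), and counts a matched pair as a true positive
when its IoU is at least the threshold minus $10^{-9}$ — the slack lets
threshold 1.0 admit exact matches despite floating point. `f1_curve()`
evaluates $F1 = 2TP/(2TP + FP + FN)$ at eleven IoU thresholds from 0.5 to
1.0 in steps of 0.05 and aggregates across images as the unweighted mean of
per-image F1 (pooled counts are available behind a flag).

## The synthetic scene simulator

`generate_scene()` places non-overlapping spherocylinders (rejection
sampling on capsule-capsule distances) and rasterizes exact footprints as
label masks at a 15 nm render pixel size. Default conditions follow the
fluorescent-membrane simulation protocol the package is tested against:
tip-to-tip length 4 µm; widths variable (default uniform over
0.53–1.04 µm, the calibration range; the width distribution is a parameter
because no canonical choice exists); orientation uniform over 0–180°;
membrane emitters on 90% of contour points; emission wavelength 600 nm, NA
1.49, refractive index 1.5; final rescale to 65 nm/px.

`render_membrane_stack()` models the optics with an isotropic 2D Gaussian
PSF of $\sigma = 0.21\lambda/\mathrm{NA}$ (≈ 84.6 nm) per plane, broadened
with defocus on the axial scale $n\lambda/\mathrm{NA}^2$; this Gaussian is
an approximation, not a reimplementation of a full vectorial PSF. At axial
offset $dz$ a cell of radius $r$ contributes its cross-section outline of
radius $\sqrt{r^2 - dz^2}$ (planes beyond $|dz| \ge r$ contribute
nothing), which reproduces the two properties real z-stacks show: apparent
width is maximal at the mid-cell focal plane, and widths measured from
max/mean/sum projections agree closely. Optional Poisson shot noise and
Gaussian read noise are available and seeded. `rescale_scene()`
block-averages intensities and majority-votes labels per output pixel,
handling non-integer scale ratios by pixel-center assignment.

What the simulator does *not* emulate: camera-specific noise calibration,
spectral bleed-through, uneven staining beyond random emitter dropout,
curved or tapered cells, and chained cells sharing septa are not rendered
by default. Passing tests on these scenes therefore validates the geometry
and statistics of the pipeline, not its robustness to every imaging
artifact of real membrane stains.

## Problem sizes and runtime choices

The shipped test-suite and acceptance script use desk-scale problems chosen
to exercise every code path: 50-cell recovery suites for geometry, 100
random small scenes for the matching oracle, 20 seeded simulations for
posterior coverage, 200–1000 point regressions, and single-scene renders at
full 15 nm resolution. These sizes keep a complete run in the low minutes
while leaving the estimators' behaviour clearly measurable.
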