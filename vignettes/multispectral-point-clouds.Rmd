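---
title: "Illumination-corrected multispectral point clouds: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Illumination-corrected multispectral point clouds: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Close-range spectral imaging of plants confounds two signals: the intrinsic
reflectance of the tissue (the quantity that carries physiological
information) and the local illumination state — how far each surface element
sits from the lamp, how steeply light strikes it, and from where the camera
observes it. A flat calibration reference corrects only one illumination
state per frame, so leaves above, below, or tilted against the reference
plane come out systematically too bright or too dark, and the same leaf
changes its apparent spectrum from view to view.

`specpcd` implements a correction pipeline built around a *geometric*
reference: a matte hemisphere whose surface presents a continuum of
positions and orientations to the light. By imaging the hemisphere at many
rig positions, one samples the sensor's digital numbers (DN) across the
joint space of position and surface orientation. A regression model trained
on those samples predicts, for every *plant* pixel, the DN a reference
surface would have produced at the same position and orientation — and the
pixelwise ratio of plant DN to predicted reference DN cancels the shared
illumination factor, leaving reflectance. Mapped onto the point cloud
backprojected from the depth image, this yields a 3D multispectral point
cloud with illumination-corrected per-point spectra.

The pipeline has four stages, each exposed as package functions:

1. **Multimodal registration** of the snapshot multispectral image onto the
   RGB-D frame: preprocessing (HSV/depth and NDVI segmentation, histogram
   matching), adaptive SURF coarse registration, Demons nonrigid
   refinement, and a single composed resampling of all 25 bands.
2. **3D light-field features**: the depth image is backprojected into an
   organized point cloud; per-pixel normals come from 3×3 local SVD plane
   fits; each pixel gets the 8-channel descriptor
   (d_i, d_v, θ_i, θ_v, θ, x, y, z) — distance to light, distance to
   camera, incidence angle, viewing angle, in-plane azimuth between the
   light and view directions, and the 3D coordinates.
3. **Reference model**: a shallow neural network (8 → 20 sigmoid → 25
   linear) or a nearest-neighbour search over the pooled reference pixels
   maps features to the 25-band reference DN spectrum.
4. **Correction and export**: pixelwise ratio, outlier masking, and PLY
   export of the surviving points with their reflectance spectra.

# Registration

**Fixed and moving roles.** The G channel of the RGB image is the fixed
image; the 740 nm band (band 7 of 25) is the moving image — the band pair
with the most shared structure across the modality gap. Both are segmented
to plant foreground (the background carries no mutual information and
histogram matching across the modality gap only makes sense on commensurate
content), and the moving image is histogram-matched to the fixed.

**Coarse stage.** SURF keypoints are detected from approximated Hessian
determinants computed with box filters on integral images,
`c = Dxx·Dyy − (w·Dxy)²` with `w = 0.9`. The filter-response weight enters
squared by default; a config switch (`surf.hessian_w_mode: linear`)
provides the `w·Dxy²` variant for compatibility. Keypoints are 3×3×3
scale-space maxima above a response threshold, described by 64-dimensional
oriented Haar-response descriptors and matched by mutual nearest neighbour
with a descriptor-distance threshold.

Rather than hand-tuning the two thresholds, the adaptive search scores a
grid of (response, distance) threshold pairs — default 10 × 10 interior
nodes over the observed ranges — by estimating a planar transform from each
node's surviving matches, warping, and computing SSIM against the fixed
image. The interval is then shrunk to the index span of the four
best-scoring nodes and re-divided; rounds stop when the relative gain of
the best-ever SSIM falls to `e1` (default 0.01, max 5 rounds). The
best-ever transform is retained, so the reported SSIM is non-decreasing by
construction. Transform estimation is robustified with seeded inlier
resampling (tolerance 3 px — above the nonrigid residual the fine stage is
expected to absorb) followed by a least-squares refit; the plain
least-squares path is available by setting `ransac_iters = 0`.

**Fine stage.** Thirion-style Demons iterates
`u = (s − m∘t)·∇m / (‖∇m‖² + α²(s − m∘t)²)` with `α = 1`, a denominator
guard at 1e-9, and Gaussian field smoothing (σ_d = 1 px) each iteration;
the stop rule mirrors the coarse stage with threshold `e2` (default 0.001,
max 100 iterations), returning the best-SSIM field. The SSIM stop rule
saturates well before the displacement field stops improving — SSIM is
insensitive to sub-pixel residuals — so experiments that score endpoint
error run the stage with `e2 = 1e-4` to `0` and a higher iteration cap.

**Composed application.** The 25 bands are resampled exactly once through
the composed map `x → T⁻¹(x + t(x))` (bicubic); warping twice would
compound interpolation blur.

**SSIM convention.** 11 × 11 Gaussian window (σ = 1.5), `C1 = (0.01 L)²`,
`C2 = (0.03 L)²`. During registration SSIM is averaged over windows whose
centre lies in the union of the two foregrounds (`ssim.on_foreground`);
scoring empty background against empty background would inflate the score.

# Light-field features

Depth (z) backprojects through the pinhole model
`x = (u − cx)·z/fx, y = (v − cy)·z/fy`. Normals come from the singular
vector of least singular value of the centred 3×3 window scatter, computed
in closed form (trigonometric eigenvalues + row cross products) so whole
frames vectorize. Window neighbours further than 10 mm in depth from the
centre are rejected before the fit: window adjacency does not imply spatial
adjacency at leaf boundaries, and unfiltered fits produce strongly biased
rim normals. Normals are oriented toward the camera, making θ_v ≤ 90° and
θ_i well defined without a global mesh orientation. The azimuth θ between
the in-plane projections of the light and view directions is unsigned in
[0, π], with θ = 0 where either projection degenerates (< 1e-9).

# Reference model

All reference pixels from all hemisphere frames are pooled; features and DN
outputs are min–max normalized (feature scales are heterogeneous: metres
vs radians). The network is trained with nnet's full-batch BFGS in 10
warm-restarted stages totalling 500 iterations, with a 70/15/15
train/validation/test split and selection of the stage with the best
validation MSE. Two deliberate restraint choices:

* **No weight decay, modest iteration budget.** The hemisphere surface ties
  each sampled normal to its position: the training rows live on a union of
  thin two-dimensional sheets inside the feature space, while plant pixels
  query *between* those sheets. The validation split, drawn from the same
  sheets, cannot detect off-sheet behaviour; in our experiments, optimizing
  substantially past this budget kept improving on-sheet fit while visibly
  degrading plant-pixel predictions. The bounded budget is the regularizer.
* **Extrapolation flagging.** Pixels whose features leave the training
  min–max hull are predicted anyway but flagged, and by default
  (`model.mask_extrapolated`) excluded from the corrected cube — these are
  precisely the grazing-angle and out-of-volume pixels for which the
  reference database is silent.

The per-pixel split is the default; `split_mode = "frame"` holds out whole
rig positions, the honest generalization test across poses.

The search-based alternative matches each plant pixel's normalized feature
vector to its nearest database row under one of nine metrics (Euclidean,
weighted Euclidean v1/v2, cosine, Mahalanobis, Chebychev, PCA-cosine,
weighted Mahalanobis v1/v2). Weighted-Euclidean weights are random-forest
feature importances (predicting the band-mean DN — the forest has a single
response and the bands are strongly rank-correlated) normalized to a top
weight of 1; weighted-Mahalanobis weights are the PCA variance
contributions, v1 assigning large weights to important dimensions and v2
the reverse. Every metric runs as an exact vectorized scan (metrics that
admit it are reduced to Euclidean distance in a linearly transformed
space); exactness against a brute-force double loop is enforced by test.

# Correction, outliers, export

`R(p, b) = ρ_ref(b) · DN_plant(p, b) / DN_ref(p, b)`. With the default
`ρ_ref = 1` this is the raw percentage ratio; supplying the measured
reference spectrum (matte PTFE ≈ 0.6) rescales to absolute reflectance,
which also keeps vegetation spectra inside the outlier bounds. A pixel is
masked when any band is negative or more than 20% of its bands leave
[0.01, 0.8] — negative and near-zero values mark reference-prediction
breakdown, values above 0.8 mark specular or misregistered pixels.
Surviving pixels map one-to-one onto the organized cloud, row-major, and
serialize to PLY (ascii or binary little-endian) with one
`refl_<wavelength>` float property per band.

# The synthetic rig

The package replaces the physical acquisition rig with a ray-casting
renderer under a Lambertian shading law
`DN = g_b · ρ_b · max(0, cos θ_i) · cos^p(ψ) / d_i² + a_b + noise`:

* **Geometry.** Pinhole cameras; the depth camera reports z-depth in
  millimetre-quantized 16-bit PNGs (0 = invalid). The rig is pitched 40°
  with a 0.75 m working distance; "plant up" in camera coordinates is the
  correspondingly tilted axis, so height sweeps change both image y and
  depth, as on the physical stand.
* **References.** Matte domes of 100 mm diameter and albedo 0.6, posed on a
  10 (vertical) × 7 (horizontal) grid — 70 poses, vertical step 10% of the
  plant height, dome axis toward the camera.
* **Lamp.** A point source with inverse-square falloff and a `cos^8`
  angular emission profile aimed at the stage centre. The beam term is
  essential, not cosmetic: under a perfectly isotropic point source the
  five relational features (d_i, d_v, θ_i, θ_v, θ) are a *sufficient
  statistic* for Lambertian shading, position adds no information, and no
  regressor can benefit from 8 inputs over 5. Real reflector lamps are
  directionally nonuniform — illumination nonuniformity is one of the
  effects the hemisphere method exists to correct — and a few-tens-of-
  degrees beam restores the position dependence. Much narrower beams make
  the DN field so steep that the 20-unit network underfits it; `cos^8` at
  the configured lamp distance is the realistic middle. Configurable
  (`spot_exponent`, 0 = isotropic).
* **Plants.** Elliptical leaf patches (alternating planar and gently
  curved spherical caps), zenith inclinations 20–45°, azimuths within ±45°
  of the camera direction, scattered through the working volume; albedo
  spectra are smooth red-edge curves with three NIR plateau levels. Views
  rotate the scene about the world-vertical axis through the stage centre
  across a 90° span — every leaf keeps a lever arm about the turntable
  axis, so every view change modulates its illumination. Sensor noise
  defaults to 1% of the peak reference DN. All randomness flows from
  explicit per-call seeds.
* **Ground truth.** Per-pixel object ids, planted albedo, analytic normals
  and all eight feature channels evaluated from the primitives' exact
  geometry (never from the rendered depth grid), plus exact dense
  displacement fields for fabricated registration pairs
  (`make_registration_pair` composes a planar transform with a
  constant-norm rotating sinusoidal displacement and inverts it
  numerically for rendering).

**What passing tests do and do not show.** The renderer is ideal-Lambertian
with a single point source: no specularity, no multiple scattering, no
occlusion-driven shadowing, no transmission. Success on this substrate
validates the pipeline's mechanics — registration recovery, feature
fidelity, the cancellation algebra, and the model's interpolation across
reference poses — not robustness to waxy leaves, dense canopies, or sensor
artefacts, which the physical method itself handles only partially.

# Study conditions and problem sizes

The validation study (test suite and `scripts/acceptance.R`) runs at a
reduced snapshot-camera resolution of 205 × 108 with the measured reference
spectrum (0.6): 70 reference frames (≈ 35k database rows, capped at 30k
training rows), a 15-view leaf scene, 500 network iterations; registration
experiments use 128 × 128 blob images with 120 blobs (texture everywhere —
SSIM over large flat regions saturates and discriminates poorly). The
multiview consistency gain is summarized as the reduction of the *mean*
per-leaf distance range: individual leaves whose normals happen to lie near
the turntable axis see almost no illumination change across views, so their
uncorrected range is near zero and a per-leaf ratio is numerically
meaningless.

# Known limitations

* The Demons stop rule inherits SSIM's insensitivity to sub-pixel error;
  quantitative warping studies should lower `e2`.
* The correction assumes the ambient term is negligible (the ratio cancels
  multiplicative illumination only); `a_b > 0` in the renderer injects a
  controlled violation for sensitivity studies.
* The reference network interpolates between discrete dome poses; its error
  is largest for feature combinations far from any pose (flagged via the
  extrapolation mask) — denser layouts trade acquisition effort for
  accuracy.
* Multiview point-cloud *merging* is out of scope: per-view rigid
  transforms must be supplied by the user if a fused model is wanted.
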