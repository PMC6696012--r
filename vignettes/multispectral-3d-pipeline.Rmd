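---
title: "Methods: multispectral 3D canopy measurement with ms3d"
author: "ms3d authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multispectral 3D canopy measurement with ms3d}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ms3d)
```

## The measurement problem

Leaf chlorophyll, routinely proxied by the unitless SPAD reading of a
hand-held meter, correlates with narrow-band reflectance through
vegetation indices such as NDVI = (ρ~Nir~ − ρ~Red~)/(ρ~Nir~ + ρ~Red~).
Index values measured from a single camera position are unstable for a
plant with complex 3D architecture: each viewpoint sees a different
subset of the canopy, so single-view reflectance statistics vary between
positions and under-sample the canopy. `ms3d` implements the alternative:
fuse RGB-D frames taken at several turntable positions into one
multispectral 3D point cloud of the whole canopy, compute indices per
point, and calibrate SPAD against the canopy-mean index.

The pipeline has five stages, each usable on its own:

1. **Spectral-to-depth registration** (`estimate_similarity`,
   `register_cube`). The reflectance imager and the depth camera view the
   scene through different optics; their pixel grids differ by an unknown
   2D similarity transform (translation, rotation, scale). Because the
   two sensors produce radiometrically different images with a large zoom
   ratio, feature-point matching is unreliable; the transform is
   estimated in the frequency domain instead. Translation comes from
   phase correlation: the normalized cross-power spectrum of two shifted
   images is a pure phase ramp whose inverse FFT is an impulse at the
   shift. Rotation and scale come from the Fourier–Mellin construction:
   the Fourier magnitude is invariant to translation, a rotation of the
   image rotates it, and a scaling scales it inversely, so resampling the
   magnitude onto a (log ρ, θ) grid turns both into translations that the
   same phase correlation recovers. The transform is calibrated once per
   rig and reused for every band and view.
2. **Turntable self-calibration** (`detect_sticker_center`,
   `estimate_axis`). Two colored stickers on the table are detected by an
   HSV threshold on the cloud's RGB attributes; their 3D centroids are
   observed at table rotations 0° and 180°. Each sticker's midpoint
   between the two rotations lies on the rotation axis, so the axis
   center M is the mean of the two midpoints, and the axis normal P is
   the unit normal of the table plane through the four centers.
3. **Rough registration** (`unproject`, `to_common_frame`). Depth pixels
   unproject through the pinhole model, x = (i − c~x~)·z/f~x~,
   y = −(j − c~y~)·z/f~y~, z = Depth(i,j)/1000; the sign flip on y makes
   +Y point up. Each view is then translated by −M, rotated about X and
   then Z so that P maps exactly onto (0, 1, 0), and finally rotated
   about Y by the view's inverse table angle γ = spin_sign · k · 360°/V~N~.
   All views now share the turntable frame.
4. **Precise registration and fusion** (`icp`, `fuse_views`). Sequential
   point-to-point ICP: the first view is registered to the second, the
   accumulated model to the third, and so on; correspondences are
   nearest neighbors gated at 10 mm, the rigid update is the closed-form
   SVD fit, and the result is voxel-downsampled at 2 mm with NA-aware
   attribute averaging. ROI cropping and statistical outlier removal
   (k = 20 neighbors, threshold mean + 2 SD of the mean k-NN distance)
   precede fusion; the canopy is then cut at the pot-top height.
5. **Indices and SPAD calibration** (`annotate_cloud`, `canopy_stats`,
   `spad_fit`, `spad_paper_model`). Nine indices (NDVI, GNDVI, NDVIR,
   CIG, RCIG, NG, NR, RVI, GRVI) are computed per point and averaged
   afterwards — average-of-index, not index-of-average — and SPAD is
   calibrated against the canopy mean with four prototype functions:
   M1 linear a·x + b, M2 quadratic a·x² + b·x + c, M3 exponential
   c·10^(k·x)^, M4 power c·x^k^. A registry of published 3DROI
   calibrations for all nine indices is served verbatim by
   `spad_paper_model()`.

## Conventions and numerical choices

* Image pixels are 0-based, x = column, y = row, origin top-left. A
  similarity transform maps moving-grid onto reference-grid coordinates
  about the grid centers; `warp_similarity` inverse-maps output pixels
  with bilinear interpolation.
* All FFT inputs are mean-subtracted and Hann-windowed to suppress
  wrap-around edge artifacts; the circular-shift diagnostics disable the
  window because strictly circular content needs none, and that is what
  makes integer shifts exactly recoverable.
* The log-polar grid defaults to 128 radius × 180 angle bins over
  θ ∈ [0°, 180°) (the magnitude spectrum is point-symmetric), radii from
  2 to half the image size, after a standard high-pass emphasis
  (1 − X)(2 − X) with X = cos(πf~x~)cos(πf~y~). The 180° rotation
  ambiguity is resolved by de-rotating with both candidate angles and
  keeping the one with the stronger translation peak. Peaks are refined
  by 3×3 parabolic interpolation; the cross-power spectrum is normalized
  with ε = 10^−12^. An estimated scale outside [1/4, 4] signals
  registration failure.
* The two axis-alignment rotations are built directly from the unit
  normal (a, b, c): about X with cos α = b/s, sin α = c/s where
  s = √(b² + c²), then about Z with cos β = s, sin β = a, composed so
  that the normal lands on (0, 1, 0) to machine precision — this exact
  invariant is what the test suite asserts, and it fixes the sign
  convention of both rotations. An axis parallel to camera X (s ≈ 0)
  is rejected as degenerate.
* γ's sign depends on the table's spin direction, which the hardware does
  not report; `spin_sign` is a configuration entry (+1 = counter-clockwise
  seen from +Y, the generator's convention).
* RMSE of SPAD fits uses denominator n (not n − p); R² is
  1 − SS~res~/SS~tot~, with squared Pearson correlation available as
  `spad_r2_pearson()` for comparison. M3/M4 are fitted by
  Levenberg–Marquardt nonlinear least squares initialized from the
  log-linearized OLS solution.
* Sticker "centers" are inlier centroids (a circle fit is a possible
  alternative; the centroid is accurate to well under 2 mm on rendered
  bare-table views). Detection requires at least 20 inliers.
* Reflectance outside [0, 1] is clipped with a warning. Missing
  reflectance is NA throughout and propagates into indices; canopy
  statistics ignore NA and use the sample (n − 1) standard deviation.

## The synthetic-scene generator

No imaging data are deposited with the original study, so validation
relies on `make_scene()`/`render_view()`, which emulate the rig: a 20 cm
turntable disc carrying two 5 cm calibration stickers (yellow and red,
placed at azimuths where neither the pot nor the plant blocks the
camera's line of sight), a pot, a stem, and parametric leaves arranged by
golden-angle phyllotaxis; a pinhole RGB-D camera about 1.05 m away
(within the sensor's 0.5–4.5 m range) viewing the table from ~30°
elevation at 224×200 px with f = 300 px; and a reflectance imager whose
grid differs from the depth grid by the fixture transform
(dx = 8 px, dy = −5 px, θ = 4°, σ = 0.85), chosen to exercise every
similarity parameter.

Per-point SPAD is uniform over [31.46, 60.90] and band reflectance is
generated by inverting the published CIG calibration
(SPAD = 24.001·10^0.333·CIG^) for ρ~Nir~/ρ~Green~, plus Gaussian band
noise (σ = 0.01); the reflectance-SPAD link is therefore invertible by
construction, which makes SPAD-recovery tests well-posed. Depth noise is
additive Gaussian with σ = 1.5 mm (typical time-of-flight jitter), and
depth is quantized to integer millimeters as a 16-bit PNG would store it.

Rendering projects every surface point and z-buffers per pixel, with two
deliberate refinements: the pixel's depth is the mean over the winning
surface's samples inside the pixel (within 3 mm of the nearest), and the
pixel's color/reflectance comes from the sample nearest that mean. A
nearest-sample-wins buffer would systematically pull every surface
toward the camera-near edge of the pixel footprint (several mm at
oblique incidence), which a real integrating pixel does not do.
Background pixels show the white imaging-room wall (reflectance 0.85) in
the spectral bands and carry no depth return.

What the generator does **not** emulate: mixed pixels inside one sensor
element (each pixel sees one surface), multi-path and flying-pixel
artifacts of time-of-flight sensors, specular reflectance, radiative
transfer within leaves, illumination gradients, and motion blur. Passing
the synthetic suite therefore demonstrates the geometry and algebra of
the pipeline — axis calibration to < 3 mm / < 1°, similarity recovery to
(0.5 px, 1°, 3%), fused-surface RMS < 3 mm, exact index algebra and
SPAD-model identification — not robustness to every real-sensor
pathology. Published real-data summary tables (per-band standard
deviations, CVs, point-count shares, and the R²/RMSE of the printed
calibrations) depend on a 60-plant dataset that is not available and are
reproduced only structurally.

A note on calibration practice: axis calibration images the *bare*
table. With the plant present, the pot can clip a sticker's inner edge
and bias its centroid by a few millimeters; the 180°-midpoint
construction cancels most of that bias for the axis center, so
plant-present self-calibration still recovers the axis within
tolerance, but bare-table imaging is the cleaner protocol and is what
the sticker-accuracy checks use.

## Problem sizes used in validation

The default test scene renders ~2,400 valid depth pixels per view
(four views, 90° apart), fusing to a model of ~9,000 points before the
canopy cut; the reconstruction error is measured against the same scene
resampled at 4× point density. Registration checks use 128×128
band-limited random textures (20 random transforms, 50 random integer
shifts); axis calibration is repeated over 20 random camera poses;
index identities are checked on 10^6^ random reflectance draws; SPAD
recovery uses n = 60 observations × 100 noise realizations. These sizes
keep the full suite under a minute while leaving every tolerance
comfortably non-trivial.

## Worked example

```{r example, eval = FALSE}
scene <- make_scene(seed = 5)
views <- lapply(0:3, function(k) render_view(scene, k * 90))
res <- run_pipeline(views)

res$reg_transform       # recovered spectral-to-depth similarity
res$calib               # recovered turntable axis
nrow(res$model)         # fused canopy points
head(res$stats)         # per-band/index canopy statistics

## SPAD calibration from canopy means against meter readings
## (x: canopy-mean CIG per plant; y: mean SPAD per plant)
fit <- spad_fit(x, y, "M3", index_name = "CIG")
```

## Known limitations

* Sequential pairwise ICP accumulates drift around the loop; there is no
  global pose-graph optimization or loop closure (out of scope).
* One depth frame per view; multi-frame temporal averaging per view
  would reduce sensor noise further.
* The PLY reader supports the vertex-only layout this package writes,
  not arbitrary PLY.
* Registration assumes the two sensors share an approximately fronto-
  parallel view of the scene so that a 2D similarity suffices; strong
  perspective differences between the sensors would require a projective
  model, which is out of scope.
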