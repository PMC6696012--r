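# ms3d — multispectral 3D point-cloud measurement of plant canopies

`ms3d` builds multispectral 3D point-cloud models of potted plants
imaged on a motorized turntable by an RGB-D camera together with a
co-mounted narrow-band reflectance imager, and derives chlorophyll
(SPAD) calibrations from the fused canopy cloud. It is aimed at plant
phenotyping work where single-view canopy reflectance is too unstable to
calibrate against: each viewpoint sees a different subset of a plant's
3D architecture, so the package fuses views taken 360°/V_N apart into
one canopy model and computes vegetation indices per 3D point.

The pipeline:

1. **Spectral-to-depth registration.** The reflectance imager's grid
   differs from the depth grid by an unknown 2D similarity transform.
   Translation is estimated by phase correlation — the inverse FFT of
   the normalized cross-power spectrum
   `M(ξ,η)F*(ξ,η)/|M(ξ,η)F*(ξ,η)| = exp(−j2π(ξx₀ + ηy₀))`
   peaks at the shift (x₀, y₀) — and rotation θ₀/scale σ by the
   Fourier–Mellin method: on a log-polar resampling of the Fourier
   magnitude, `F(log ρ, θ) = M(log ρ − log σ, θ − θ₀)`, so the same
   phase correlation recovers both. One calibrated transform maps every
   band of the reflectance cube onto the depth grid.
2. **Turntable self-calibration.** Two colored stickers on the table
   are detected by an HSV threshold and observed at rotations 0° and
   180°; the sticker midpoints give the axis center M = (a₀, b₀, c₀)
   and the table plane gives the unit axis normal P = (a, b, c).
3. **Rough registration.** Depth pixels unproject through the pinhole
   model (x = (i − cₓ)z/fₓ, y = −(j − c_y)z/f_y, z = Depth(i,j)/1000);
   each view is translated by −M, rotated so P ↦ (0, 1, 0), and rotated
   about Y by its inverse table angle γ, putting all views in one frame.
4. **Precise registration.** Sequential point-to-point ICP
   (distance-gated nearest neighbors + closed-form SVD rigid fit) fuses
   the views; the concatenation is voxel-downsampled to the 3DROI model.
5. **Indices and SPAD.** Nine vegetation indices (NDVI, GNDVI, NDVIR,
   CIG, RCIG, NG, NR, RVI, GRVI) are computed per point; canopy means
   feed SPAD calibration models of four prototype forms (linear,
   quadratic, exponential c·10^(k·x), power c·x^k), and a registry of
   published 3DROI calibration equations is served verbatim.

A synthetic-scene generator (`make_scene`, `render_view`) produces
turntable scenes with full ground truth — axis, per-view poses, the
spectral offset transform, per-point SPAD and labels — so the whole
pipeline is testable without any external data.

## Worked example

```r
library(ms3d)
scene <- make_scene(seed = 5)                 # synthetic turntable scene
views <- lapply(0:3, function(k) render_view(scene, k * 90))
res <- run_pipeline(views)

res$reg_transform
#> 2D similarity transform: dx=8.002 px, dy=-5.002 px, theta0=3.862 deg,
#>   sigma=0.8551 (peak response 0.762)
res$calib
#> turntable axis: center (0.0202, -0.0995, 1.0497) m,
#>   normal (0.0298, 0.8647, -0.5015), residual 8.44e-05 m
```

The scene's true offset is (8 px, −5 px, 4°, 0.85) and its true axis
center is (0.02, −0.10, 1.05) m — both recovered to a few hundredths of
a pixel / about a millimetre. The four views contribute 2,383–2,506
points each; fusion yields an 8,813-point model, 3,359 of them canopy:

```r
head(res$stats)
#>      variable   mean     std cv_percent n_points
#> 1    rho_blue 0.1134 0.09193      81.07     3359
#> 2   rho_green 0.2093 0.08167      39.03     3359
#> 3     rho_red 0.1272 0.09047      71.11     3359
#> 4 rho_rededge 0.2263 0.08016      35.43     3359
#> 5     rho_nir 0.3242 0.07505      23.15     3359
#> 6    idx_NDVI 0.4898 0.17593      35.92     3359

m <- spad_paper_model("CIG")
#> SPAD model M3 (CIG): SPAD = 24.001 * 10^(0.333 x)  [R^2 = 0.9443, RMSE = 0.8508]
spad_predict(m, mean(res$model$idx_CIG, na.rm = TRUE))
#> [1] 39.04175
```

The last number is the canopy-level SPAD estimate from the fused
model's mean CIG. `res$spad_cloud` carries the same prediction per
point for spatial SPAD maps, and `run_pipeline(..., output_dir = ...)`
writes `model.ply`, `stats.csv`, `spad.ply` and a JSON run report.

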