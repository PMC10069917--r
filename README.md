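# specpcd — illumination-corrected 3D multispectral point clouds of plants

Close-range spectral imaging of plants mixes the signal of interest —
per-band tissue reflectance — with the local illumination state: distance
to the lamp, incidence angle, viewing angle. A flat white reference
corrects one illumination state per frame, so leaves at other heights and
inclinations come out wrong, and the same leaf changes its apparent
spectrum from view to view. `specpcd` implements a pipeline that removes
this effect with a *geometric* reference and produces 3D point clouds
whose points carry corrected 25-band spectra:

1. **Registration** — the snapshot multispectral image (25 bands,
   650–950 nm) is registered onto the RGB-D frame: HSV/depth and NDVI
   foreground segmentation, histogram matching, adaptive SURF coarse
   registration (a grid of Hessian-response and descriptor-distance
   thresholds scored by SSIM, shrunk around the best nodes), Demons
   nonrigid refinement, then one composed bicubic resampling of all bands.
2. **3D light-field features** — the depth image becomes an organized point
   cloud; 3×3 local-SVD plane fits give per-pixel normals; each pixel gets
   the descriptor (d_i, d_v, θ_i, θ_v, θ, x, y, z): distances to the light
   source and camera, incidence / viewing angles, the in-plane azimuth
   between both directions, and position.
3. **Reference model** — matte hemispheres imaged at 70 rig poses sample
   reference DN across positions and orientations; a shallow network
   (8 inputs → 20 sigmoid units → 25 linear outputs, 70/15/15 split,
   min–max normalization) or a nearest-neighbour search (Euclidean,
   weighted Euclidean, cosine, Mahalanobis, Chebychev, PCA-cosine,
   weighted Mahalanobis) predicts the reference DN for every plant pixel.
4. **Correction** — `R(p,b) = ρ_ref(b) · DN_plant(p,b) / DN_ref(p,b)`
   cancels the shared illumination factor; implausible pixels (negative
   bands, values near 0 or above 0.8) are masked; survivors are exported
   as PLY point clouds with per-vertex `refl_<wavelength>` properties.

A synthetic Lambertian scene renderer with analytic ground truth (domes,
leaf patches, a reflector-lamp illumination model, fabricated registration
pairs with known warps) replaces the physical rig, so the full pipeline is
testable offline. See the vignette
(`vignettes/multispectral-point-clouds.Rmd`) for the model details and
design rationale.

## Worked example

Train a reference model on a simulated hemisphere session, correct a
15-view leaf scene, and measure the result against the planted albedo:

```r
library(specpcd)

cfg <- default_config()
cfg$cameras$ms <- list(fx = 205, fy = 205, cx = 102, cy = 53.5,
                       width = 205L, height = 108L)
cfg$reference$reflectance <- 0.6          # measured matte-reference spectrum

illum <- rig_illumination(cfg, noise_frac = 0.01)
refs  <- render_reference_frames(cfg, illum = illum, seed = 11)
db    <- build_reference_db(refs, feature_set = 8L)
model <- train_ann(db, epochs = 500, seed = 5)
model
#> <reflectance_model 8-20-25, test R2 0.996 RMSE 0.0131>

views <- render_leaf_views(cfg, n_views = 15, illum = illum, seed = 21)
res   <- run_pipeline(views, model = model, cfg = cfg, out_dir = "out")

## per-pixel spectral RMSE against the planted albedo of view 1
cube <- res[[1]]$cube
err2 <- Reduce(`+`, lapply(1:25, function(b)
  (cube$reflectance[, , b] - views[[1]]$gt$albedo[, , b])^2))
median(sqrt(err2[cube$mask] / 25))
#> [1] 0.037
```

The printed model line reports the held-out fit of the reference network
(R² of normalized DN); the final number is the median per-pixel spectral
RMSE of corrected reflectance for the first (most rotated, hardest) view —
a few hundredths of a reflectance unit, versus leaf albedo plateaus of
0.45–0.65 and flat-reference errors an order of magnitude larger. `out/`
receives one PLY per view plus a JSON manifest.

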