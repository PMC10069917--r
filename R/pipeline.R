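## End-to-end orchestration: registered plant frame + reference model ->
## corrected reflectance cube -> outlier masking -> multispectral point
## cloud, per view; plus synthetic-rig conveniences that render the
## hemisphere reference database and multiview leaf scenes the physical
## setup would provide.

#' Render the hemisphere reference frames of a synthetic rig session
#'
#' One frame per hemisphere pose of [make_hemisphere_layout()], rendered
#' with the configured camera and illumination; each frame carries the
#' depth-derived light-field features (the pipeline's own normal
#' estimation, not the analytic ground truth), the DN stack and the
#' reference foreground mask.
#'
#' @param cfg configuration list
#' @param intrinsics camera used for the reference session (defaults to
#'   the multispectral camera of `cfg`)
#' @param illum an [illumination_model]
#' @param seed base RNG seed (per-frame noise seeds derive from it)
#' @return list of frames suitable for [build_reference_db()]
#' @export
render_reference_frames <- function(cfg = default_config(), intrinsics = NULL,
                                    illum = illumination_model(noise_sd = 0),
                                    seed = 1L) {
  K <- intrinsics %||% with(cfg$cameras$ms,
                            camera_intrinsics(fx, fy, cx, cy, width, height))
  geom <- scene_geometry(cfg$scene$light_position, cfg$scene$camera_position)
  poses <- make_hemisphere_layout(cfg$reference$n_vertical,
                                  cfg$reference$n_horizontal,
                                  cfg$reference$plant_height_m,
                                  cfg$reference$horizontal_span_m,
                                  cfg$reference$diameter_m,
                                  cfg$scene$working_distance_m,
                                  albedo = 0.6,
                                  pitch_deg = cfg$scene$pitch_deg)
  wl <- cfg$bands$wavelengths
  lapply(seq_along(poses), function(i) {
    sc <- render_scene(list(poses[[i]]), K, geom, illum, wl,
                       seed = seed * 1000L + i)
    lf <- lightfield_features(sc$depth, K, geom, cfg)
    list(features = lf$features, dn = sc$ms$dn,
         mask = sc$gt$mask & lf$valid, gt = sc$gt, depth = sc$depth,
         cloud = lf$cloud)
  })
}

#' Render a multiview leaf scene session
#'
#' The same pseudo-random leaf arrangement viewed under `n_views`
#' sample-holder rotations spanning `rotation_span_deg`; each view carries
#' depth, DN stack, depth-derived features, the leaf foreground mask and
#' the renderer's ground truth (per-leaf ids and planted albedo).
#'
#' @param cfg configuration list
#' @param n_views number of views (default 15)
#' @param rotation_span_deg total rotation span, centred on zero
#' @param n_leaves leaves in the scene
#' @param albedo_bank list of per-band albedo spectra (defaults to three
#'   vegetation-like spectra)
#' @param intrinsics camera (defaults to the multispectral camera)
#' @param illum an [illumination_model]
#' @param seed scene + noise seed
#' @return list of view frames
#' @export
render_leaf_views <- function(cfg = default_config(), n_views = 15L,
                              rotation_span_deg = 90, n_leaves = 6L,
                              albedo_bank = NULL, intrinsics = NULL,
                              illum = illumination_model(noise_sd = 0),
                              seed = 1L) {
  K <- intrinsics %||% with(cfg$cameras$ms,
                            camera_intrinsics(fx, fy, cx, cy, width, height))
  geom <- scene_geometry(cfg$scene$light_position, cfg$scene$camera_position)
  wl <- cfg$bands$wavelengths
  albedo_bank <- albedo_bank %||% default_albedo_bank(wl)
  angles <- if (n_views == 1) 0 else
    seq(-rotation_span_deg / 2, rotation_span_deg / 2, length.out = n_views)
  lapply(seq_len(n_views), function(v) {
    prims <- make_leaf_scene(n_leaves, albedo_bank,
                             seed = seed, view_rotation_deg = angles[v],
                             distance_m = cfg$scene$working_distance_m,
                             pitch_deg = cfg$scene$pitch_deg)
    sc <- render_scene(prims, K, geom, illum, wl, seed = seed * 2000L + v)
    lf <- lightfield_features(sc$depth, K, geom, cfg)
    list(features = lf$features, dn = sc$ms$dn,
         mask = sc$gt$mask & lf$valid, gt = sc$gt, depth = sc$depth,
         cloud = lf$cloud, view_angle_deg = angles[v])
  })
}

#' Vegetation-like albedo spectra for the synthetic leaves
#'
#' Smooth red-edge shaped spectra over the configured bands: low red
#' reflectance rising to a near-infrared plateau, at three plateau levels.
#'
#' @param wavelengths band centres (nm)
#' @return list of per-band albedo vectors
#' @export
default_albedo_bank <- function(wavelengths) {
  edge <- function(plateau, mid = 715, width = 16) {
    0.06 + (plateau - 0.06) / (1 + exp(-(wavelengths - mid) / width))
  }
  list(edge(0.45), edge(0.55), edge(0.65))
}

#' DN spectrum of a flat reference at the canopy position
#'
#' Renders a fronto-parallel matte reference plane at the stage centre and
#' returns its mean DN spectrum: the conventional whiteboard measurement
#' the baseline correction divides by.
#'
#' @param cfg configuration list
#' @param intrinsics camera (defaults to the multispectral camera)
#' @param illum an [illumination_model]
#' @param albedo reference plane albedo (0.99 whiteboard-like)
#' @return length-B DN spectrum
#' @export
render_flat_reference_dn <- function(cfg = default_config(), intrinsics = NULL,
                                     illum = illumination_model(noise_sd = 0),
                                     albedo = 0.99) {
  K <- intrinsics %||% with(cfg$cameras$ms,
                            camera_intrinsics(fx, fy, cx, cy, width, height))
  geom <- scene_geometry(cfg$scene$light_position, cfg$scene$camera_position)
  ctr <- c(0, 0, cfg$scene$working_distance_m)
  plane <- surface_primitive("planar_leaf", ctr, albedo,
                             radius = 0.10, axis = -ctr / vec_norm(ctr),
                             rgb = c(0.95, 0.95, 0.95), id = 1L)
  sc <- render_scene(list(plane), K, geom, illum, cfg$bands$wavelengths,
                     seed = NULL)
  apply(sc$ms$dn, 3, function(m) mean(m[sc$gt$mask]))
}

#' Correct one aligned view against a reference model or database
#'
#' The view's light-field features drive either the ANN prediction or the
#' nearest-neighbour search of the reference DN; the plant DN is then
#' ratio-corrected, outlier-masked and mapped onto the point cloud.
#'
#' @param view a frame from [render_leaf_views()] (or any list with
#'   `features`, `dn`, `mask`, `cloud`)
#' @param model a [train_ann()] model (for `method = "ann"`)
#' @param db a [build_reference_db()] database (for `method = "search"`)
#' @param method "ann" or "search"
#' @param metric search metric (when `method = "search"`)
#' @param cfg configuration list
#' @param stats optional [db_search_stats()]
#' @param max_db_rows optional search db cap
#' @return list: `cube` (outlier-masked `reflectance_cube`), `cloud`
#'   ([ms_point_cloud]), `ref_dn`
#' @export
correct_view <- function(view, model = NULL, db = NULL,
                         method = c("ann", "search"), metric = "euclidean",
                         cfg = default_config(), stats = NULL,
                         max_db_rows = NULL) {
  method <- match.arg(method)
  ref <- if (method == "ann") {
    if (is.null(model)) stopf("method 'ann' needs a trained model")
    predict_reference_dn(model, view$features, view$mask)
  } else {
    if (is.null(db)) stopf("method 'search' needs a reference database")
    search_reference_dn(db, view$features, view$mask, metric,
                        stats = stats, max_db_rows = max_db_rows)
  }
  mask <- view$mask
  if (method == "ann" && isTRUE(cfg$model$mask_extrapolated))
    mask <- mask & !ref$extrapolated
  cube <- correct_reflectance(view$dn, ref$dn, cfg$reference$reflectance,
                              mask)
  cube <- mask_outliers(cube, cfg$outliers$low, cfg$outliers$high,
                        cfg$outliers$band_fraction, cfg$outliers$clip)
  cloud <- make_multispectral_cloud(view$cloud, cube, cfg$bands$wavelengths)
  list(cube = cube, cloud = cloud, ref_dn = ref$dn)
}

#' Mean reflectance curve per leaf per view
#'
#' Groups a corrected view's pixels by the renderer's leaf ids and returns
#' the per-leaf mean spectrum, the input to the multiview distance-range
#' evaluation.
#'
#' @param cube a `reflectance_cube`
#' @param id_map H x W integer leaf id map (0 = background)
#' @return matrix with one row per leaf id present (rownames = ids)
#' @export
leaf_mean_curves <- function(cube, id_map) {
  ids <- sort(setdiff(unique(as.vector(id_map[cube$mask])), 0))
  B <- dim(cube$reflectance)[3]
  out <- matrix(NA_real_, length(ids), B)
  for (i in seq_along(ids)) {
    sel <- cube$mask & id_map == ids[i]
    if (!any(sel)) next
    out[i, ] <- vapply(seq_len(B),
                       function(b) mean(cube$reflectance[, , b][sel]), 0)
  }
  rownames(out) <- ids
  out
}

#' Register a frame pair and return the registered multispectral stack
#'
#' Runs the full coarse-to-fine chain on one [frame_pair]: preprocessing
#' (segmentation + histogram matching), adaptive SURF coarse registration,
#' Demons refinement, and single-resampling application of the composed
#' warp to all bands.
#'
#' @param frame a [frame_pair]
#' @param cfg configuration list
#' @return list: `ms_registered` ([ms_stack] on the RGB-D grid),
#'   `transform`, `field`, `coarse`, `fine`, `pre`
#' @export
register_frame <- function(frame, cfg = default_config()) {
  pre <- preprocess_frame(frame, cfg)
  co <- adaptive_register(pre$fixed, pre$moving, cfg$surf$transform_kind,
                          cfg$surf$grid_i, cfg$surf$grid_j, cfg$surf$e1,
                          cfg$surf$max_rounds, cfg)
  ## the paper re-balances brightness of the coarse-registered image before
  ## the nonrigid stage
  warped_bal <- histogram_match(co$warped, pre$fixed,
                                cfg$preprocess$histogram_levels,
                                mask = co$warped > 0, fixed_mask = pre$fixed > 0)
  fi <- demons_register(pre$fixed, warped_bal, cfg$demons$alpha,
                        cfg$demons$sigma_d, cfg$demons$e2,
                        cfg$demons$max_iters, cfg)
  msr <- apply_full_registration(frame$ms, co$transform, fi$field)
  list(ms_registered = msr, transform = co$transform, field = fi$field,
       coarse = co, fine = fi, pre = pre)
}

#' Run the full pipeline over a list of views
#'
#' For each view: (already-aligned inputs) light-field features ->
#' reference DN prediction -> ratio correction -> outlier masking -> point
#' cloud; optionally written as PLY files plus a JSON manifest. Views that
#' fail are reported in the manifest and skipped.
#'
#' @param views list of aligned view frames (see [render_leaf_views()])
#' @param model trained [train_ann()] model (or NULL with `db`)
#' @param db reference database for search-based correction
#' @param method "ann" or "search"
#' @param cfg configuration list
#' @param out_dir optional output directory for PLY + manifest
#' @param metric search metric
#' @return list of per-view results (see [correct_view()]), with a
#'   `manifest` attribute
#' @export
run_pipeline <- function(views, model = NULL, db = NULL,
                         method = c("ann", "search"),
                         cfg = default_config(), out_dir = NULL,
                         metric = "euclidean") {
  method <- match.arg(method)
  stats <- if (method == "search") db_search_stats(db) else NULL
  results <- list(); manifest <- list()
  for (v in seq_along(views)) {
    res <- tryCatch(
      correct_view(views[[v]], model, db, method, metric, cfg, stats),
      error = function(e) e)
    if (inherits(res, "error")) {
      manifest[[v]] <- list(view = v, status = "failed",
                            message = conditionMessage(res))
      next
    }
    manifest[[v]] <- list(view = v, status = "ok",
                          n_points = nrow(res$cloud$points),
                          n_outliers = res$cube$n_outliers)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_multispectral_ply(res$cloud,
                              file.path(out_dir, sprintf("view_%03d.ply", v)))
    }
    results[[v]] <- res
  }
  if (!is.null(out_dir))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  attr(results, "manifest") <- manifest
  results
}
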