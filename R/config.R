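#' Default pipeline configuration
#'
#' Every tunable parameter of the pipeline lives under a named key; user
#' config files (YAML or JSON) override a subset and unknown keys are
#' rejected. Geometry is metres, angles degrees in the config (converted to
#' radians internally where needed).
#'
#' @return nested named list of defaults
#' @export
default_config <- function() {
  list(
    cameras = list(
      ## RGB-D sensor (depth pixel-registered with RGB)
      rgbd = list(fx = 610, fy = 610, cx = 639.5, cy = 359.5,
                  width = 1280L, height = 720L),
      ## snapshot multispectral camera (lower resolution)
      ms = list(fx = 410, fy = 410, cx = 204, cy = 107.5,
                width = 409L, height = 216L)
    ),
    scene = list(
      light_position = c(0.0, -0.30, 0.10),   # metres, camera frame
      camera_position = c(0.0, 0.0, 0.0),
      pitch_deg = 40,                         # rig pitch, informational
      working_distance_m = 0.75
    ),
    bands = list(
      n = 25L,
      wavelengths = seq(650, 950, length.out = 25),
      red_nm = 665,        # NDVI red band (closest band centre used)
      nir_nm = 800,        # NDVI NIR band
      registration_band = 7L   # 740.7 nm band used as the moving image
    ),
    preprocess = list(
      hsv_h = c(60, 180), hsv_s_min = 0.15, hsv_v_min = 0.05,
      depth_range_m = c(0.4, 1.5),
      ndvi_threshold = 0.3,
      morph_radius = 1L, min_blob_px = 25L,
      histogram_levels = 256L
    ),
    ssim = list(
      window = 11L, sigma = 1.5, k1 = 0.01, k2 = 0.03,
      dynamic_range = 1.0, on_foreground = TRUE
    ),
    surf = list(
      hessian_w = 0.9,
      hessian_w_mode = "squared",  # (w*Dxy)^2; "linear" gives w*Dxy^2 as printed
      filter_sizes = c(9L, 15L, 21L, 27L),
      grid_i = 10L, grid_j = 10L,
      e1 = 0.01, max_rounds = 5L,
      transform_kind = "affine",
      ransac_iters = 200L, ransac_tol_px = 2.0
    ),
    demons = list(
      alpha = 1.0, eps_den = 1e-9, sigma_d = 1.0,
      e2 = 0.001, max_iters = 100L
    ),
    lightfield = list(
      window = 3L, depth_discontinuity_m = 0.010, eps_proj = 1e-9
    ),
    model = list(
      feature_set = 8L,            # 3 (x,y,z), 5 (angles+distances) or 8
      hidden_units = 20L,
      split = c(0.70, 0.15, 0.15),
      epochs = 500L,
      split_mode = "pixel",        # or "frame"
      mask_extrapolated = TRUE     # drop pixels outside the training hull
    ),
    reference = list(
      diameter_m = 0.100,          # Teflon hemisphere diameter
      reflectance = 1.0,           # scalar or length-B spectrum; 1 = raw DN ratio
      n_vertical = 10L, n_horizontal = 7L,
      plant_height_m = 0.5,
      horizontal_span_m = 0.30
    ),
    outliers = list(
      low = 0.01, high = 0.8, band_fraction = 0.2, clip = FALSE
    )
  )
}

merge_config <- function(base, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(base))
      stopf("unknown config key: '%s'", full)
    if (is.list(base[[key]]) && !is.null(names(base[[key]]))) {
      if (!is.list(user[[key]]))
        stopf("config key '%s' must be a mapping", full)
      base[[key]] <- merge_config(base[[key]], user[[key]], full)
    } else {
      base[[key]] <- user[[key]]
    }
  }
  base
}

validate_config <- function(cfg) {
  for (cam in c("rgbd", "ms")) {
    p <- cfg$cameras[[cam]]
    ## constructor performs the range checks
    camera_intrinsics(p$fx, p$fy, p$cx, p$cy, p$width, p$height)
  }
  scene_geometry(cfg$scene$light_position, cfg$scene$camera_position)
  if (any(diff(cfg$bands$wavelengths) <= 0))
    stopf("bands.wavelengths must be strictly increasing")
  if (cfg$surf$hessian_w <= 0) stopf("surf.hessian_w must be > 0")
  if (!cfg$surf$hessian_w_mode %in% c("squared", "linear"))
    stopf("surf.hessian_w_mode must be 'squared' or 'linear'")
  if (cfg$demons$alpha <= 0) stopf("demons.alpha must be > 0")
  if (cfg$model$hidden_units < 1) stopf("model.hidden_units must be >= 1")
  if (!isTRUE(all.equal(sum(cfg$model$split), 1)))
    stopf("model.split must sum to 1")
  if (!cfg$model$feature_set %in% c(3L, 5L, 8L))
    stopf("model.feature_set must be 3, 5 or 8")
  if (cfg$outliers$low < 0 || cfg$outliers$low >= cfg$outliers$high)
    stopf("outliers bounds must satisfy 0 <= low < high")
  if (cfg$lightfield$window %% 2 != 1 || cfg$lightfield$window < 3)
    stopf("lightfield.window must be odd and >= 3")
  invisible(cfg)
}

#' Load and validate a pipeline configuration file
#'
#' Reads a YAML (or JSON) file, overlays it on [default_config()], rejects
#' unknown keys (with the offending key name) and validates ranges. An empty
#' or missing-keys file yields the full default configuration.
#'
#' @param path path to YAML/JSON config, or `NULL` for pure defaults
#' @return validated configuration list
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stopf("config file not found: %s", path)
    user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
    if (is.null(user)) user <- list()
    cfg <- merge_config(cfg, user)
  }
  validate_config(cfg)
  cfg
}
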