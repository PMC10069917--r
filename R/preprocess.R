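## Registration preprocessing: plant foreground extraction in both
## modalities, morphological cleanup, and brightness balancing of the
## moving image by histogram matching.

#' Segment the plant foreground in an RGB-D frame
#'
#' A pixel is kept iff its HSV colour lies inside the configured bounds AND
#' its depth lies inside `depth_range_m`; invalid depth is excluded. An
#' empty result is allowed (a warning is raised, not an error).
#'
#' @param rgb H x W x 3 array in `[0, 1]`
#' @param depth a [depth_image] or H x W matrix (metres, NA invalid)
#' @param hsv_h hue bounds in degrees `[0, 360)`
#' @param s_min,v_min minimum saturation / value
#' @param depth_range_m depth window (metres)
#' @return H x W logical mask
#' @export
segment_plant_rgbd <- function(rgb, depth, hsv_h = c(60, 180),
                               s_min = 0.15, v_min = 0.05,
                               depth_range_m = c(0.4, 1.5)) {
  dv <- if (inherits(depth, "depth_image")) depth$values else depth
  if (!all(dim(rgb)[1:2] == dim(dv))) stopf("rgb and depth dimensions differ")
  hsv <- grDevices::rgb2hsv(r = as.vector(rgb[, , 1]), g = as.vector(rgb[, , 2]),
                            b = as.vector(rgb[, , 3]), maxColorValue = 1)
  hdeg <- hsv[1, ] * 360
  keep <- hdeg >= hsv_h[1] & hdeg <= hsv_h[2] &
    hsv[2, ] >= s_min & hsv[3, ] >= v_min
  m <- matrix(keep, nrow(dv), ncol(dv))
  dok <- !is.na(dv) & dv >= depth_range_m[1] & dv <= depth_range_m[2]
  out <- m & dok
  if (!any(out)) warning("RGB-D segmentation produced an empty mask")
  out
}

#' Segment the plant foreground in a multispectral stack by NDVI
#'
#' NDVI = (DN_nir - DN_red) / (DN_nir + DN_red); pixels with
#' NDVI >= threshold are kept, zero-denominator pixels excluded.
#'
#' @param ms a [ms_stack] or H x W x B array
#' @param ndvi_threshold minimum NDVI
#' @param red_band,nir_band band indices (1-based)
#' @return H x W logical mask
#' @export
segment_plant_ms <- function(ms, ndvi_threshold = 0.3, red_band, nir_band) {
  dn <- if (inherits(ms, "ms_stack")) ms$dn else ms
  B <- dim(dn)[3]
  if (red_band < 1 || red_band > B || nir_band < 1 || nir_band > B)
    stopf("band index out of range 1..%d", B)
  if (red_band == nir_band) stopf("red and NIR bands must differ")
  red <- dn[, , red_band]; nir <- dn[, , nir_band]
  den <- nir + red
  ndvi <- (nir - red) / den
  mask <- !is.na(ndvi) & den > 0 & ndvi >= ndvi_threshold
  if (!any(mask)) warning("NDVI segmentation produced an empty mask")
  mask
}

## band index whose centre is closest to a target wavelength
closest_band <- function(wavelengths, target_nm) which.min(abs(wavelengths - target_nm))

#' Morphological cleanup of a foreground mask
#'
#' Opening with a disc structuring element followed by removal of
#' 8-connected components smaller than `min_blob_px`. Idempotent under
#' repeated application with the same parameters.
#'
#' @param mask H x W logical matrix
#' @param min_blob_px minimum connected-component area kept (pixels)
#' @param radius disc radius for the opening; 0 skips the opening
#' @return cleaned logical mask
#' @export
morph_clean <- function(mask, min_blob_px = 25L, radius = 1L) {
  if (radius < 0) stopf("radius must be >= 0")
  m <- mask * 1
  if (radius > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
    m <- EBImage::opening(m, brush)
  }
  if (min_blob_px > 0) {
    lab <- EBImage::bwlabel(m)
    sizes <- tabulate(lab[lab > 0])
    drop <- which(sizes < min_blob_px)
    if (length(drop)) m[lab %in% drop] <- 0
  }
  matrix(m > 0.5, nrow(mask), ncol(mask))
}

#' Match the grayscale histogram of a moving image to a fixed image
#'
#' Monotone intensity remap by CDF matching at `n_levels` quantization
#' bins; the output range is contained in the fixed image's range. When a
#' mask is given the mapping is estimated and applied on masked pixels only
#' (background left at zero).
#'
#' @param moving,fixed single-channel matrices (sizes may differ)
#' @param n_levels quantization levels for the CDFs
#' @param mask optional logical matrix (moving grid) restricting the
#'   remapped region; background is left at zero
#' @param fixed_mask optional logical matrix (fixed grid) restricting the
#'   reference histogram
#' @return matched version of `moving`
#' @export
histogram_match <- function(moving, fixed, n_levels = 256L, mask = NULL,
                            fixed_mask = NULL) {
  mv <- if (is.null(mask)) as.vector(moving) else moving[mask]
  fv <- if (is.null(fixed_mask)) as.vector(fixed) else fixed[fixed_mask]
  if (length(unique(fv)) < 2) stopf("fixed image is constant; cannot match histograms")
  rng_m <- range(mv); rng_f <- range(fv)
  if (rng_m[1] == rng_m[2]) {
    out_val <- stats::median(fv)
    out <- moving; out[] <- 0
    if (is.null(mask)) out[] <- out_val else out[mask] <- out_val
    return(out)
  }
  ## quantize the moving values, map each level through the fixed quantile
  ## at the moving CDF value
  q <- pmin(floor((mv - rng_m[1]) / (rng_m[2] - rng_m[1]) * (n_levels - 1)) + 1,
            n_levels)
  cdf <- cumsum(tabulate(q, n_levels)) / length(q)
  matched_levels <- stats::quantile(fv, probs = cdf, names = FALSE, type = 1)
  mapped <- matched_levels[q]
  out <- moving
  if (is.null(mask)) out[] <- mapped else { out[] <- 0; out[mask] <- mapped }
  out
}

#' Run the full registration preprocessing on a frame pair
#'
#' Extracts the fixed image (G channel of the RGB), the moving image (the
#' configured multispectral band), segments both modalities, cleans the
#' masks and histogram-matches the moving image to the fixed one on the
#' foreground.
#'
#' @param frame a [frame_pair]
#' @param cfg configuration list ([default_config()])
#' @return list: `fixed`, `moving` (matched, on the moving image's grid),
#'   `mask_fixed`, `mask_moving`
#' @export
preprocess_frame <- function(frame, cfg = default_config()) {
  p <- cfg$preprocess
  g <- frame$rgb[, , 2]
  mask_f <- segment_plant_rgbd(frame$rgb, frame$depth, p$hsv_h, p$hsv_s_min,
                               p$hsv_v_min, p$depth_range_m)
  mask_f <- morph_clean(mask_f, p$min_blob_px, p$morph_radius)
  wl <- frame$ms$wavelengths
  red_b <- closest_band(wl, cfg$bands$red_nm)
  nir_b <- closest_band(wl, cfg$bands$nir_nm)
  mask_m <- segment_plant_ms(frame$ms, p$ndvi_threshold, red_b, nir_b)
  mask_m <- morph_clean(mask_m, p$min_blob_px, p$morph_radius)
  mov <- frame$ms$dn[, , cfg$bands$registration_band]
  mov_scaled <- mov / max(mov)
  fixed_fg <- g; fixed_fg[!mask_f] <- 0
  mov_fg <- mov_scaled; mov_fg[!mask_m] <- 0
  matched <- histogram_match(mov_fg, fixed_fg, cfg$preprocess$histogram_levels,
                             mask = mask_m, fixed_mask = mask_f)
  list(fixed = fixed_fg, moving = matched,
       mask_fixed = mask_f, mask_moving = mask_m)
}
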