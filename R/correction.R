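## Reflectance correction and point-cloud assembly: per-pixel ratio of
## plant DN to the predicted reference DN, scaled by the reference's own
## reflectance spectrum; out-of-range outlier masking; mapping of the
## corrected cube onto the organized point cloud.

#' Correct plant DN to reflectance against predicted reference DN
#'
#' R(p, b) = ref_reflectance(b) * DN_plant(p, b) / DN_ref(p, b). With the
#' default ref_reflectance = 1 this is the raw DN percentage ratio;
#' supplying the measured reference spectrum (matte Teflon is ~0.60)
#' rescales to absolute reflectance. Pixels where the predicted reference
#' DN is nonpositive are masked and counted.
#'
#' @param plant_dn H x W x B registered plant DN ([ms_stack] or array)
#' @param ref_dn H x W x B predicted reference DN
#' @param ref_reflectance scalar or length-B reference reflectance
#' @param mask H x W logical foreground mask
#' @return list of class `reflectance_cube`: `reflectance` (H x W x B, NA
#'   outside mask), `mask`, `n_nonpositive_ref`
#' @export
correct_reflectance <- function(plant_dn, ref_dn, ref_reflectance = 1,
                                mask = NULL) {
  dn <- if (inherits(plant_dn, "ms_stack")) plant_dn$dn else plant_dn
  if (!all(dim(dn) == dim(ref_dn))) stopf("plant and reference grids differ")
  B <- dim(dn)[3]
  rr <- rep(ref_reflectance, length.out = B)
  if (is.null(mask)) mask <- matrix(TRUE, dim(dn)[1], dim(dn)[2])
  badref <- matrix(FALSE, dim(dn)[1], dim(dn)[2])
  for (b in seq_len(B)) badref <- badref | !is.finite(ref_dn[, , b]) | ref_dn[, , b] <= 0
  keep <- mask & !badref
  out <- array(NA_real_, dim(dn))
  for (b in seq_len(B)) {
    m <- rr[b] * dn[, , b] / ref_dn[, , b]
    m[!keep] <- NA_real_
    out[, , b] <- m
  }
  structure(list(reflectance = out, mask = keep,
                 n_nonpositive_ref = sum(mask & badref)),
            class = "reflectance_cube")
}

#' Mask physically implausible reflectance pixels
#'
#' A pixel is masked when any band is negative, or when more than
#' `band_fraction` of its bands fall outside `[low, high]` (negative
#' values, values close to zero and values above ~0.8 are the hallmarks of
#' specular highlights and reference-prediction breakdown). Surviving
#' pixels keep their values; with `clip = TRUE` their out-of-range bands
#' are clipped to the bounds instead of kept as-is.
#'
#' @param cube a `reflectance_cube` from [correct_reflectance()]
#' @param low,high plausibility bounds (defaults 0.01 and 0.8)
#' @param band_fraction tolerated fraction of out-of-range bands
#' @param clip clip surviving out-of-range bands to the bounds
#' @return the cube with the outlier pixels removed from `mask` and their
#'   values NA'd; adds `n_outliers`
#' @export
mask_outliers <- function(cube, low = 0.01, high = 0.8, band_fraction = 0.2,
                          clip = FALSE) {
  if (low < 0 || low >= high) stopf("bounds must satisfy 0 <= low < high")
  refl <- cube$reflectance
  B <- dim(refl)[3]
  neg <- matrix(FALSE, dim(refl)[1], dim(refl)[2])
  n_out <- matrix(0L, dim(refl)[1], dim(refl)[2])
  for (b in seq_len(B)) {
    v <- refl[, , b]
    neg <- neg | (!is.na(v) & v < 0)
    n_out <- n_out + (!is.na(v) & (v < low | v > high))
  }
  bad <- cube$mask & (neg | n_out > band_fraction * B)
  keep <- cube$mask & !bad
  for (b in seq_len(B)) {
    v <- refl[, , b]
    v[!keep] <- NA_real_
    if (clip) v <- clampv(v, low, high)
    refl[, , b] <- v
  }
  structure(list(reflectance = refl, mask = keep,
                 n_nonpositive_ref = cube$n_nonpositive_ref,
                 n_outliers = sum(bad)),
            class = "reflectance_cube")
}

#' Map a corrected reflectance cube onto the organized point cloud
#'
#' One point per pixel that is valid in the cloud AND inside the
#' foreground mask AND not outlier-masked, in row-major pixel order.
#'
#' @param cloud organized cloud from [depth_to_points()]
#' @param cube a `reflectance_cube`
#' @param wavelengths band centres (nm)
#' @param mask optional extra H x W mask (e.g. foreground)
#' @return a [ms_point_cloud]
#' @export
make_multispectral_cloud <- function(cloud, cube, wavelengths, mask = NULL) {
  keep <- cloud$valid & cube$mask
  if (!is.null(mask)) keep <- keep & mask
  ## row-major order: transpose the column-major index grid
  idx_rc <- which(t(keep))
  h <- dim(cube$reflectance)[1]; w <- dim(cube$reflectance)[2]
  rows <- ((idx_rc - 1) %/% w) + 1
  cols <- ((idx_rc - 1) %% w) + 1
  lin <- (cols - 1) * h + rows
  if (!length(lin)) stopf("no surviving points to export")
  B <- dim(cube$reflectance)[3]
  pts <- cbind(cloud$xyz[, , 1][lin], cloud$xyz[, , 2][lin], cloud$xyz[, , 3][lin])
  refl <- sapply(seq_len(B), function(b) cube$reflectance[, , b][lin])
  if (is.null(dim(refl))) refl <- matrix(refl, nrow = length(lin))
  ms_point_cloud(pts, refl, wavelengths)
}

#' Flat-reference baseline correction
#'
#' The conventional whiteboard calibration: every pixel's DN spectrum is
#' divided by one flat-reference DN spectrum for the whole frame (the
#' reference imaged at the canopy height), ignoring per-pixel geometry.
#' Serves as the uncorrected baseline the hemisphere method is compared
#' against.
#'
#' @param plant_dn H x W x B plant DN
#' @param flat_dn length-B flat-reference DN spectrum (> 0)
#' @param ref_reflectance scalar or length-B reference reflectance
#' @param mask H x W logical foreground mask
#' @return a `reflectance_cube`
#' @export
flat_reference_correction <- function(plant_dn, flat_dn, ref_reflectance = 1,
                                      mask = NULL) {
  dn <- if (inherits(plant_dn, "ms_stack")) plant_dn$dn else plant_dn
  B <- dim(dn)[3]
  if (length(flat_dn) != B) stopf("flat reference spectrum must have %d bands", B)
  if (any(flat_dn <= 0)) stopf("flat reference DN must be positive")
  ref <- array(rep(flat_dn, each = dim(dn)[1] * dim(dn)[2]), dim(dn))
  correct_reflectance(dn, ref, ref_reflectance, mask)
}
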