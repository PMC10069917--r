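## Core domain types. Conventions used throughout the package:
##  * images are H x W matrices (row = y, col = x); pixel centres sit at
##    0-based integer coordinates (x = col - 1, y = row - 1)
##  * all geometry is in metres, camera frame: x right, y down, z forward,
##    camera optical centre at the origin; the world frame coincides with the
##    camera frame (static rig)
##  * unit conversions (e.g. millimetre depth PNGs) happen only at I/O
##    boundaries

#' Camera intrinsics for an ideal pinhole model
#'
#' @param fx,fy focal lengths in pixels (> 0)
#' @param cx,cy principal point in pixels, 0-based
#' @param width,height image size in pixels
#' @return object of class `camera_intrinsics`
#' @export
camera_intrinsics <- function(fx, fy, cx, cy, width, height) {
  for (v in list(fx, fy, cx, cy, width, height))
    if (!is_num_scalar(v)) stopf("intrinsics fields must be finite scalars")
  if (fx <= 0 || fy <= 0) stopf("focal lengths must be positive (fx=%g, fy=%g)", fx, fy)
  if (cx < 0 || cx >= width) stopf("cx=%g outside [0, width)", cx)
  if (cy < 0 || cy >= height) stopf("cy=%g outside [0, height)", cy)
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy,
                 width = as.integer(width), height = as.integer(height)),
            class = "camera_intrinsics")
}

#' Scene geometry: positions of the light source and camera
#'
#' @param light_position 3-vector, metres, camera frame
#' @param camera_position 3-vector, metres (conventionally the origin)
#' @return object of class `scene_geometry`
#' @export
scene_geometry <- function(light_position, camera_position = c(0, 0, 0)) {
  light_position <- as.numeric(light_position)
  camera_position <- as.numeric(camera_position)
  if (length(light_position) != 3 || !all(is.finite(light_position)))
    stopf("light_position must be a finite 3-vector")
  if (length(camera_position) != 3 || !all(is.finite(camera_position)))
    stopf("camera_position must be a finite 3-vector")
  if (all(light_position == camera_position))
    stopf("light_position must differ from camera_position")
  structure(list(light_position = light_position,
                 camera_position = camera_position),
            class = "scene_geometry")
}

#' Depth image (metres, invalid pixels NA)
#'
#' @param values H x W matrix of z-depths in metres; invalid pixels NA (0 on
#'   disk maps to NA)
#' @return object of class `depth_image`
#' @export
depth_image <- function(values) {
  if (!is.matrix(values)) stopf("depth values must be a matrix")
  if (any(values <= 0, na.rm = TRUE)) stopf("valid depth values must be > 0")
  structure(list(values = values), class = "depth_image")
}

#' Multispectral digital-number stack
#'
#' @param dn H x W x B array of nonnegative digital numbers
#' @param wavelengths length-B vector of band centres (nm), strictly increasing
#' @return object of class `ms_stack`
#' @export
ms_stack <- function(dn, wavelengths) {
  if (length(dim(dn)) != 3) stopf("dn must be an H x W x B array")
  if (dim(dn)[3] != length(wavelengths))
    stopf("band count %d != wavelength count %d", dim(dn)[3], length(wavelengths))
  if (any(diff(wavelengths) <= 0)) stopf("wavelengths must be strictly increasing")
  if (any(dn < 0, na.rm = TRUE)) stopf("digital numbers must be nonnegative")
  structure(list(dn = dn, wavelengths = as.numeric(wavelengths)),
            class = "ms_stack")
}

#' One view's depth + RGB + multispectral frame pair
#'
#' @param rgb H x W x 3 array in `[0, 1]`
#' @param depth a [depth_image]
#' @param ms a [ms_stack] (may differ in size until registered)
#' @param view_id label for the view
#' @return object of class `frame_pair`
#' @export
frame_pair <- function(rgb, depth, ms, view_id = "view") {
  stopifnot(inherits(depth, "depth_image"), inherits(ms, "ms_stack"))
  if (length(dim(rgb)) != 3 || dim(rgb)[3] != 3) stopf("rgb must be H x W x 3")
  if (!all(dim(rgb)[1:2] == dim(depth$values)))
    stopf("rgb and depth dimensions differ")
  structure(list(rgb = rgb, depth = depth, ms = ms, view_id = view_id),
            class = "frame_pair")
}

#' Multispectral point cloud
#'
#' @param points M x 3 matrix of coordinates (metres)
#' @param reflectance M x B matrix of reflectance values
#' @param wavelengths length-B band centres (nm)
#' @return object of class `ms_point_cloud`
#' @export
ms_point_cloud <- function(points, reflectance, wavelengths) {
  points <- as.matrix(points); reflectance <- as.matrix(reflectance)
  if (ncol(points) != 3) stopf("points must be M x 3")
  if (nrow(points) < 1) stopf("point cloud must contain at least one point")
  if (nrow(reflectance) != nrow(points))
    stopf("points (%d) and reflectance (%d) row counts differ",
          nrow(points), nrow(reflectance))
  if (ncol(reflectance) != length(wavelengths))
    stopf("reflectance bands != wavelengths")
  if (!all(is.finite(points)) || !all(is.finite(reflectance)))
    stopf("point cloud contains non-finite rows; drop masked rows first")
  structure(list(points = points, reflectance = reflectance,
                 wavelengths = as.numeric(wavelengths)),
            class = "ms_point_cloud")
}

#' @export
print.camera_intrinsics <- function(x, ...) {
  cat(sprintf("<camera_intrinsics %dx%d fx=%.1f fy=%.1f cx=%.1f cy=%.1f>\n",
              x$width, x$height, x$fx, x$fy, x$cx, x$cy))
  invisible(x)
}

#' @export
print.ms_point_cloud <- function(x, ...) {
  cat(sprintf("<ms_point_cloud %d points, %d bands (%.1f-%.1f nm)>\n",
              nrow(x$points), length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}
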