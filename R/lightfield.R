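## Organized point clouds from depth images and the eight per-pixel 3D
## light-field features: distances to light source and camera, incidence /
## viewing / projected-azimuth angles from local-SVD plane normals, and the
## 3D coordinates themselves.

#' Backproject a depth image into an organized point cloud
#'
#' Pinhole model: x = (u - cx) z / fx, y = (v - cy) z / fy, z = depth, with
#' (u, v) 0-based pixel coordinates. Invalid depth gives invalid points.
#'
#' @param depth a [depth_image] or H x W matrix (metres, NA invalid)
#' @param intrinsics a [camera_intrinsics] matching the depth grid
#' @return list: `xyz` (H x W x 3), `valid` (H x W logical)
#' @export
depth_to_points <- function(depth, intrinsics) {
  z <- if (inherits(depth, "depth_image")) depth$values else depth
  K <- intrinsics
  if (!all(dim(z) == c(K$height, K$width)))
    stopf("depth is %d x %d but intrinsics declare %d x %d",
          nrow(z), ncol(z), K$height, K$width)
  h <- nrow(z); w <- ncol(z)
  u <- matrix(rep(0:(w - 1), each = h), h, w)
  v <- matrix(rep(0:(h - 1), w), h, w)
  xyz <- array(NA_real_, c(h, w, 3))
  xyz[, , 1] <- (u - K$cx) * z / K$fx
  xyz[, , 2] <- (v - K$cy) * z / K$fy
  xyz[, , 3] <- z
  list(xyz = xyz, valid = !is.na(z))
}

#' Estimate per-pixel normals by local SVD plane fitting
#'
#' For every valid pixel, the valid points inside the sliding window
#' (default 3 x 3) are gathered; window neighbours lying further than
#' `depth_discontinuity_m` in depth from the centre are rejected (window
#' neighbours are adjacent in the image but not necessarily in space,
#' which otherwise biases normals at leaf edges). With at least 3 points
#' the centroid is subtracted and the singular vector of least singular
#' value of the local scatter is taken as the plane normal, flipped to
#' face the camera.
#'
#' @param cloud organized cloud from [depth_to_points()]
#' @param window odd window size >= 3
#' @param depth_discontinuity_m neighbour rejection threshold (metres)
#' @return list: `normals` (H x W x 3 unit vectors, NA where undefined),
#'   `valid` (H x W logical)
#' @export
estimate_normals <- function(cloud, window = 3L,
                             depth_discontinuity_m = 0.010) {
  if (window %% 2 != 1 || window < 3) stopf("window must be odd and >= 3")
  xyz <- cloud$xyz; valid <- cloud$valid
  h <- dim(xyz)[1]; w <- dim(xyz)[2]
  r <- (window - 1L) / 2L
  offs <- expand.grid(dr = -r:r, dc = -r:r)
  k <- nrow(offs)
  ## gather the window neighbourhoods as k-layer stacks (border replicated
  ## then masked out by validity + discontinuity)
  X <- array(NA_real_, c(h, w, k)); Y <- X; Z <- X; OK <- array(FALSE, c(h, w, k))
  zc <- xyz[, , 3]
  for (i in seq_len(k)) {
    dr <- offs$dr[i]; dc <- offs$dc[i]
    rs <- clampv(1:h + dr, 1, h); cs <- clampv(1:w + dc, 1, w)
    inb <- outer(1:h + dr, 1:w + dc,
                 function(a, b) a >= 1 & a <= h & b >= 1 & b <= w)
    X[, , i] <- xyz[rs, cs, 1]; Y[, , i] <- xyz[rs, cs, 2]; Z[, , i] <- xyz[rs, cs, 3]
    OK[, , i] <- inb & valid[rs, cs] & (abs(xyz[rs, cs, 3] - zc) <= depth_discontinuity_m)
  }
  OK[is.na(OK)] <- FALSE
  cnt <- rowSums(OK, dims = 2)
  normals <- array(NA_real_, c(h, w, 3))
  ## covariance accumulation, vectorized over pixels
  Xo <- X; Xo[!OK] <- 0; Yo <- Y; Yo[!OK] <- 0; Zo <- Z; Zo[!OK] <- 0
  n <- pmax(cnt, 1)
  mx <- rowSums(Xo, dims = 2) / n
  my <- rowSums(Yo, dims = 2) / n
  mz <- rowSums(Zo, dims = 2) / n
  Sxx <- Syy <- Szz <- Sxy <- Sxz <- Syz <- matrix(0, h, w)
  for (i in seq_len(k)) {
    dx <- (X[, , i] - mx); dy <- (Y[, , i] - my); dz <- (Z[, , i] - mz)
    m <- OK[, , i]
    dx[!m] <- 0; dy[!m] <- 0; dz[!m] <- 0
    Sxx <- Sxx + dx * dx; Syy <- Syy + dy * dy; Szz <- Szz + dz * dz
    Sxy <- Sxy + dx * dy; Sxz <- Sxz + dx * dz; Syz <- Syz + dy * dz
  }
  ## smallest eigenvector of the 3x3 scatter, vectorized over pixels:
  ## trigonometric eigenvalue formula for symmetric 3x3, then the
  ## eigenvector from cross products of rows of (S - lambda_min I)
  cand <- which(valid & cnt >= 3)
  if (length(cand)) {
    sxx <- Sxx[cand]; syy <- Syy[cand]; szz <- Szz[cand]
    sxy <- Sxy[cand]; sxz <- Sxz[cand]; syz <- Syz[cand]
    q <- (sxx + syy + szz) / 3
    p2 <- (sxx - q)^2 + (syy - q)^2 + (szz - q)^2 + 2 * (sxy^2 + sxz^2 + syz^2)
    p <- sqrt(pmax(p2, 0) / 6)
    safe_p <- pmax(p, 1e-300)
    b11 <- (sxx - q) / safe_p; b22 <- (syy - q) / safe_p; b33 <- (szz - q) / safe_p
    b12 <- sxy / safe_p; b13 <- sxz / safe_p; b23 <- syz / safe_p
    detB <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
      b13 * (b12 * b23 - b22 * b13)
    r <- clampv(detB / 2, -1, 1)
    phi <- acos(r) / 3
    lmin <- q + 2 * p * cos(phi + 2 * pi / 3)
    a11 <- sxx - lmin; a22 <- syy - lmin; a33 <- szz - lmin
    ## candidate eigenvectors: cross products of row pairs
    c1x <- sxy * syz - a22 * sxz;  c1y <- sxy * sxz - a11 * syz
    c1z <- a11 * a22 - sxy^2                       # r1 x r2
    c2x <- sxy * a33 - syz * sxz;  c2y <- sxz^2 - a11 * a33
    c2z <- a11 * syz - sxy * sxz                   # r1 x r3
    c3x <- a22 * a33 - syz^2;      c3y <- syz * sxz - sxy * a33
    c3z <- sxy * syz - a22 * sxz                   # r2 x r3
    n1sq <- c1x^2 + c1y^2 + c1z^2
    n2sq <- c2x^2 + c2y^2 + c2z^2
    n3sq <- c3x^2 + c3y^2 + c3z^2
    use2 <- n2sq > n1sq & n2sq >= n3sq
    use3 <- n3sq > n1sq & n3sq > n2sq
    nx <- c1x; ny <- c1y; nz <- c1z
    nx[use2] <- c2x[use2]; ny[use2] <- c2y[use2]; nz[use2] <- c2z[use2]
    nx[use3] <- c3x[use3]; ny[use3] <- c3y[use3]; nz[use3] <- c3z[use3]
    nn <- sqrt(nx^2 + ny^2 + nz^2)
    deg <- nn < 1e-30 | p < 1e-30   # isotropic / degenerate scatter
    nn[deg] <- 1
    nx <- nx / nn; ny <- ny / nn; nz <- nz / nn
    nx[deg] <- 0; ny[deg] <- 0; nz[deg] <- -1
    ## orient toward the camera (viewing ray direction is p - cam = p here)
    px <- xyz[, , 1][cand]; py <- xyz[, , 2][cand]; pz <- xyz[, , 3][cand]
    flip <- (nx * px + ny * py + nz * pz) > 0
    nx[flip] <- -nx[flip]; ny[flip] <- -ny[flip]; nz[flip] <- -nz[flip]
    n1 <- matrix(NA_real_, h, w); n2 <- n1; n3 <- n1
    n1[cand] <- nx; n2[cand] <- ny; n3[cand] <- nz
    normals[, , 1] <- n1; normals[, , 2] <- n2; normals[, , 3] <- n3
  }
  list(normals = normals, valid = valid & cnt >= 3)
}

#' Compute the eight 3D light-field feature channels
#'
#' Channels in fixed order (d_i, d_v, theta_i, theta_v, theta, x, y, z):
#' distance to the light source, distance to the camera, incidence angle
#' between the surface normal and the light direction, viewing angle
#' between the normal and the camera direction, the unsigned angle between
#' the in-plane projections of the two directions (0 when either
#' projection degenerates), and the 3D coordinates.
#'
#' @param cloud organized cloud from [depth_to_points()]
#' @param normals output of [estimate_normals()]
#' @param geometry a [scene_geometry]
#' @param eps_proj projection-degeneracy guard
#' @return list: `features` (H x W x 8), `valid` (H x W logical),
#'   `channels` (channel names)
#' @export
compute_features <- function(cloud, normals, geometry, eps_proj = 1e-9) {
  xyz <- cloud$xyz
  h <- dim(xyz)[1]; w <- dim(xyz)[2]
  valid <- normals$valid & cloud$valid
  idx <- which(valid)
  feats <- array(NA_real_, c(h, w, 8))
  if (length(idx)) {
    P <- cbind(xyz[, , 1][idx], xyz[, , 2][idx], xyz[, , 3][idx])
    N3 <- cbind(normals$normals[, , 1][idx], normals$normals[, , 2][idx],
                normals$normals[, , 3][idx])
    lf <- lightfield_geometry(P, N3, geometry$light_position,
                              geometry$camera_position, eps_proj)
    vals <- cbind(lf$d_i, lf$d_v, lf$theta_i, lf$theta_v, lf$theta, P)
    for (ch in 1:8) {
      m <- matrix(NA_real_, h, w); m[idx] <- vals[, ch]
      feats[, , ch] <- m
    }
  }
  list(features = feats, valid = valid,
       channels = c("d_i", "d_v", "theta_i", "theta_v", "theta",
                    "x", "y", "z"))
}

#' Full depth-to-features pipeline for one frame
#'
#' @param depth a [depth_image]
#' @param intrinsics matching [camera_intrinsics]
#' @param geometry a [scene_geometry]
#' @param cfg configuration (light-field block)
#' @return as [compute_features()], plus `cloud` and `normals`
#' @export
lightfield_features <- function(depth, intrinsics, geometry,
                                cfg = default_config()) {
  cloud <- depth_to_points(depth, intrinsics)
  nr <- estimate_normals(cloud, cfg$lightfield$window,
                         cfg$lightfield$depth_discontinuity_m)
  f <- compute_features(cloud, nr, geometry, cfg$lightfield$eps_proj)
  c(f, list(cloud = cloud, normals = nr))
}
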