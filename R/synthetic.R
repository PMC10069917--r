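## Synthetic Lambertian scene rendering with analytic ground truth. This
## stands in for the physical rig: matte hemisphere references and
## plant-like leaf patches are ray-cast through a pinhole camera and shaded
## with a point light source, DN(p, b) = g_b * rho_b * max(0, cos theta_i)
## / d_i^2 + a_b + noise. Inverse-square falloff is the minimal physical
## model that makes the light distance informative; it can be switched off.

#' Per-band illumination model for the synthetic renderer
#'
#' @param gain length-B source gains g_b (DN m^2); recycled from a scalar
#' @param ambient length-B ambient offsets a_b (DN)
#' @param noise_sd Gaussian sensor noise standard deviation (DN)
#' @param inverse_square include 1/d_i^2 falloff (default TRUE)
#' @param spot_axis optional unit direction of peak emission; with a
#'   positive `spot_exponent` the source is directionally nonuniform
#'   (halogen-with-reflector-like): emission scales with
#'   max(0, cos psi)^exponent, psi the angle off the axis
#' @param spot_exponent angular falloff exponent (0 = isotropic)
#' @return object of class `illumination_model`
#' @export
illumination_model <- function(gain = 1, ambient = 0, noise_sd = 0,
                               inverse_square = TRUE, spot_axis = NULL,
                               spot_exponent = 0) {
  if (any(gain <= 0)) stopf("gains must be positive")
  if (any(ambient < 0) || noise_sd < 0) stopf("ambient/noise must be >= 0")
  if (spot_exponent < 0) stopf("spot_exponent must be >= 0")
  if (!is.null(spot_axis)) spot_axis <- spot_axis / vec_norm(spot_axis)
  structure(list(gain = gain, ambient = ambient, noise_sd = noise_sd,
                 inverse_square = inverse_square, spot_axis = spot_axis,
                 spot_exponent = spot_exponent),
            class = "illumination_model")
}

#' Illumination model of the emulated rig
#'
#' A single halogen-like source at the configured light position, aimed at
#' the stage centre with a mild angular falloff (real reflector lamps are
#' directionally nonuniform), inverse-square propagation, and optional
#' sensor noise expressed as a fraction of the peak reference DN.
#'
#' @param cfg configuration list
#' @param noise_frac noise standard deviation as a fraction of the
#'   brightest reference DN (0 = noiseless)
#' @param gain per-band source gain
#' @param spot_exponent angular falloff exponent; the default 8
#'   corresponds to a typical reflector-lamp beam of a few tens of degrees
#' @return an [illumination_model]
#' @export
rig_illumination <- function(cfg = default_config(), noise_frac = 0,
                             gain = 1, spot_exponent = 8) {
  light <- cfg$scene$light_position
  stage <- c(0, 0, cfg$scene$working_distance_m)
  axis <- stage - light
  ## peak DN scale of a 0.6-albedo reference facing the light at the
  ## stage distance, used to express noise as a DN fraction
  peak <- max(gain) * 0.6 / sum(axis^2)
  illumination_model(gain = gain, noise_sd = noise_frac * peak,
                     spot_axis = axis, spot_exponent = spot_exponent)
}

#' Surface primitives for the synthetic renderer
#'
#' `hemisphere`: matte dome of given diameter whose axis points from the
#' flat face toward the dome top. `planar_leaf`: elliptical planar patch.
#' `quadric_leaf`: gently curved spherical-cap patch of curvature radius
#' `curvature_radius`. Albedo is the per-band intrinsic reflectance.
#'
#' @param kind one of "hemisphere", "planar_leaf", "quadric_leaf", "background"
#' @param center 3-vector (metres): dome centre / patch centre / point on plane
#' @param albedo per-band reflectance in `[0, 1]` (recycled from a scalar)
#' @param radius hemisphere or patch radius (metres)
#' @param axis hemisphere axis or patch normal (unit vector, any scale)
#' @param semi_axes length-2 in-plane semi-axes for leaf patches (metres);
#'   defaults to `c(radius, radius)`
#' @param curvature_radius sphere radius for `quadric_leaf` (metres)
#' @param rgb display colour for the RGB rendering
#' @param id integer object label (0 is reserved for background/no hit)
#' @return object of class `surface_primitive`
#' @export
surface_primitive <- function(kind, center, albedo, radius = 0.05,
                              axis = c(0, 0, -1), semi_axes = NULL,
                              curvature_radius = 0.25,
                              rgb = c(0.2, 0.7, 0.2), id = 1L) {
  kind <- match.arg(kind, c("hemisphere", "planar_leaf", "quadric_leaf",
                            "background"))
  if (radius <= 0) stopf("primitive size must be > 0")
  if (any(albedo < 0 | albedo > 1)) stopf("albedo must lie in [0, 1]")
  axis <- axis / vec_norm(axis)
  structure(list(kind = kind, center = as.numeric(center),
                 albedo = as.numeric(albedo), radius = radius, axis = axis,
                 semi_axes = semi_axes %||% c(radius, radius),
                 curvature_radius = curvature_radius,
                 rgb = rgb, id = as.integer(id)),
            class = "surface_primitive")
}

## Ray-primitive intersection for a bundle of rays from the origin with
## directions D (N x 3, unit). Returns list(t, normal) with t = Inf for
## misses; normals are outward (flipped toward the camera by the caller).
intersect_primitive <- function(prim, D) {
  n_ray <- nrow(D)
  t <- rep(Inf, n_ray)
  nrm <- matrix(NA_real_, n_ray, 3)
  c0 <- prim$center
  if (prim$kind %in% c("hemisphere", "quadric_leaf")) {
    ctr <- c0; R <- prim$radius
    if (prim$kind == "quadric_leaf") {
      R <- prim$curvature_radius
      ctr <- c0 - prim$axis * R   # cap centred on the patch centre
    }
    b <- D %*% ctr                      # N x 1: dot(dir, centre)
    cc <- sum(ctr^2) - R^2
    disc <- as.vector(b)^2 - cc
    ok <- disc > 0
    sq <- sqrt(pmax(disc, 0))
    t1 <- as.vector(b) - sq; t2 <- as.vector(b) + sq
    for (cand in list(t1, t2)) {
      sel <- ok & cand > 1e-6 & cand < t
      if (!any(sel)) next
      p <- D[sel, , drop = FALSE] * cand[sel]
      side <- (p - matrix(ctr, sum(sel), 3, byrow = TRUE)) %*% prim$axis
      keep <- if (prim$kind == "hemisphere") {
        as.vector(side) >= 0
      } else {
        ## spherical cap: accept hits within the patch's angular radius
        as.vector(side) >= sqrt(max(R^2 - prim$radius^2, 0))
      }
      idx <- which(sel)[keep]
      if (!length(idx)) next
      t[idx] <- cand[idx]
      p2 <- D[idx, , drop = FALSE] * t[idx]
      nrm[idx, ] <- (p2 - matrix(ctr, length(idx), 3, byrow = TRUE)) / R
    }
  } else {
    ## planar patch or infinite background plane
    nv <- prim$axis
    denom <- as.vector(D %*% nv)
    tt <- sum(c0 * nv) / denom
    ok <- is.finite(tt) & tt > 1e-6
    p <- D * tt
    if (prim$kind == "planar_leaf") {
      ## in-plane ellipse test
      u <- pick_tangent(nv)
      v <- cross3(nv, u)
      rel <- sweep(p, 2, c0)
      pu <- as.vector(rel %*% u) / prim$semi_axes[1]
      pv <- as.vector(rel %*% v) / prim$semi_axes[2]
      ok <- ok & (pu^2 + pv^2 <= 1)
    }
    sel <- ok & tt < t
    t[sel] <- tt[sel]
    nrm[sel, ] <- matrix(nv, sum(sel), 3, byrow = TRUE)
  }
  list(t = t, normal = nrm)
}

cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

pick_tangent <- function(n) {
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- cross3(n, ref)
  u / vec_norm(u)
}

## Evaluate the five relational light-field quantities for points P (N x 3)
## with unit normals N3 (N x 3), light l and camera cam (3-vectors).
## Normals are flipped toward the camera first. This is the defining vector
## arithmetic shared by the renderer's analytic ground truth.
lightfield_geometry <- function(P, N3, light, cam, eps_proj = 1e-9) {
  to_cam <- sweep(-P, 2, -cam)              # cam - p
  d_v <- sqrt(rowSums(to_cam^2))
  flip <- rowSums(N3 * to_cam) < 0
  N3[flip, ] <- -N3[flip, , drop = FALSE]
  to_light <- sweep(-P, 2, -light)          # light - p
  d_i <- sqrt(rowSums(to_light^2))
  li <- to_light / d_i
  vi <- to_cam / d_v
  cos_i <- clampv(rowSums(N3 * li), -1, 1)
  cos_v <- clampv(rowSums(N3 * vi), -1, 1)
  theta_i <- acos(cos_i)
  theta_v <- acos(cos_v)
  ## azimuth between the in-plane projections of the two directions
  proj_l <- li - N3 * rowSums(N3 * li)
  proj_v <- vi - N3 * rowSums(N3 * vi)
  nl <- sqrt(rowSums(proj_l^2)); nv <- sqrt(rowSums(proj_v^2))
  cth <- rowSums(proj_l * proj_v) / (nl * nv)
  theta <- acos(clampv(cth, -1, 1))
  theta[nl < eps_proj | nv < eps_proj] <- 0
  list(d_i = d_i, d_v = d_v, theta_i = theta_i, theta_v = theta_v,
       theta = theta, normal = N3, cos_i = cos_i)
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

#' Render a synthetic scene through a pinhole camera
#'
#' First-hit ray casting of the primitives, Lambertian shading with
#' inverse-square falloff, Gaussian sensor noise, and analytic ground-truth
#' maps (object ids, albedo, normals, and all eight light-field feature
#' channels computed from the primitives' exact geometry, not from the
#' rendered depth grid).
#'
#' @param primitives list of [surface_primitive] objects
#' @param intrinsics a [camera_intrinsics]
#' @param geometry a [scene_geometry]
#' @param illum an [illumination_model]
#' @param wavelengths band centres (nm)
#' @param seed RNG seed for the sensor noise (`NULL` = leave RNG alone)
#' @return list with `depth` ([depth_image]), `rgb` (H x W x 3), `ms`
#'   ([ms_stack]), and `gt` (ground truth: `id_map`, `albedo` H x W x B,
#'   `normals` H x W x 3, `features` H x W x 8, `mask` of hit pixels)
#' @export
render_scene <- function(primitives, intrinsics, geometry, illum,
                         wavelengths = seq(650, 950, length.out = 25),
                         seed = NULL) {
  if (!length(primitives)) stopf("no primitives supplied")
  K <- intrinsics
  h <- K$height; w <- K$width
  B <- length(wavelengths)
  ## ray directions through each pixel centre (0-based coordinates)
  u <- matrix(rep(0:(w - 1), each = h), h, w)
  v <- matrix(rep(0:(h - 1), w), h, w)
  dx <- (u - K$cx) / K$fx; dy <- (v - K$cy) / K$fy
  D <- cbind(as.vector(dx), as.vector(dy), 1)
  D <- D / sqrt(rowSums(D^2))
  n_ray <- nrow(D)
  best_t <- rep(Inf, n_ray)
  best_id <- integer(n_ray)
  best_nrm <- matrix(NA_real_, n_ray, 3)
  prim_by_id <- list()
  for (prim in primitives) {
    hit <- intersect_primitive(prim, D)
    sel <- hit$t < best_t
    best_t[sel] <- hit$t[sel]
    best_id[sel] <- prim$id
    best_nrm[sel, ] <- hit$normal[sel, , drop = FALSE]
    prim_by_id[[as.character(prim$id)]] <- prim
  }
  hitm <- is.finite(best_t)
  if (!any(hitm)) stopf("no primitive is visible from the camera")
  P <- D * best_t
  P[!hitm, ] <- NA_real_
  lf <- lightfield_geometry(P[hitm, , drop = FALSE],
                            best_nrm[hitm, , drop = FALSE],
                            geometry$light_position, geometry$camera_position)
  shade <- pmax(0, lf$cos_i)
  if (isTRUE(illum$inverse_square)) shade <- shade / lf$d_i^2
  if (!is.null(illum$spot_axis) && illum$spot_exponent > 0) {
    ## emission direction from the source to the point vs the lamp axis
    emis <- sweep(P[hitm, , drop = FALSE], 2, geometry$light_position)
    emis <- emis / sqrt(rowSums(emis^2))
    cpsi <- pmax(0, as.vector(emis %*% illum$spot_axis))
    shade <- shade * cpsi^illum$spot_exponent
  }
  gain <- rep(illum$gain, length.out = B)
  ambient <- rep(illum$ambient, length.out = B)
  ## per-pixel albedo
  alb <- matrix(0, sum(hitm), B)
  ids <- best_id[hitm]
  for (idc in unique(ids)) {
    prim <- prim_by_id[[as.character(idc)]]
    alb[ids == idc, ] <- matrix(rep(prim$albedo, length.out = B),
                                sum(ids == idc), B, byrow = TRUE)
  }
  dn <- matrix(ambient, n_ray, B, byrow = TRUE)
  dn[hitm, ] <- dn[hitm, , drop = FALSE] + (shade * alb) %*% diag(gain, B)
  if (illum$noise_sd > 0) {
    noise <- with_seed(seed, matrix(rnorm(n_ray * B, 0, illum$noise_sd), n_ray, B))
    dn <- pmax(dn + noise, 0)
  }
  ## RGB: shading-scaled display colour
  rgbm <- matrix(0, n_ray, 3)
  for (idc in unique(ids)) {
    prim <- prim_by_id[[as.character(idc)]]
    rgbm[best_id == idc & hitm, ] <- matrix(prim$rgb, sum(best_id == idc & hitm),
                                            3, byrow = TRUE)
  }
  smax <- max(shade)
  sh_full <- numeric(n_ray); sh_full[hitm] <- shade / (smax + (smax == 0))
  rgbm <- rgbm * sh_full
  ## assemble H x W containers (rays are in column-major pixel order)
  zmat <- matrix(P[, 3], h, w)
  feats <- array(NA_real_, c(h, w, 8))
  fvals <- cbind(lf$d_i, lf$d_v, lf$theta_i, lf$theta_v, lf$theta,
                 P[hitm, , drop = FALSE])
  for (ch in 1:8) {
    m <- matrix(NA_real_, h, w); m[hitm] <- fvals[, ch]
    feats[, , ch] <- m
  }
  normals <- array(NA_real_, c(h, w, 3))
  nfix <- matrix(NA_real_, n_ray, 3); nfix[hitm, ] <- lf$normal
  for (ch in 1:3) normals[, , ch] <- matrix(nfix[, ch], h, w)
  albedo_cube <- array(NA_real_, c(h, w, B))
  for (b in 1:B) {
    m <- matrix(NA_real_, h, w); m[hitm] <- alb[, b]
    albedo_cube[, , b] <- m
  }
  list(
    depth = depth_image(zmat),
    rgb = array(clampv(rgbm, 0, 1), c(h, w, 3)),
    ms = ms_stack(array(dn, c(h, w, B)), wavelengths),
    gt = list(id_map = matrix(best_id, h, w),
              albedo = albedo_cube,
              normals = normals,
              features = feats,
              mask = matrix(hitm, h, w))
  )
}

#' Grid of hemisphere reference poses
#'
#' Emulates imaging the reference at many rig positions: `n_vertical`
#' height steps (step = 10% of the plant height) by `n_horizontal` lateral
#' steps, all at the working distance, dome axis toward the camera.
#'
#' @param n_vertical,n_horizontal grid counts (defaults 10 x 7 = 70 poses)
#' @param plant_height_m plant height; vertical step is 10% of it
#' @param horizontal_span_m total lateral extent of the grid
#' @param diameter_m hemisphere diameter (default 100 mm)
#' @param distance_m working distance from the camera (metres)
#' @param albedo reference albedo spectrum (flat matte Teflon-like)
#' @param pitch_deg camera pitch below the horizontal; the world-vertical
#'   height steps therefore sweep both camera-frame y and depth, as on the
#'   pitched rig
#' @return list of [surface_primitive] hemisphere poses
#' @export
make_hemisphere_layout <- function(n_vertical = 10L, n_horizontal = 7L,
                                   plant_height_m = 0.5,
                                   horizontal_span_m = 0.30,
                                   diameter_m = 0.100,
                                   distance_m = 0.75,
                                   albedo = 0.6,
                                   pitch_deg = 40) {
  if (n_vertical < 1 || n_horizontal < 1) stopf("layout counts must be >= 1")
  vstep <- 0.10 * plant_height_m
  up <- world_up_in_camera(pitch_deg)
  hs <- (seq_len(n_vertical) - (n_vertical + 1) / 2) * vstep
  xs <- if (n_horizontal == 1) 0 else
    seq(-horizontal_span_m / 2, horizontal_span_m / 2, length.out = n_horizontal)
  poses <- list()
  k <- 1L
  for (hh in hs) for (x in xs) {
    ctr <- c(x, 0, distance_m) + hh * up
    poses[[k]] <- surface_primitive("hemisphere", ctr, albedo,
                                    radius = diameter_m / 2,
                                    axis = -ctr / vec_norm(ctr),
                                    rgb = c(0.85, 0.85, 0.85), id = k)
    k <- k + 1L
  }
  poses
}

## world-vertical ("plant up") direction expressed in the camera frame of a
## rig pitched pitch_deg below the horizontal (camera y down, z forward)
world_up_in_camera <- function(pitch_deg) {
  th <- pitch_deg * pi / 180
  c(0, -cos(th), -sin(th))
}

#' Pseudo-random plant-like leaf scene
#'
#' Places `n_leaves` elliptical leaf patches (a mix of planar and gently
#' curved) in the working volume with reproducible pseudo-random positions,
#' inclinations and per-leaf albedo spectra drawn from `albedo_bank`.
#' `view_rotation_deg` rotates the whole scene about the vertical axis
#' through the stage centre, emulating the rotating sample holder; the
#' per-leaf albedo is intrinsic and unchanged by the rotation.
#'
#' @param n_leaves number of leaves (>= 1)
#' @param albedo_bank list of per-band albedo spectra to draw from
#' @param inclination_range_deg leaf normal tilt range away from the camera
#'   direction, degrees
#' @param seed RNG seed (scene layout is a deterministic function of it)
#' @param view_rotation_deg sample-holder rotation for this view
#' @param extent_m lateral half-extent of the leaf cloud
#' @param plant_height_m vertical (world up) extent of the plant
#' @param distance_m working distance of the stage centre
#' @param leaf_radius_m typical leaf semi-major axis
#' @param pitch_deg camera pitch (leaves spread along world up, and the
#'   sample holder rotates about the world-vertical axis)
#' @return list of [surface_primitive] leaves (ids 1..n_leaves, with the
#'   drawn albedo attached to each)
#' @export
make_leaf_scene <- function(n_leaves = 6L, albedo_bank,
                            inclination_range_deg = c(20, 45),
                            azimuth_range_deg = c(-45, 45),
                            seed = 1L, view_rotation_deg = 0,
                            extent_m = 0.12, plant_height_m = 0.35,
                            distance_m = 0.75,
                            leaf_radius_m = 0.035, pitch_deg = 40) {
  if (n_leaves < 1) stopf("n_leaves must be >= 1")
  if (!length(albedo_bank)) stopf("albedo bank must not be empty")
  up <- world_up_in_camera(pitch_deg)
  fwd <- cross3(c(1, 0, 0), up)          # horizontal, toward the camera
  pivot <- c(0, 0, distance_m)
  prims <- with_seed(seed, {
    lapply(seq_len(n_leaves), function(i) {
      pos <- pivot +
        runif(1, -extent_m, extent_m) * c(1, 0, 0) +
        runif(1, -plant_height_m / 2, plant_height_m / 2) * up +
        runif(1, -0.04, 0.04) * fwd
      ## leaf normal by zenith tilt from world-up (every leaf keeps a
      ## lever arm about the turntable axis) and a camera-biased azimuth
      ## (all leaves observable across the rotation sweep)
      incl <- runif(1, inclination_range_deg[1], inclination_range_deg[2]) * pi / 180
      azim <- runif(1, azimuth_range_deg[1], azimuth_range_deg[2]) * pi / 180
      nrm <- cos(incl) * up + sin(incl) * (cos(azim) * fwd + sin(azim) * c(1, 0, 0))
      kind <- if (i %% 2 == 0) "quadric_leaf" else "planar_leaf"
      surface_primitive(kind, pos,
                        albedo = albedo_bank[[(i - 1) %% length(albedo_bank) + 1]],
                        radius = leaf_radius_m, axis = nrm,
                        semi_axes = leaf_radius_m * c(1, 0.6),
                        curvature_radius = 0.30,
                        rgb = c(0.15, 0.65, 0.2), id = i)
    })
  })
  if (view_rotation_deg != 0) {
    th <- view_rotation_deg * pi / 180
    R <- rotation_about_axis(up, th)
    prims <- lapply(prims, function(p) {
      p$center <- as.vector(R %*% (p$center - pivot)) + pivot
      p$axis <- as.vector(R %*% p$axis)
      p
    })
  }
  prims
}

## Rodrigues rotation matrix about a unit axis
rotation_about_axis <- function(axis, theta) {
  a <- axis / vec_norm(axis)
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Fabricate a fixed/moving registration pair with a known warp
#'
#' The ground-truth map from fixed to moving coordinates is
#' G(x) = A(x) + s(x): a planar similarity/affine part A (rotation, scale,
#' translation about the image centre) plus a smooth sinusoidal displacement
#' of the given amplitude (constant norm, rotating direction). The moving
#' image is the base image resampled through the numerically inverted map,
#' then passed through a gamma + affine intensity remap emulating the
#' modality gap. The dense ground-truth displacement field G(x) - x is
#' returned for endpoint-error scoring.
#'
#' @param base H x W matrix in `[0, 1]`, nonconstant
#' @param rotation_deg,scale,translation_px planar transform parameters
#' @param nonrigid_amplitude_px sinusoid amplitude (px)
#' @param nonrigid_period_px sinusoid period (px)
#' @param gamma,gain,offset intensity remap `gain * x^gamma + offset`
#' @return list: `fixed`, `moving`, `field` (H x W x 2 array, dx then dy),
#'   `A` (3 x 3 fixed-to-moving planar matrix)
#' @export
make_registration_pair <- function(base, rotation_deg = 0, scale = 1,
                                   translation_px = c(0, 0),
                                   nonrigid_amplitude_px = 0,
                                   nonrigid_period_px = 48,
                                   gamma = 1, gain = 1, offset = 0) {
  if (max(base) == min(base)) stopf("base image must be nonconstant")
  if (scale == 0) stopf("degenerate transform: zero scale")
  h <- nrow(base); w <- ncol(base)
  th <- rotation_deg * pi / 180
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  R <- scale * matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
  tvec <- c(cx, cy) - R %*% c(cx, cy) + translation_px
  A <- rbind(cbind(R, tvec), c(0, 0, 1))
  xs <- matrix(rep(0:(w - 1), each = h), h, w)
  ys <- matrix(rep(0:(h - 1), w), h, w)
  sfun <- function(x, y) {
    if (nonrigid_amplitude_px == 0) return(list(dx = 0 * x, dy = 0 * x))
    u <- 2 * pi * (x + y) / nonrigid_period_px
    list(dx = nonrigid_amplitude_px * sin(u),
         dy = nonrigid_amplitude_px * cos(u))
  }
  s <- sfun(xs, ys)
  gx <- A[1, 1] * xs + A[1, 2] * ys + A[1, 3] + s$dx
  gy <- A[2, 1] * xs + A[2, 2] * ys + A[2, 3] + s$dy
  field <- array(0, c(h, w, 2))
  field[, , 1] <- gx - xs
  field[, , 2] <- gy - ys
  ## invert G per moving pixel by fixed-point iteration:
  ## x_{k+1} = A^{-1}(y - s(x_k))
  Ai <- solve(A)
  px <- as.vector(xs); py <- as.vector(ys)    # moving pixel coordinates y
  qx <- Ai[1, 1] * px + Ai[1, 2] * py + Ai[1, 3]
  qy <- Ai[2, 1] * px + Ai[2, 2] * py + Ai[2, 3]
  if (nonrigid_amplitude_px > 0) {
    for (it in 1:25) {
      sv <- sfun(qx, qy)
      qx <- Ai[1, 1] * (px - sv$dx) + Ai[1, 2] * (py - sv$dy) + Ai[1, 3]
      qy <- Ai[2, 1] * (px - sv$dx) + Ai[2, 2] * (py - sv$dy) + Ai[2, 3]
    }
  }
  moving <- matrix(sample_bicubic(base, qx, qy, fill = 0), h, w)
  moving <- clampv(moving, 0, 1)
  moving <- clampv(gain * moving^gamma + offset, 0, 1)
  list(fixed = base, moving = moving, field = field, A = A)
}

#' Smooth random blob image for registration experiments
#'
#' Sum of Gaussian blobs at reproducible pseudo-random positions/scales,
#' normalized to `[0, 1]`; gives SURF plenty of scale-space structure.
#'
#' @param h,w image size
#' @param n_blobs number of blobs
#' @param seed RNG seed
#' @return H x W matrix in `[0, 1]`
#' @export
random_blob_image <- function(h = 128, w = 128, n_blobs = 30, seed = 1) {
  with_seed(seed, {
    img <- matrix(0, h, w)
    xs <- matrix(rep(0:(w - 1), each = h), h, w)
    ys <- matrix(rep(0:(h - 1), w), h, w)
    for (i in seq_len(n_blobs)) {
      x0 <- runif(1, 0.1 * w, 0.9 * w); y0 <- runif(1, 0.1 * h, 0.9 * h)
      s <- runif(1, 1.5, 6); a <- runif(1, 0.4, 1)
      img <- img + a * exp(-((xs - x0)^2 + (ys - y0)^2) / (2 * s^2))
    }
    (img - min(img)) / (max(img) - min(img))
  })
}
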