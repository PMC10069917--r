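test_that("depth backprojection follows the pinhole model", {
  K <- camera_intrinsics(500, 500, 63.5, 47.5, 128, 96)
  z <- matrix(1.2, 96, 128)
  cl <- depth_to_points(depth_image(z), K)
  ## principal point maps to the optical axis
  r0 <- round(K$cy) + 1; c0 <- round(K$cx) + 1
  expect_lt(abs(cl$xyz[r0, c0, 1]), 1.2 / 500)
  expect_equal(cl$xyz[r0, c0, 3], 1.2)
  ## similar triangles: x = (u - cx) z / fx
  z1 <- matrix(1.0, 96, 128)
  cl1 <- depth_to_points(depth_image(z1), K)
  u <- (c0 + 50) - 1                       # 0-based column of that pixel
  expect_equal(cl1$xyz[r0, c0 + 50, 1], (u - 63.5) * 1.0 / 500,
               tolerance = 1e-12)
  z[5, 5] <- NA
  cl2 <- depth_to_points(depth_image(z), K)
  expect_false(cl2$valid[5, 5])
  expect_error(depth_to_points(depth_image(matrix(1, 10, 10)), K), "intrinsics")
})

test_that("backprojected rendered planes are coplanar", {
  K <- test_camera()
  geom <- scene_geometry(c(0, -0.2, 0))
  leaf <- surface_primitive("planar_leaf", c(0, 0, 0.7), 0.5, radius = 0.06,
                            axis = c(0.3, 0.2, -1))
  sc <- render_scene(list(leaf), K, geom, illumination_model(noise_sd = 0))
  cl <- depth_to_points(sc$depth, K)
  idx <- which(cl$valid)
  P <- cbind(cl$xyz[, , 1][idx], cl$xyz[, , 2][idx], cl$xyz[, , 3][idx])
  ## residual of the best-fit plane
  ctr <- colMeans(P)
  sv <- svd(sweep(P, 2, ctr))
  res <- abs(sweep(P, 2, ctr) %*% sv$v[, 3])
  expect_lt(max(res), 1e-6)
})

test_that("window-SVD normals are exact on planes and accurate on domes", {
  K <- test_camera()
  z <- matrix(0.8, K$height, K$width)
  cl <- depth_to_points(depth_image(z), K)
  nr <- estimate_normals(cl)
  idx <- which(nr$valid)
  expect_gt(length(idx), 100)
  nz <- nr$normals[, , 3][idx]
  expect_lt(max(abs(nz + 1)), 1e-6)          # (0, 0, -1), toward the camera
  ## isolated valid pixel has no plane
  z2 <- matrix(NA_real_, 20, 20); z2[10, 10] <- 0.8
  K2 <- camera_intrinsics(100, 100, 9.5, 9.5, 20, 20)
  nr2 <- estimate_normals(depth_to_points(depth_image(z2), K2))
  expect_false(nr2$valid[10, 10])
  ## rendered hemisphere: median angular error < 5 degrees off the rim
  geom <- scene_geometry(c(0, -0.3, 0.1))
  hemi <- surface_primitive("hemisphere", c(0, 0, 0.75), 0.6, radius = 0.05,
                            axis = c(0, 0, -1))
  sc <- render_scene(list(hemi), K, geom, illumination_model(noise_sd = 0))
  cl3 <- depth_to_points(sc$depth, K)
  nr3 <- estimate_normals(cl3)
  v <- which(nr3$valid & sc$gt$mask)
  est <- cbind(nr3$normals[, , 1][v], nr3$normals[, , 2][v], nr3$normals[, , 3][v])
  gt <- cbind(sc$gt$normals[, , 1][v], sc$gt$normals[, , 2][v], sc$gt$normals[, , 3][v])
  ang <- acos(pmin(1, abs(rowSums(est * gt)))) * 180 / pi
  expect_lt(median(ang), 5)
})

test_that("feature channels implement their defining vector geometry", {
  ## one synthetic pixel with a hand-posed configuration
  K <- camera_intrinsics(100, 100, 1, 1, 3, 3)
  z <- matrix(1, 3, 3)
  cl <- depth_to_points(depth_image(z), K)
  nr <- estimate_normals(cl)
  ## light along the normal at the centre pixel: theta_i = 0
  geomN <- scene_geometry(c(0, 0, 0.2))
  f <- compute_features(cl, nr, geomN)
  expect_lt(f$features[2, 2, 3], 1e-6)
  expect_equal(f$features[2, 2, 1], 0.8, tolerance = 1e-9)   # d_i
  expect_equal(f$features[2, 2, 2], 1.0, tolerance = 1e-9)   # d_v
  expect_equal(f$features[2, 2, 8], 1.0)                     # z passthrough
  ## light and camera symmetric about the normal within one plane: the
  ## in-plane projections of the two directions are antiparallel, theta = pi
  geomS <- scene_geometry(c(-0.5, 0, 0), c(0.5, 0, 0))
  fs <- compute_features(cl, nr, geomS)
  expect_equal(fs$features[2, 2, 5], pi, tolerance = 1e-6)
  ## camera exactly along the normal: projections degenerate, theta = 0
  geomD <- scene_geometry(c(-0.5, 0, 0), c(0, 0, 0))
  fd <- compute_features(cl, nr, geomD)
  expect_equal(fd$features[2, 2, 5], 0)
  expect_lt(fd$features[2, 2, 4], 1e-6)    # theta_v = 0 on the axis
})

test_that("features are equivariant under joint scene translation", {
  K <- test_camera()
  cfg <- test_config_small()
  geom <- scene_geometry(c(0.1, -0.25, 0.05))
  leaf <- surface_primitive("planar_leaf", c(0, 0, 0.7), 0.5, radius = 0.05,
                            axis = c(0.1, 0.2, -1))
  sc <- render_scene(list(leaf), K, geom, illumination_model(noise_sd = 0))
  lf <- lightfield_features(sc$depth, K, geom, cfg)
  ## translate points, camera and light together: relational channels fixed
  tr <- c(0.03, -0.02, 0.04)
  cl2 <- depth_to_points(sc$depth, K)
  for (ch in 1:3) cl2$xyz[, , ch] <- cl2$xyz[, , ch] + tr[ch]
  nr2 <- estimate_normals(cl2)
  geom2 <- scene_geometry(geom$light_position + tr, tr)
  f2 <- compute_features(cl2, nr2, geom2)
  v <- lf$valid & f2$valid
  for (ch in 1:5)
    expect_lt(max(abs(f2$features[, , ch][v] - lf$features[, , ch][v])), 1e-9)
  for (ch in 6:8)
    expect_equal(f2$features[, , ch][v] - lf$features[, , ch][v],
                 rep(tr[ch - 5], sum(v)), tolerance = 1e-12)
})

test_that("normal estimates converge to analytic normals with resolution", {
  geom <- scene_geometry(c(0, -0.3, 0.1))
  errs <- sapply(c(72, 144), function(hh) {
    K <- camera_intrinsics(hh * 120 / 72, hh * 120 / 72, (hh * 4 / 3 - 1) / 2,
                           (hh - 1) / 2, round(hh * 4 / 3), hh)
    hemi <- surface_primitive("hemisphere", c(0, 0, 0.75), 0.6, radius = 0.05,
                              axis = c(0, 0, -1))
    sc <- render_scene(list(hemi), K, geom, illumination_model(noise_sd = 0))
    nr <- estimate_normals(depth_to_points(sc$depth, K))
    v <- which(nr$valid & sc$gt$mask)
    est <- cbind(nr$normals[, , 1][v], nr$normals[, , 2][v], nr$normals[, , 3][v])
    gt <- cbind(sc$gt$normals[, , 1][v], sc$gt$normals[, , 2][v],
                sc$gt$normals[, , 3][v])
    median(acos(pmin(1, abs(rowSums(est * gt)))) * 180 / pi)
  })
  expect_lt(errs[2], errs[1])
})
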