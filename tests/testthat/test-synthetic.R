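test_that("rendered DN obeys the Lambertian closed form exactly without noise", {
  K <- test_camera()
  geom <- scene_geometry(c(0.1, -0.2, 0.05))
  wl <- seq(650, 950, length.out = 4)
  gains <- c(1, 2, 0.5, 3)
  illum <- illumination_model(gain = gains, ambient = 0.01, noise_sd = 0)
  alb <- c(0.2, 0.4, 0.6, 0.3)
  leaf <- surface_primitive("planar_leaf", c(0, 0, 0.7), alb, radius = 0.05,
                            axis = c(0.2, -0.1, -1), id = 1L)
  sc <- render_scene(list(leaf), K, geom, illum, wl)
  idx <- which(sc$gt$mask)
  expect_gt(length(idx), 50)
  ## per-pixel oracle from the analytic ground-truth maps
  p <- cbind(sc$gt$features[, , 6][idx], sc$gt$features[, , 7][idx],
             sc$gt$features[, , 8][idx])
  n <- leaf$axis / sqrt(sum(leaf$axis^2))
  for (b in 1:4) {
    tol <- sweep(-p, 2, -geom$light_position)   # light - p
    d_i <- sqrt(rowSums(tol^2))
    cosi <- abs((tol %*% n)) / d_i
    expected <- gains[b] * alb[b] * pmax(0, cosi) / d_i^2 + 0.01
    expect_equal(sc$ms$dn[, , b][idx], as.vector(expected), tolerance = 1e-10)
  }
})

test_that("rendering is deterministic and the noise seed is reproducible", {
  K <- test_camera()
  geom <- scene_geometry(c(0, -0.2, 0))
  hemi <- surface_primitive("hemisphere", c(0, 0, 0.6), 0.6, radius = 0.05,
                            axis = c(0, 0, -1))
  il0 <- illumination_model(noise_sd = 0)
  a <- render_scene(list(hemi), K, geom, il0, seed = 1)
  b <- render_scene(list(hemi), K, geom, il0, seed = 99)
  expect_identical(a$ms$dn, b$ms$dn)           # no noise: seeds irrelevant
  iln <- illumination_model(noise_sd = 0.01)
  n1 <- render_scene(list(hemi), K, geom, iln, seed = 5)
  n2 <- render_scene(list(hemi), K, geom, iln, seed = 5)
  n3 <- render_scene(list(hemi), K, geom, iln, seed = 6)
  expect_identical(n1$ms$dn, n2$ms$dn)
  expect_false(identical(n1$ms$dn, n3$ms$dn))
  expect_error(render_scene(list(), K, geom, il0), "primitive")
})

test_that("hemisphere apex shading peaks where the light is along the normal", {
  K <- test_camera()
  ## light straight above the dome centre on the dome axis
  hemi <- surface_primitive("hemisphere", c(0, 0, 0.6), 0.6, radius = 0.05,
                            axis = c(0, 0, -1))
  geom <- scene_geometry(c(0, 0, 0.1))
  illum <- illumination_model(noise_sd = 0, inverse_square = FALSE)
  sc <- render_scene(list(hemi), K, geom, illum)
  b1 <- sc$ms$dn[, , 1]
  peak <- which(b1 == max(b1), arr.ind = TRUE)[1, ]
  ## apex projects to the principal point (dome centre is on the axis)
  expect_lt(abs(peak[1] - 1 - K$cy), 2)
  expect_lt(abs(peak[2] - 1 - K$cx), 2)
  ## theta_i at the apex pixel is ~0
  expect_lt(sc$gt$features[peak[1], peak[2], 3], 0.1)
})

test_that("hemisphere layout matches the rig protocol", {
  poses <- make_hemisphere_layout()
  expect_length(poses, 70)
  expect_length(make_hemisphere_layout(1, 1), 1)
  expect_error(make_hemisphere_layout(0, 7), ">= 1")
  ## vertical step = 10% of plant height, along the world-up direction
  p2 <- make_hemisphere_layout(n_vertical = 2, n_horizontal = 1,
                               plant_height_m = 0.5)
  step <- sqrt(sum((p2[[2]]$center - p2[[1]]$center)^2))
  expect_equal(step, 0.05, tolerance = 1e-12)
  expect_equal(poses[[1]]$radius, 0.05)        # 100 mm diameter
})

test_that("leaf scenes are seed-reproducible with rotation-invariant albedo", {
  bank <- default_albedo_bank(seq(650, 950, length.out = 25))
  a <- make_leaf_scene(5, bank, seed = 3)
  b <- make_leaf_scene(5, bank, seed = 3)
  expect_identical(a, b)
  r <- make_leaf_scene(5, bank, seed = 3, view_rotation_deg = 90)
  for (i in 1:5) {
    expect_identical(r[[i]]$albedo, a[[i]]$albedo)  # albedo is intrinsic
    expect_false(isTRUE(all.equal(r[[i]]$center, a[[i]]$center)))
  }
  ## degenerate inclination range: all normals parallel (to world up)
  flat <- make_leaf_scene(4, bank, inclination_range_deg = c(0, 0), seed = 1)
  axes <- t(sapply(flat, `[[`, "axis"))
  expect_lt(max(apply(axes, 1, function(v) sum(abs(v - axes[1, ])))), 1e-12)
  expect_error(make_leaf_scene(3, list(), seed = 1), "albedo bank")
})

test_that("registration pairs carry an exact ground-truth displacement field", {
  base <- random_blob_image(64, 64, 20, seed = 2)
  p0 <- make_registration_pair(base)
  expect_equal(p0$moving, p0$fixed, tolerance = 1e-12)
  expect_true(all(p0$field == 0))
  pt <- make_registration_pair(base, translation_px = c(5, -3))
  expect_true(all(pt$field[, , 1] == 5))
  expect_true(all(pt$field[, , 2] == -3))
  ps <- make_registration_pair(base, nonrigid_amplitude_px = 3)
  mag <- sqrt(ps$field[, , 1]^2 + ps$field[, , 2]^2)
  expect_equal(max(mag), 3, tolerance = 1e-9)
  expect_error(make_registration_pair(base, scale = 0), "degenerate")
  expect_error(make_registration_pair(matrix(1, 8, 8)), "nonconstant")
})

test_that("analytic feature maps agree with the depth-grid pipeline", {
  cfg <- test_config_small()
  K <- test_camera()
  geom <- scene_geometry(c(0, -0.3, 0.1))
  hemi <- surface_primitive("hemisphere", c(0, 0, 0.75), 0.6, radius = 0.05,
                            axis = c(0, 0, -1))
  sc <- render_scene(list(hemi), K, geom, illumination_model(noise_sd = 0))
  lf <- lightfield_features(sc$depth, K, geom, cfg)
  v <- lf$valid & sc$gt$mask
  ## distances (m) and angles (rad) within discretization tolerance
  expect_lt(median(abs(lf$features[, , 1][v] - sc$gt$features[, , 1][v])), 1e-3)
  expect_lt(median(abs(lf$features[, , 2][v] - sc$gt$features[, , 2][v])), 1e-3)
  for (ch in 3:5)
    expect_lt(median(abs(lf$features[, , ch][v] - sc$gt$features[, , ch][v])),
              5 * pi / 180)
})
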