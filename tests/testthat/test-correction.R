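test_that("ratio correction follows its per-pixel formula", {
  plant <- array(30, c(4, 5, 3))
  ref <- array(60, c(4, 5, 3))
  cube <- correct_reflectance(plant, ref, 0.6)
  expect_equal(cube$reflectance[1, 1, ], rep(0.3, 3))
  ## the default reference reflectance of 1 gives the raw DN ratio
  cube2 <- correct_reflectance(plant, ref)
  expect_equal(cube2$reflectance[2, 3, ], rep(0.5, 3))
  ## nonpositive predicted reference DN masks the pixel and counts it
  ref[2, 2, 1] <- 0
  c3 <- correct_reflectance(plant, ref)
  expect_false(c3$mask[2, 2])
  expect_equal(c3$n_nonpositive_ref, 1)
  expect_true(all(is.na(c3$reflectance[2, 2, ])))
  expect_error(correct_reflectance(plant, ref[, , 1:2]), "grids differ")
})

test_that("the ratio cancels the shading for an exact reference model", {
  ## render the same geometry with leaf albedo and reference albedo: the
  ## DN ratio times the reference reflectance equals the planted albedo
  K <- test_camera()
  geom <- scene_geometry(c(0.1, -0.3, 0.1))
  wl <- seq(650, 950, length.out = 6)
  alb <- c(0.1, 0.2, 0.35, 0.5, 0.55, 0.6)
  mk <- function(a) surface_primitive("planar_leaf", c(0, 0, 0.7), a,
                                      radius = 0.05, axis = c(0.2, -0.3, -1))
  il <- illumination_model(gain = 2, noise_sd = 0)
  sc_p <- render_scene(list(mk(alb)), K, geom, il, wl)
  sc_r <- render_scene(list(mk(0.6)), K, geom, il, wl)
  cube <- correct_reflectance(sc_p$ms$dn, sc_r$ms$dn, 0.6, sc_p$gt$mask)
  for (b in 1:6)
    expect_equal(cube$reflectance[, , b][cube$mask],
                 rep(alb[b], sum(cube$mask)), tolerance = 1e-9)
  ## invariance to a per-band global gain applied to both stacks
  g <- c(1.5, 2, 0.5, 3, 1, 2.5)
  plant_g <- sweep(sc_p$ms$dn, 3, g, "*")
  ref_g <- sweep(sc_r$ms$dn, 3, g, "*")
  cube_g <- correct_reflectance(plant_g, ref_g, 0.6, sc_p$gt$mask)
  expect_equal(cube_g$reflectance[cube_g$mask], cube$reflectance[cube$mask],
               tolerance = 1e-9)
})

test_that("outlier masking applies the negative / out-of-range rules", {
  refl <- array(0.4, c(2, 5, 5))
  mask <- matrix(TRUE, 2, 5)
  cube <- structure(list(reflectance = refl, mask = mask,
                         n_nonpositive_ref = 0), class = "reflectance_cube")
  ## plant three violators in a 10-pixel cube
  cube$reflectance[1, 1, 2] <- -0.05            # any negative band -> masked
  cube$reflectance[1, 2, ] <- c(0.9, 0.85, 0.9, 0.4, 0.4)  # 3/5 > 0.8
  cube$reflectance[2, 3, ] <- rep(0.001, 5)     # all bands close to 0
  out <- mask_outliers(cube, low = 0.01, high = 0.8, band_fraction = 0.2)
  expect_equal(out$n_outliers, 3)
  expect_false(out$mask[1, 1]); expect_false(out$mask[1, 2])
  expect_false(out$mask[2, 3])
  expect_true(out$mask[2, 2])                   # all bands in [0.2, 0.6] kept
  ## one band slightly over the bound survives band_fraction = 0.2
  cube2 <- cube
  cube2$reflectance[1, 1, 2] <- 0.85
  cube2$reflectance[1, 2, ] <- 0.4
  cube2$reflectance[2, 3, ] <- 0.4
  out2 <- mask_outliers(cube2)
  expect_true(out2$mask[1, 1])
  expect_error(mask_outliers(cube, low = 0.9, high = 0.8), "bounds")
})

test_that("point clouds collect exactly the surviving pixels in row-major order", {
  wl <- seq(650, 950, length.out = 4)
  h <- 3; w <- 4
  xyz <- array(0, c(h, w, 3))
  xyz[, , 1] <- matrix(seq_len(h * w), h, w)    # distinguishable x
  xyz[, , 3] <- 0.7
  cloud <- list(xyz = xyz, valid = matrix(TRUE, h, w))
  refl <- array(0.5, c(h, w, 4))
  cube <- structure(list(reflectance = refl, mask = matrix(TRUE, h, w),
                         n_nonpositive_ref = 0), class = "reflectance_cube")
  pc <- make_multispectral_cloud(cloud, cube, wl)
  expect_equal(nrow(pc$points), h * w)
  ## row-major: first two points come from row 1, columns 1 and 2
  expect_equal(pc$points[1:2, 1], c(xyz[1, 1, 1], xyz[1, 2, 1]))
  ## single unmasked pixel
  cube$mask[] <- FALSE; cube$mask[2, 3] <- TRUE
  pc1 <- make_multispectral_cloud(cloud, cube, wl)
  expect_equal(nrow(pc1$points), 1)
  expect_equal(pc1$points[1, 1], xyz[2, 3, 1])
  expect_equal(as.vector(pc1$reflectance), rep(0.5, 4))
  cube$mask[] <- FALSE
  expect_error(make_multispectral_cloud(cloud, cube, wl), "no surviving")
})

test_that("the flat-reference baseline divides by one spectrum per frame", {
  plant <- array(rep(c(10, 20, 30), each = 6), c(2, 3, 3))
  flat <- c(50, 40, 60)
  cube <- flat_reference_correction(plant, flat, 0.99)
  expect_equal(cube$reflectance[1, 1, ], 0.99 * c(10, 20, 30) / flat)
  expect_error(flat_reference_correction(plant, c(1, 2)), "bands")
  expect_error(flat_reference_correction(plant, c(0, 1, 2)), "positive")
})
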