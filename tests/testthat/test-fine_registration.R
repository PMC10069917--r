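test_that("the Demons increment follows its per-pixel formula", {
  ## hand-computed single-pixel case: s = 1, m = 0.5, grad = (1, 0), alpha = 1
  s <- matrix(1, 1, 1); m <- matrix(0.5, 1, 1)
  u <- demons_step(s, m, list(gx = matrix(1, 1, 1), gy = matrix(0, 1, 1)), 1)
  expect_equal(u$ux[1, 1], 0.4)
  expect_equal(u$uy[1, 1], 0)
  ## s = m everywhere: zero increment
  img <- matrix(runif(25), 5, 5)
  g <- list(gx = matrix(1, 5, 5), gy = matrix(1, 5, 5))
  u0 <- demons_step(img, img, g, 1)
  expect_true(all(u0$ux == 0) && all(u0$uy == 0))
  ## zero gradient with nonzero mismatch: denominator guard applies but the
  ## alpha^2 (s - m)^2 term keeps the denominator finite; increment is 0
  uz <- demons_step(matrix(1, 2, 2), matrix(1, 2, 2),
                    list(gx = matrix(0, 2, 2), gy = matrix(0, 2, 2)), 1)
  expect_true(all(uz$ux == 0))
  expect_error(demons_step(s, m, g, alpha = 0), "alpha")
})

test_that("the Demons increment matches a scalar reference implementation", {
  set.seed(13)
  s <- matrix(runif(20 * 16), 20, 16)
  m <- matrix(runif(20 * 16), 20, 16)
  gx <- matrix(rnorm(20 * 16), 20, 16)
  gy <- matrix(rnorm(20 * 16), 20, 16)
  u <- demons_step(s, m, list(gx = gx, gy = gy), alpha = 0.7)
  ref <- demons_step_bruteforce(s, m, gx, gy, alpha = 0.7)
  expect_lt(max(abs(u$ux - ref$ux)), 1e-12)
  expect_lt(max(abs(u$uy - ref$uy)), 1e-12)
})

test_that("Demons iteration recovers a planted nonrigid warp", {
  base <- random_blob_image(96, 96, 60, seed = 14)
  pair <- make_registration_pair(base, nonrigid_amplitude_px = 2,
                                 nonrigid_period_px = 40)
  ## identical inputs: zero field after one iteration
  same <- demons_register(base, base)
  expect_lt(max(abs(same$field)), 1e-6)
  expect_length(same$ssim_trace, 2)        # initial + single iteration
  ## e2 = +Inf also stops after the first iteration
  one <- demons_register(pair$fixed, pair$moving, e2 = Inf)
  expect_length(one$ssim_trace, 2)
  ## full run (iterate while SSIM still improves): mean EPE < 0.5 px
  reg <- demons_register(pair$fixed, pair$moving, e2 = 0, max_iters = 300)
  epe <- sqrt((reg$field[, , 1] - pair$field[, , 1])^2 +
              (reg$field[, , 2] - pair$field[, , 2])^2)
  fg <- pair$fixed > 0.1
  expect_lt(mean(epe[fg]), 0.5)
  expect_gt(reg$ssim, compute_ssim(pair$fixed, pair$moving,
                                   mask = pair$fixed > 0))
})

test_that("the composed warp is applied to all bands with one resampling", {
  cfg <- test_config_small()
  wl <- cfg$bands$wavelengths
  set.seed(15)
  dn <- array(runif(40 * 40 * 4), c(40, 40, 4))
  ms <- ms_stack(dn, wl[1:4])
  zero_field <- array(0, c(40, 40, 2))
  out <- apply_full_registration(ms, diag(3), zero_field)
  expect_equal(out$dn, dn, tolerance = 1e-12)
  ## consistency: the warped band equals warping that band alone
  A <- make_registration_pair(random_blob_image(40, 40, 10, seed = 1),
                              rotation_deg = 5)$A
  Tm <- solve(A)
  field <- array(0, c(40, 40, 2)); field[, , 1] <- 0.5
  full <- apply_full_registration(ms, Tm, field)
  ## single-band reference via the composed map
  xs <- rep(0:39, each = 40) + 0.5; ys <- rep(0:39, 40)
  p <- apply_planar(solve(Tm), xs, ys)
  ref <- matrix(pmax(sample_bicubic(dn[, , 2], p$x, p$y), 0), 40, 40)
  expect_equal(full$dn[, , 2], ref, tolerance = 1e-6)
  ## composed single resampling beats warping twice
  base <- random_blob_image(64, 64, 30, seed = 16)
  pair <- make_registration_pair(base, rotation_deg = 8, scale = 1.05,
                                 nonrigid_amplitude_px = 1.5)
  st <- ms_stack(array(pair$moving, c(64, 64, 1)), 740)
  co <- adaptive_register(pair$fixed, pair$moving, "affine",
                          cfg = default_config())
  fi <- demons_register(pair$fixed, co$warped, e2 = 1e-4)
  composed <- apply_full_registration(st, co$transform, fi$field)$dn[, , 1]
  double <- warp_image(warp_image(pair$moving, co$transform,
                                  out_dim = c(64, 64)),
                       fi$field)
  msk <- pair$fixed > 0.1
  s_comp <- compute_ssim(pair$fixed, composed, mask = msk)
  s_doub <- compute_ssim(pair$fixed, double, mask = msk)
  expect_gte(s_comp, s_doub - 1e-3)
})
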