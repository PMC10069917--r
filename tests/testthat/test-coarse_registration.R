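test_that("box-filter Hessian responses match a dense brute-force reference", {
  set.seed(5)
  img <- matrix(runif(48 * 40), 40, 48)
  hr <- hessian_response(img, c(9L, 15L, 21L))
  for (s in 1:3) {
    bf <- hessian_bruteforce(img, c(9, 15, 21)[s])
    ok <- !is.na(bf)
    expect_lt(max(abs(hr$responses[[s]][ok] - bf[ok])), 1e-9)
  }
  ## printed-form variant (w * Dxy^2)
  hrl <- hessian_response(img, c(9L, 15L, 21L), w_mode = "linear")
  bfl <- hessian_bruteforce(img, 9, squared = FALSE)
  ok <- !is.na(bfl)
  expect_lt(max(abs(hrl$responses[[1]][ok] - bfl[ok])), 1e-9)
  ## constant image: all second derivatives vanish
  hc <- hessian_response(matrix(3, 32, 32), c(9L, 15L, 21L))
  expect_true(all(abs(hc$responses[[1]][!is.na(hc$responses[[1]])]) < 1e-12))
  expect_error(hessian_response(matrix(0, 10, 10)), "smaller")
})

test_that("keypoint detection finds blob centres with scale-space suppression", {
  ## five well-separated Gaussian blobs
  h <- 96; w <- 96
  xs <- matrix(rep(0:(w - 1), each = h), h, w)
  ys <- matrix(rep(0:(h - 1), w), h, w)
  centres <- rbind(c(20, 20), c(70, 25), c(25, 70), c(70, 70), c(48, 45))
  img <- matrix(0, h, w)
  for (i in 1:5)
    img <- img + exp(-((xs - centres[i, 1])^2 + (ys - centres[i, 2])^2) / (2 * 2.5^2))
  hr <- hessian_response(img)
  kp <- detect_keypoints(hr, 0)
  expect_gte(nrow(kp), 5)
  for (i in 1:5) {
    d <- sqrt((kp$x - centres[i, 1])^2 + (kp$y - centres[i, 2])^2)
    expect_lt(min(d), 1)
  }
  expect_equal(nrow(detect_keypoints(hr, max(kp$response) * 2)), 0)
  expect_error(detect_keypoints(list(responses = hr$responses[1:2]), 0), "3 scales")
})

test_that("descriptors match identical images to themselves at distance ~0", {
  img <- random_blob_image(96, 96, 25, seed = 8)
  hr <- hessian_response(img)
  kp <- detect_keypoints(hr, 0)
  d <- surf_descriptors(img, kp)
  expect_equal(unname(sqrt(rowSums(d$descriptors^2))),
               rep(1, nrow(d$descriptors)), tolerance = 1e-6)
  m <- describe_and_match(d, d, Inf)
  expect_equal(nrow(m), nrow(d$kps))
  expect_lt(max(m$distance), 1e-6)
  expect_identical(m$fixed_idx, m$moving_idx)
  ## a zero distance threshold on distinct images leaves (almost surely) none
  img2 <- random_blob_image(96, 96, 25, seed = 9)
  d2 <- surf_descriptors(img2, detect_keypoints(hessian_response(img2), 0))
  expect_equal(nrow(describe_and_match(d, d2, 0)), 0)
})

test_that("descriptor matching is rotation tolerant", {
  img <- random_blob_image(128, 128, 40, seed = 12)
  pair <- make_registration_pair(img, rotation_deg = 10)
  d1 <- surf_descriptors(pair$fixed, detect_keypoints(hessian_response(pair$fixed), 0))
  d2 <- surf_descriptors(pair$moving, detect_keypoints(hessian_response(pair$moving), 0))
  m <- describe_and_match(d1, d2, Inf)
  expect_gte(nrow(m), 10)
  p <- apply_planar(pair$A, d1$kps$x[m$fixed_idx], d1$kps$y[m$fixed_idx])
  err <- sqrt((p$x - d2$kps$x[m$moving_idx])^2 + (p$y - d2$kps$y[m$moving_idx])^2)
  expect_gte(mean(err < 3), 0.5)
})

test_that("planar transform estimation recovers exact and contaminated maps", {
  A <- matrix(c(1.02, -0.05, 4, 0.03, 0.98, -2, 0, 0, 1), 3, 3, byrow = TRUE)
  set.seed(2)
  src <- cbind(runif(12, 0, 100), runif(12, 0, 100))
  p <- apply_planar(A, src[, 1], src[, 2])
  dst <- cbind(p$x, p$y)
  ## exact correspondences: parameters recovered to 1e-9
  T1 <- estimate_transform(src[1:4, ], dst[1:4, ], "affine", ransac_iters = 0)
  expect_lt(max(abs(T1 - A)), 1e-9)
  ## identity correspondences
  T0 <- estimate_transform(src, src, "affine", ransac_iters = 0)
  expect_lt(max(abs(T0 - diag(3))), 1e-9)
  ## 80% inliers, 20% uniform outliers, fixed seed
  dst_c <- dst
  dst_c[1:2, ] <- matrix(runif(4, 0, 100), 2, 2)  # 2 of 12 corrupted
  n_out <- 2
  Tr <- estimate_transform(src, dst_c, "affine", ransac_iters = 200,
                           tol_px = 1, seed = 7)
  corners <- rbind(c(0, 0), c(100, 0), c(0, 100), c(100, 100))
  pg <- apply_planar(A, corners[, 1], corners[, 2])
  pe <- apply_planar(Tr, corners[, 1], corners[, 2])
  expect_lt(max(sqrt((pg$x - pe$x)^2 + (pg$y - pe$y)^2)), 0.5)
  expect_error(estimate_transform(src[1:2, ], dst[1:2, ], "affine"), ">= 3")
  ## similarity and projective round-trip on exact data
  Ts <- estimate_transform(src[1:2, ], dst[1:2, ], "similarity", ransac_iters = 0)
  expect_equal(dim(Ts), c(3, 3))
  Tp <- estimate_transform(src[1:6, ], dst[1:6, ], "projective", ransac_iters = 0)
  pp <- apply_planar(Tp, src[, 1], src[, 2])
  expect_lt(max(abs(pp$x - dst[, 1])), 1e-6)
})

test_that("warping is exact on integer maps and self-consistent under inversion", {
  img <- random_blob_image(64, 64, 15, seed = 4)
  expect_equal(warp_image(img, diag(3)), img, tolerance = 1e-12)
  Tt <- diag(3); Tt[1, 3] <- 3; Tt[2, 3] <- -2   # moving -> fixed shift
  w <- warp_image(img, Tt)
  expect_equal(w[10:60, 10:60], img[(10:60) + 2, (10:60) - 3], tolerance = 1e-12)
  A <- make_registration_pair(img, rotation_deg = 7, scale = 1.03)$A
  ## T then T^-1 returns the original up to interpolation loss
  w1 <- warp_image(img, solve(A))
  w2 <- warp_image(w1, A)
  ctr <- 16:48
  expect_gt(compute_ssim(img[ctr, ctr], w2[ctr, ctr]), 0.98)
  expect_error(warp_image(img, matrix(0, 3, 3)), "invertible")
})

test_that("adaptive threshold search improves SSIM and respects its stop rule", {
  img <- random_blob_image(96, 96, 60, seed = 6)
  cfg <- default_config()
  ## trivial pair: near-perfect SSIM, near-identity transform
  self <- adaptive_register(img, img, "affine", cfg = cfg)
  expect_gt(self$ssim, 0.999)
  expect_lt(max(abs(self$transform - diag(3))), 0.2)
  ## e1 = +Inf stops after exactly one round
  one <- adaptive_register(img, img, "affine", e1 = Inf, cfg = cfg)
  expect_length(one$ssim_trace, 1)
  ## planted affine pair: recovered corner error < 1 px, SSIM improves
  pair <- make_registration_pair(img, rotation_deg = 6, scale = 1.04,
                                 translation_px = c(4, -2))
  reg <- adaptive_register(pair$fixed, pair$moving, "affine", cfg = cfg)
  corners <- rbind(c(0, 0), c(95, 0), c(0, 95), c(95, 95))
  pg <- apply_planar(pair$A, corners[, 1], corners[, 2])
  pe <- apply_planar(solve(reg$transform), corners[, 1], corners[, 2])
  expect_lt(max(sqrt((pg$x - pe$x)^2 + (pg$y - pe$y)^2)), 1)
  ## best-ever SSIM is monotone non-decreasing across rounds
  expect_true(all(diff(reg$ssim_trace) >= -1e-12))
  m0 <- (pair$fixed > 0) | (pair$moving > 0)
  expect_gt(reg$ssim, compute_ssim(pair$fixed, pair$moving, mask = m0))
})
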