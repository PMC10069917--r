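## a tiny fabricated frame set: smooth known mapping features -> DN
make_toy_frames <- function(n_frames = 4, h = 12, w = 15, B = 6, seed = 1) {
  withr::with_seed(seed, lapply(seq_len(n_frames), function(i) {
    feats <- array(0, c(h, w, 8))
    for (ch in 1:8) feats[, , ch] <- matrix(runif(h * w, 0.2, 1), h, w)
    dn <- array(0, c(h, w, B))
    ## smooth function of the 5-feature relational subset only, so both the
    ## 5- and 8-input models can represent it exactly
    shade <- 0.3 * feats[, , 1] + 0.5 * cos(feats[, , 3]) +
      0.2 * feats[, , 2] * feats[, , 4]
    for (b in 1:B) dn[, , b] <- (0.5 + 0.1 * b) * shade
    list(features = feats, dn = dn, mask = matrix(TRUE, h, w))
  }))
}

test_that("reference databases pool masked pixels with min-max statistics", {
  frames <- make_toy_frames()
  frames[[1]]$mask[1:3, ] <- FALSE
  db <- build_reference_db(frames, 8L)
  expect_equal(nrow(db$features), 4 * 12 * 15 - 3 * 15)
  expect_equal(db$channels, c("d_i", "d_v", "theta_i", "theta_v", "theta",
                              "x", "y", "z"))
  db3 <- build_reference_db(frames, 3L)
  expect_equal(db3$channels, c("x", "y", "z"))
  expect_equal(ncol(db3$features), 3)
  ## min-max normalization: column (2, 4, 6) -> (0, 0.5, 1)
  fake <- list(fmin = 2, fmax = 6)
  expect_equal(as.vector(specpcd:::normalize_features(fake, matrix(c(2, 4, 6)))),
               c(0, 0.5, 1))
  ## constant feature column is rejected by name
  bad <- frames
  for (i in seq_along(bad)) bad[[i]]$features[, , 2] <- 1
  expect_error(build_reference_db(bad, 8L), "d_v")
})

test_that("the ANN recovers a smooth noiseless mapping and is seed-deterministic", {
  frames <- make_toy_frames(6, 15, 15, B = 4, seed = 2)
  db <- build_reference_db(frames, 5L)
  m1 <- train_ann(db, hidden_units = 10, epochs = 400, stages = 4, seed = 3)
  expect_gte(m1$report$test_r2, 0.99)
  m2 <- train_ann(db, hidden_units = 10, epochs = 400, stages = 4, seed = 3)
  expect_identical(m1$net$wts, m2$net$wts)
  expect_error(train_ann(db, split = c(1, 0, 0)), "nonempty")
  ## per-frame split also trains
  m3 <- train_ann(db, hidden_units = 10, epochs = 100, stages = 2, seed = 3,
                  split_mode = "frame")
  expect_gt(m3$report$test_r2, 0.9)
})

test_that("reference DN prediction memorizes converged noiseless rows", {
  frames <- make_toy_frames(6, 15, 15, B = 4, seed = 2)
  db <- build_reference_db(frames, 5L)
  model <- train_ann(db, hidden_units = 10, epochs = 400, stages = 4, seed = 3)
  fr <- frames[[1]]
  pred <- predict_reference_dn(model, fr$features, fr$mask)
  expect_equal(dim(pred$dn), c(15, 15, 4))
  err <- abs(pred$dn - fr$dn)
  expect_lt(median(err, na.rm = TRUE), 0.02)
  ## identical features give identical predictions
  f2 <- fr$features; f2[2, 2, ] <- f2[1, 1, ]
  p2 <- predict_reference_dn(model, f2, fr$mask)
  expect_identical(p2$dn[2, 2, ], p2$dn[1, 1, ])
  ## all-invalid mask gives all-invalid output
  p0 <- predict_reference_dn(model, fr$features, matrix(FALSE, 15, 15))
  expect_true(all(is.na(p0$dn)))
  ## out-of-hull features are flagged, not dropped
  f3 <- fr$features; f3[3, 3, ] <- 100
  p3 <- predict_reference_dn(model, f3, fr$mask)
  expect_true(p3$extrapolated[3, 3])
  expect_false(p3$extrapolated[4, 4])
  expect_true(is.finite(p3$dn[3, 3, 1]))
})

test_that("every search metric agrees with a naive linear scan", {
  set.seed(21)
  frames <- make_toy_frames(3, 10, 12, B = 3, seed = 5)
  db <- build_reference_db(frames, 8L)
  stats <- db_search_stats(db, seed = 2, max_rows = 300)
  X <- specpcd:::normalize_features(db, db$features)
  Q <- X[sample(nrow(X), 40), , drop = FALSE] +
    matrix(rnorm(40 * 8, 0, 0.03), 40, 8)
  for (metric in specpcd:::SEARCH_METRICS) {
    got <- specpcd:::nn_search(metric, Q, X, stats, k = 1L, chunk = 16L)
    ref <- nn_bruteforce(metric, Q, X, stats)
    expect_equal(got$dist[, 1], ref[, 2], tolerance = 1e-8,
                 info = metric, ignore_attr = TRUE)
    ## allow index ties at equal distance
    same <- got$idx[, 1] == ref[, 1]
    tied <- abs(got$dist[, 1] - ref[, 2]) < 1e-10
    expect_true(all(same | tied), info = metric)
  }
})

test_that("membership queries return their own row at distance zero", {
  frames <- make_toy_frames(2, 8, 10, B = 3, seed = 6)
  db <- build_reference_db(frames, 8L)
  stats <- db_search_stats(db, seed = 2, max_rows = 160)
  fr <- frames[[1]]
  for (metric in c("euclidean", "cosine", "mahalanobis", "chebychev",
                   "pca_cosine", "weighted_euclidean_v1",
                   "weighted_mahalanobis_v1")) {
    out <- search_reference_dn(db, fr$features, fr$mask, metric, stats = stats)
    expect_lt(max(out$distance, na.rm = TRUE), 1e-6)
    expect_equal(out$dn[, , 1], fr$dn[, , 1], tolerance = 1e-8)
  }
  expect_error(search_reference_dn(db, fr$features, fr$mask, "manhattan",
                                   stats = stats), "unknown metric")
})

test_that("weight constructions follow their stated conventions", {
  frames <- make_toy_frames(3, 10, 12, B = 3, seed = 5)
  db <- build_reference_db(frames, 8L)
  stats <- db_search_stats(db, seed = 2, max_rows = 300)
  expect_equal(max(stats$rf_weights), 1)         # top importance = 1.00
  expect_equal(max(stats$pc_weights), 1)         # top PC contribution = 1.00
  expect_true(all(diff(stats$pc_weights) <= 1e-12))  # descending eigenvalues
  ## v2 assigns the same multiset of weights in reverse rank order
  w <- stats$rf_weights
  w2 <- specpcd:::reverse_weights(w)
  expect_equal(unname(sort(w)), unname(sort(w2)))
  expect_equal(order(w), rev(order(w2)))
  ## PCA-cosine equals a from-scratch eigendecomposition oracle
  X <- specpcd:::normalize_features(db, db$features)
  ctr <- colMeans(X)
  C <- cov(sweep(X, 2, ctr))
  ev <- eigen(C, symmetric = TRUE)$vectors
  P1 <- abs(stats$pca_rotation)
  expect_equal(P1, abs(ev), tolerance = 1e-8)    # up to column signs
})

test_that("weighted Euclidean search accepts an externally supplied scheme", {
  ## the importance-style weighting (d_i and theta_i dominant) can be
  ## injected through the stats object and is honoured by the metric
  frames <- make_toy_frames(2, 8, 10, B = 3, seed = 8)
  db <- build_reference_db(frames, 8L)
  stats <- db_search_stats(db, seed = 2, max_rows = 160)
  stats$rf_weights <- c(0.82, 0.19, 1.00, 0.04, 0.16, 0.10, 0.84, 0.29)
  X <- specpcd:::normalize_features(db, db$features)
  q <- X[5, , drop = FALSE] + 0.01
  got <- specpcd:::nn_search("weighted_euclidean_v1", q, X, stats)
  ref <- nn_bruteforce("weighted_euclidean_v1", q, X, stats)
  expect_equal(got$dist[1, 1], ref[1, 2], tolerance = 1e-10)
  expect_equal(got$dist[1, 1],
               sqrt(sum(stats$rf_weights * (q - X[ref[1, 1], ])^2)),
               tolerance = 1e-10)
})

test_that("baseline regressors are deterministic and fit linear data", {
  frames <- make_toy_frames(3, 10, 12, B = 3, seed = 7)
  db <- build_reference_db(frames, 8L)
  t1 <- fit_baseline_regressors(db, models = c("lr", "dt"), seed = 4,
                                max_rows = 300)
  t2 <- fit_baseline_regressors(db, models = c("lr", "dt"), seed = 4,
                                max_rows = 300)
  expect_identical(t1, t2)
  ## a db whose DN is linear in the features is fit by lr with R2 ~ 1
  lin <- make_toy_frames(3, 10, 12, B = 3, seed = 9)
  for (i in seq_along(lin)) {
    f <- lin[[i]]$features
    sh <- 0.2 * f[, , 1] + 0.7 * f[, , 6]
    for (b in 1:3) lin[[i]]$dn[, , b] <- b * sh
  }
  dbl <- build_reference_db(lin, 8L)
  tl <- fit_baseline_regressors(dbl, models = "lr", feature_sets = 8L,
                                seed = 4, max_rows = 300)
  expect_gt(tl$r2, 0.999)
  expect_error(fit_baseline_regressors(db, models = "magic"), "unknown model")
})
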