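## Independent reference implementations used as oracles. These are written
## as plain double loops / direct formulas, deliberately sharing no code
## with the package internals they check.

## brute-force SSIM: explicit per-window loop with Gaussian weights
ssim_bruteforce <- function(a, b, window = 11L, sigma = 1.5, k1 = 0.01,
                            k2 = 0.03, L = 1) {
  r <- (window - 1L) / 2L
  g1 <- exp(-((-r):r)^2 / (2 * sigma^2))
  W <- outer(g1, g1); W <- W / sum(W)
  C1 <- (k1 * L)^2; C2 <- (k2 * L)^2
  h <- nrow(a); w <- ncol(a)
  vals <- c()
  for (i in (r + 1):(h - r)) for (j in (r + 1):(w - r)) {
    pa <- a[(i - r):(i + r), (j - r):(j + r)]
    pb <- b[(i - r):(i + r), (j - r):(j + r)]
    mua <- sum(W * pa); mub <- sum(W * pb)
    va <- sum(W * pa^2) - mua^2; vb <- sum(W * pb^2) - mub^2
    cab <- sum(W * pa * pb) - mua * mub
    vals <- c(vals, ((2 * mua * mub + C1) * (2 * cab + C2)) /
                ((mua^2 + mub^2 + C1) * (va + vb + C2)))
  }
  mean(vals)
}

## dense (non-integral-image) box-filter Hessian response at one filter size
hessian_bruteforce <- function(img, L, w = 0.9, squared = TRUE) {
  l <- L %/% 3L; half <- (L - 1L) %/% 2L
  h <- nrow(img); wd <- ncol(img)
  out <- matrix(NA_real_, h, wd)
  lobe_half <- (l - 1L) %/% 2L
  bsum <- function(r1, r2, c1, c2) sum(img[r1:r2, c1:c2])
  for (r in (half + 1):(h - half)) for (cc in (half + 1):(wd - half)) {
    x1 <- cc - (l - 1L); x2 <- cc + (l - 1L)
    Dyy <- bsum(r - (3 * l - 1) %/% 2, r - (l + 1) %/% 2, x1, x2) -
      2 * bsum(r - lobe_half, r + lobe_half, x1, x2) +
      bsum(r + (l + 1) %/% 2, r + (3 * l - 1) %/% 2, x1, x2)
    y1 <- r - (l - 1L); y2 <- r + (l - 1L)
    Dxx <- bsum(y1, y2, cc - (3 * l - 1) %/% 2, cc - (l + 1) %/% 2) -
      2 * bsum(y1, y2, cc - lobe_half, cc + lobe_half) +
      bsum(y1, y2, cc + (l + 1) %/% 2, cc + (3 * l - 1) %/% 2)
    Dxy <- bsum(r - l, r - 1, cc - l, cc - 1) + bsum(r + 1, r + l, cc + 1, cc + l) -
      bsum(r - l, r - 1, cc + 1, cc + l) - bsum(r + 1, r + l, cc - l, cc - 1)
    A <- L^2
    Dxx <- Dxx / A; Dyy <- Dyy / A; Dxy <- Dxy / A
    out[r, cc] <- if (squared) Dxx * Dyy - (w * Dxy)^2 else Dxx * Dyy - w * Dxy^2
  }
  out
}

## per-pixel scalar Demons increment (explicit loops)
demons_step_bruteforce <- function(s, m, gx, gy, alpha, eps = 1e-9) {
  h <- nrow(s); w <- ncol(s)
  ux <- matrix(0, h, w); uy <- matrix(0, h, w)
  for (i in 1:h) for (j in 1:w) {
    d <- s[i, j] - m[i, j]
    den <- gx[i, j]^2 + gy[i, j]^2 + alpha^2 * d^2
    if (den >= eps) { ux[i, j] <- d * gx[i, j] / den; uy[i, j] <- d * gy[i, j] / den }
  }
  list(ux = ux, uy = uy)
}

## naive linear-scan nearest neighbour under each metric, double loop
nn_bruteforce <- function(metric, Q, X, stats) {
  dfun <- switch(metric,
    euclidean = function(q, x) sqrt(sum((q - x)^2)),
    weighted_euclidean_v1 = function(q, x) sqrt(sum(stats$rf_weights * (q - x)^2)),
    weighted_euclidean_v2 = {
      w <- stats$rf_weights
      w2 <- w; w2[order(w, decreasing = TRUE)] <- sort(w)
      function(q, x) sqrt(sum(w2 * (q - x)^2))
    },
    cosine = function(q, x) 1 - sum(q * x) / sqrt(sum(q^2) * sum(x^2)),
    mahalanobis = function(q, x) sqrt(mahalanobis(rbind(q), x, stats$cov)),
    chebychev = function(q, x) max(abs(q - x)),
    pca_cosine = function(q, x) {
      qp <- as.vector((q - stats$pca_center) %*% stats$pca_rotation)
      xp <- as.vector((x - stats$pca_center) %*% stats$pca_rotation)
      1 - sum(qp * xp) / sqrt(sum(qp^2) * sum(xp^2))
    },
    weighted_mahalanobis_v1 = ,
    weighted_mahalanobis_v2 = {
      w <- stats$pc_weights
      if (metric == "weighted_mahalanobis_v2") {
        w2 <- w; w2[order(w, decreasing = TRUE)] <- sort(w); w <- w2
      }
      lam <- pmax(stats$pca_values, 1e-12)
      function(q, x) {
        dp <- as.vector((q - x) %*% stats$pca_rotation)
        sqrt(sum(w * dp^2 / lam))
      }
    })
  t(apply(Q, 1, function(q) {
    d <- apply(X, 1, function(x) dfun(q, x))
    c(which.min(d), min(d))
  }))
}

## small shared camera for fast scene tests
test_camera <- function() camera_intrinsics(120, 120, 47.5, 35.5, 96, 72)

test_config_small <- function() {
  cfg <- default_config()
  cfg$cameras$ms <- list(fx = 120, fy = 120, cx = 47.5, cy = 35.5,
                         width = 96L, height = 72L)
  cfg$reference$reflectance <- 0.6
  cfg
}
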