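## Coarse registration: scale-space keypoints from approximated Hessian
## determinants computed with box filters on integral images, 64-dim
## oriented descriptors, mutual-nearest-neighbour matching, robust planar
## transform estimation, and the SSIM-ranked adaptive threshold search.

#' Approximated Hessian determinant responses over a box-filter scale space
#'
#' For each filter size L (9, 15, 21, ... in octave steps) the second-order
#' box-filter responses Dxx, Dyy, Dxy are computed on the integral image,
#' normalized by the filter area, and combined into
#' c(x, y, sigma) = Dxx * Dyy - (w * Dxy)^2 with w = 0.9 (the relative
#' weight balancing the Gaussian approximation). `w_mode = "linear"`
#' instead combines Dxx * Dyy - w * Dxy^2.
#'
#' @param image single-channel matrix
#' @param filter_sizes box filter sides, each a multiple of 3, increasing
#' @param w relative weight of the mixed response (default 0.9)
#' @param w_mode "squared" for (w Dxy)^2, "linear" for w Dxy^2
#' @return list with `responses` (list of H x W matrices, NA where the
#'   filter does not fit), `sizes`, and `sigmas` (1.2 * L / 9)
#' @export
hessian_response <- function(image, filter_sizes = c(9L, 15L, 21L, 27L),
                             w = 0.9, w_mode = c("squared", "linear")) {
  w_mode <- match.arg(w_mode)
  if (any(filter_sizes %% 3 != 0) || any(filter_sizes %% 2 == 0))
    stopf("filter sizes must be odd multiples of 3")
  if (min(dim(image)) < max(filter_sizes))
    stopf("image (%d x %d) smaller than the largest filter (%d)",
          nrow(image), ncol(image), max(filter_sizes))
  S <- integral_image(image)
  h <- nrow(image); w_img <- ncol(image)
  res <- lapply(filter_sizes, function(L) {
    l <- L %/% 3L
    half <- (L - 1L) %/% 2L
    rr <- (half + 1L):(h - half)
    cc <- (half + 1L):(w_img - half)
    r <- matrix(rep(rr, times = length(cc)), ncol = length(cc))
    c2 <- matrix(rep(cc, each = length(rr)), ncol = length(cc))
    rv <- as.vector(r); cv <- as.vector(c2)
    lobe_half <- (l - 1L) %/% 2L
    ## Dyy: three stacked (l tall) x (2l-1 wide) bands, weights 1, -2, 1
    x1 <- cv - (l - 1L); x2 <- cv + (l - 1L)
    top <- box_sum(S, rv - (3L * l - 1L) %/% 2L, rv - (l + 1L) %/% 2L, x1, x2)
    mid <- box_sum(S, rv - lobe_half, rv + lobe_half, x1, x2)
    bot <- box_sum(S, rv + (l + 1L) %/% 2L, rv + (3L * l - 1L) %/% 2L, x1, x2)
    Dyy <- top - 2 * mid + bot
    ## Dxx: transpose of the same pattern
    y1 <- rv - (l - 1L); y2 <- rv + (l - 1L)
    left <- box_sum(S, y1, y2, cv - (3L * l - 1L) %/% 2L, cv - (l + 1L) %/% 2L)
    cen <- box_sum(S, y1, y2, cv - lobe_half, cv + lobe_half)
    rgt <- box_sum(S, y1, y2, cv + (l + 1L) %/% 2L, cv + (3L * l - 1L) %/% 2L)
    Dxx <- left - 2 * cen + rgt
    ## Dxy: four l x l quadrant boxes
    tl <- box_sum(S, rv - l, rv - 1L, cv - l, cv - 1L)
    tr <- box_sum(S, rv - l, rv - 1L, cv + 1L, cv + l)
    bl <- box_sum(S, rv + 1L, rv + l, cv - l, cv - 1L)
    br <- box_sum(S, rv + 1L, rv + l, cv + 1L, cv + l)
    Dxy <- tl + br - tr - bl
    A <- as.numeric(L)^2
    Dxx <- Dxx / A; Dyy <- Dyy / A; Dxy <- Dxy / A
    cres <- if (w_mode == "squared") Dxx * Dyy - (w * Dxy)^2
            else Dxx * Dyy - w * Dxy^2
    out <- matrix(NA_real_, h, w_img)
    out[cbind(rv, cv)] <- cres
    out
  })
  list(responses = res, sizes = as.integer(filter_sizes),
       sigmas = 1.2 * filter_sizes / 9)
}

#' Detect scale-space keypoints by 3 x 3 x 3 nonmaximum suppression
#'
#' A pixel is a keypoint when its response is at least `c_threshold` and
#' strictly greater than its 26 neighbours in the 3 x 3 x 3 scale-space
#' neighbourhood (so only interior scales can fire). Subpixel position is
#' refined by an in-plane quadratic fit.
#'
#' @param hr output of [hessian_response()] (>= 3 scales)
#' @param c_threshold minimum Hessian response
#' @return data.frame with columns x, y (0-based subpixel), sigma, size,
#'   response
#' @export
detect_keypoints <- function(hr, c_threshold = 0) {
  res <- hr$responses
  ns <- length(res)
  if (ns < 3) stopf("at least 3 scales are required for 3x3x3 suppression")
  h <- nrow(res[[1]]); w <- ncol(res[[1]])
  out <- list()
  shift <- function(m, dr, dc) {
    o <- matrix(-Inf, h, w)
    r_src <- max(1, 1 - dr):min(h, h - dr)
    c_src <- max(1, 1 - dc):min(w, w - dc)
    o[r_src + dr, c_src + dc] <- m[r_src, c_src]
    o
  }
  for (s in 2:(ns - 1)) {
    cur <- res[[s]]
    ok <- !is.na(cur) & cur >= c_threshold
    if (!any(ok)) next
    curI <- cur; curI[is.na(curI)] <- -Inf
    cmp <- matrix(TRUE, h, w)
    for (ds in -1:1) {
      lay <- res[[s + ds]]
      lay[is.na(lay)] <- -Inf
      for (dr in -1:1) for (dc in -1:1) {
        if (ds == 0 && dr == 0 && dc == 0) next
        cmp <- cmp & (curI > shift(lay, dr, dc))
      }
    }
    sel <- which(ok & cmp, arr.ind = TRUE)
    if (!nrow(sel)) next
    r <- sel[, 1]; c2 <- sel[, 2]
    ## in-plane quadratic refinement (central differences)
    interior <- r > 1 & r < h & c2 > 1 & c2 < w
    dx <- dy <- numeric(nrow(sel))
    if (any(interior)) {
      ri <- r[interior]; ci <- c2[interior]
      gx <- (cur[cbind(ri, ci + 1)] - cur[cbind(ri, ci - 1)]) / 2
      gy <- (cur[cbind(ri + 1, ci)] - cur[cbind(ri - 1, ci)]) / 2
      hxx <- cur[cbind(ri, ci + 1)] - 2 * cur[cbind(ri, ci)] + cur[cbind(ri, ci - 1)]
      hyy <- cur[cbind(ri + 1, ci)] - 2 * cur[cbind(ri, ci)] + cur[cbind(ri - 1, ci)]
      hxy <- (cur[cbind(ri + 1, ci + 1)] - cur[cbind(ri + 1, ci - 1)] -
              cur[cbind(ri - 1, ci + 1)] + cur[cbind(ri - 1, ci - 1)]) / 4
      det <- hxx * hyy - hxy^2
      okd <- is.finite(det) & abs(det) > 1e-12
      ox <- ifelse(okd, -(hyy * gx - hxy * gy) / det, 0)
      oy <- ifelse(okd, -(hxx * gy - hxy * gx) / det, 0)
      dx[interior] <- clampv(ifelse(is.finite(ox), ox, 0), -0.5, 0.5)
      dy[interior] <- clampv(ifelse(is.finite(oy), oy, 0), -0.5, 0.5)
    }
    out[[length(out) + 1]] <- data.frame(
      x = (c2 - 1) + dx, y = (r - 1) + dy,
      sigma = hr$sigmas[s], size = hr$sizes[s],
      response = cur[cbind(r, c2)])
  }
  if (!length(out))
    return(data.frame(x = numeric(0), y = numeric(0), sigma = numeric(0),
                      size = integer(0), response = numeric(0)))
  do.call(rbind, out)
}

## Haar-like responses at sample points (vectorized over points) using the
## integral image: dx = right box - left box, dy = bottom box - top box,
## box half-side = round(sz/2).
haar_xy <- function(S, x, y, sz) {
  half <- pmax(1, round(sz / 2))
  r <- round(y) + 1; c2 <- round(x) + 1
  left <- box_sum(S, r - half, r + half, c2 - half, c2 - 1)
  right <- box_sum(S, r - half, r + half, c2 + 1, c2 + half)
  top <- box_sum(S, r - half, r - 1, c2 - half, c2 + half)
  bot <- box_sum(S, r + 1, r + half, c2 - half, c2 + half)
  list(dx = right - left, dy = bot - top)
}

## Dominant orientation: Haar responses in a 6-sigma disc, sampled on a
## sigma-spaced grid, Gaussian-weighted; a pi/3 sliding window over the
## response angles picks the strongest summed vector.
surf_orientation <- function(S, kp, h, w) {
  s <- kp$sigma
  g <- expand.grid(i = -6:6, j = -6:6)
  g <- g[g$i^2 + g$j^2 <= 36, ]
  px <- kp$x + g$i * s; py <- kp$y + g$j * s
  ok <- px > 2 * s & px < (w - 1 - 2 * s) & py > 2 * s & py < (h - 1 - 2 * s)
  if (sum(ok) < 12) return(0)
  hv <- haar_xy(S, px[ok], py[ok], 2 * s)
  wgt <- exp(-(g$i[ok]^2 + g$j[ok]^2) / (2 * 2.5^2))
  rx <- hv$dx * wgt; ry <- hv$dy * wgt
  ang <- atan2(ry, rx)
  best <- c(0, -Inf)
  for (a0 in seq(-pi, pi, length.out = 37)[-37]) {
    d <- ang - a0
    d <- atan2(sin(d), cos(d))
    inwin <- abs(d) <= pi / 6
    if (!any(inwin)) next
    sx <- sum(rx[inwin]); sy <- sum(ry[inwin])
    m2 <- sx^2 + sy^2
    if (m2 > best[2]) best <- c(atan2(sy, sx), m2)
  }
  best[1]
}

#' Compute 64-dimensional oriented descriptors for keypoints
#'
#' Classic formulation: a 20-sigma square window aligned with the dominant
#' orientation, split into 4 x 4 subregions of 5 x 5 samples; per subregion
#' the Gaussian-weighted sums (sum dx, sum dy, sum |dx|, sum |dy|) of
#' rotated Haar responses form the descriptor, normalized to unit length.
#'
#' @param image single-channel matrix
#' @param kps keypoint data.frame from [detect_keypoints()]
#' @return list with `kps` (possibly reduced: window must fit) and
#'   `descriptors` (N x 64 matrix, unit rows)
#' @export
surf_descriptors <- function(image, kps) {
  h <- nrow(image); w <- ncol(image)
  S <- integral_image(image)
  n <- nrow(kps)
  if (n == 0) return(list(kps = kps, descriptors = matrix(0, 0, 64)))
  ## sample lattice: subregion index (4x4), sample index (5x5)
  sub <- expand.grid(sx = 0:3, sy = 0:3)
  samp <- expand.grid(ix = 0:4, iy = 0:4)
  ## sample offsets in units of sigma, centred on the window
  offs <- do.call(rbind, lapply(seq_len(nrow(sub)), function(k) {
    data.frame(sub = k,
               ox = (sub$sx[k] * 5 + samp$ix + 0.5) - 10,
               oy = (sub$sy[k] * 5 + samp$iy + 0.5) - 10)
  }))
  gw <- exp(-(offs$ox^2 + offs$oy^2) / (2 * 3.3^2))
  desc <- matrix(0, n, 64)
  keep <- logical(n)
  for (i in seq_len(n)) {
    kp <- kps[i, ]
    s <- kp$sigma
    th <- surf_orientation(S, kp, h, w)
    ct <- cos(th); st <- sin(th)
    px <- kp$x + s * (ct * offs$ox - st * offs$oy)
    py <- kp$y + s * (st * offs$ox + ct * offs$oy)
    ## clamp samples into the Haar support (border keypoints keep a
    ## slightly truncated window rather than being dropped)
    m <- 1 + ceiling(s)
    px <- clampv(px, m, w - 1 - m); py <- clampv(py, m, h - 1 - m)
    hv <- haar_xy(S, px, py, s)
    ## rotate responses into the keypoint frame
    rdx <- (ct * hv$dx + st * hv$dy) * gw
    rdy <- (-st * hv$dx + ct * hv$dy) * gw
    v <- numeric(64)
    for (k in 1:16) {
      idx <- offs$sub == k
      v[(k - 1) * 4 + 1:4] <- c(sum(rdx[idx]), sum(rdy[idx]),
                                sum(abs(rdx[idx])), sum(abs(rdy[idx])))
    }
    nv <- sqrt(sum(v^2))
    if (nv > 0) { desc[i, ] <- v / nv; keep[i] <- TRUE }
  }
  list(kps = kps[keep, , drop = FALSE],
       descriptors = desc[keep, , drop = FALSE])
}

#' Match keypoints by mutual nearest neighbours in descriptor space
#'
#' Candidate pairs are mutual nearest neighbours under Euclidean descriptor
#' distance; pairs with distance above `d_threshold` are discarded.
#'
#' @param fixed,moving lists from [surf_descriptors()] (`kps` + `descriptors`)
#' @param d_threshold maximum descriptor distance (Inf keeps all mutual NN)
#' @return data.frame: fixed_idx, moving_idx, distance (possibly empty)
#' @export
describe_and_match <- function(fixed, moving, d_threshold = Inf) {
  Fd <- fixed$descriptors; Md <- moving$descriptors
  if (!nrow(Fd) || !nrow(Md))
    return(data.frame(fixed_idx = integer(0), moving_idx = integer(0),
                      distance = numeric(0)))
  ## squared distances via the expansion |a-b|^2 = |a|^2 + |b|^2 - 2ab
  G <- Fd %*% t(Md)
  d2 <- pmax(outer(rowSums(Fd^2), rowSums(Md^2), "+") - 2 * G, 0)
  nn_f <- max.col(-d2)                       # for each fixed: best moving
  nn_m <- max.col(-t(d2))                    # for each moving: best fixed
  fi <- which(nn_m[nn_f] == seq_len(nrow(Fd)))
  mi <- nn_f[fi]
  d <- sqrt(d2[cbind(fi, mi)])
  keep <- d <= d_threshold
  data.frame(fixed_idx = fi[keep], moving_idx = mi[keep], distance = d[keep])
}

## ---- planar transforms ----------------------------------------------------

solve_similarity <- function(src, dst) {
  ## least-squares similarity (rotation + isotropic scale + translation)
  mu_s <- colMeans(src); mu_d <- colMeans(dst)
  A <- sweep(src, 2, mu_s); B <- sweep(dst, 2, mu_d)
  Sxx <- sum(A[, 1] * B[, 1]) + sum(A[, 2] * B[, 2])
  Sxy <- sum(A[, 1] * B[, 2]) - sum(A[, 2] * B[, 1])
  den <- sum(A^2)
  if (den < 1e-12) return(NULL)
  a <- Sxx / den; b <- Sxy / den
  R <- matrix(c(a, -b, b, a), 2, 2, byrow = TRUE)
  t <- mu_d - R %*% mu_s
  rbind(cbind(R, t), c(0, 0, 1))
}

solve_affine <- function(src, dst) {
  X <- cbind(src, 1)
  fit <- tryCatch(qr.solve(X, dst), error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  rbind(t(fit), c(0, 0, 1))
}

solve_projective <- function(src, dst) {
  n <- nrow(src)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    x <- src[i, 1]; y <- src[i, 2]; u <- dst[i, 1]; v <- dst[i, 2]
    A[2 * i - 1, ] <- c(-x, -y, -1, 0, 0, 0, u * x, u * y, u)
    A[2 * i, ] <- c(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  }
  sv <- svd(A, nv = 9)
  hvec <- sv$v[, 9]
  H <- matrix(hvec, 3, 3, byrow = TRUE)
  if (abs(H[3, 3]) < 1e-12) return(NULL)
  H / H[3, 3]
}

#' Apply a 3 x 3 planar transform to point coordinates
#'
#' @param T 3 x 3 similarity/affine/projective matrix
#' @param x,y coordinate vectors
#' @return list with transformed `x`, `y`
#' @export
apply_planar <- function(T, x, y) {
  d <- T[3, 1] * x + T[3, 2] * y + T[3, 3]
  list(x = (T[1, 1] * x + T[1, 2] * y + T[1, 3]) / d,
       y = (T[2, 1] * x + T[2, 2] * y + T[2, 3]) / d)
}

#' Estimate a planar transform from matched point pairs
#'
#' Robust consensus (inlier resampling with a fixed seed) followed by a
#' least-squares refit on the consensus inliers. The returned matrix maps
#' moving coordinates to fixed coordinates.
#'
#' @param src N x 2 moving-image points (x, y)
#' @param dst N x 2 fixed-image points
#' @param kind "similarity", "affine" or "projective"
#' @param ransac_iters resampling iterations (0 = plain least squares)
#' @param tol_px inlier tolerance (px)
#' @param seed RNG seed for the resampling
#' @return 3 x 3 transform matrix (moving -> fixed)
#' @export
estimate_transform <- function(src, dst, kind = c("affine", "similarity",
                                                  "projective"),
                               ransac_iters = 200L, tol_px = 2.0, seed = 7L) {
  kind <- match.arg(kind)
  src <- as.matrix(src); dst <- as.matrix(dst)
  min_n <- c(similarity = 2L, affine = 3L, projective = 4L)[[kind]]
  if (nrow(src) < min_n)
    stopf("%s transform needs >= %d pairs, got %d", kind, min_n, nrow(src))
  solver <- switch(kind, similarity = solve_similarity, affine = solve_affine,
                   projective = solve_projective)
  fit_all <- function(idx) solver(src[idx, , drop = FALSE], dst[idx, , drop = FALSE])
  n <- nrow(src)
  best_inliers <- seq_len(n)
  if (ransac_iters > 0 && n > min_n) {
    best_cnt <- -1L
    with_seed(seed, {
      for (it in seq_len(ransac_iters)) {
        idx <- sample.int(n, min_n)
        T0 <- fit_all(idx)
        if (is.null(T0)) next
        p <- apply_planar(T0, src[, 1], src[, 2])
        err <- sqrt((p$x - dst[, 1])^2 + (p$y - dst[, 2])^2)
        inl <- which(err <= tol_px)
        if (length(inl) > best_cnt) { best_cnt <- length(inl); best_inliers <- inl }
      }
    })
    if (length(best_inliers) < min_n) best_inliers <- seq_len(n)
  }
  T <- fit_all(best_inliers)
  if (is.null(T)) stopf("degenerate point configuration")
  if (abs(det(T)) < 1e-12) stopf("estimated transform is singular")
  T
}

#' Warp an image by a planar transform or a displacement field
#'
#' For a 3 x 3 transform T (moving -> fixed) the output at fixed pixel x is
#' the bicubic sample of the image at T^-1(x); for an H x W x 2 displacement
#' field t the output at x is the sample at x + t(x). Out-of-frame samples
#' are 0.
#'
#' @param image source (moving) image
#' @param transform 3 x 3 matrix or H x W x 2 displacement field (dx, dy)
#' @param out_dim c(H, W) of the output grid (defaults to the field's grid
#'   or the image size)
#' @param interpolation "bicubic" or "bilinear"
#' @return warped image on the output grid
#' @export
warp_image <- function(image, transform, out_dim = NULL,
                       interpolation = c("bicubic", "bilinear")) {
  interpolation <- match.arg(interpolation)
  sampler <- if (interpolation == "bicubic") sample_bicubic else sample_bilinear
  if (is.matrix(transform) && all(dim(transform) == c(3, 3))) {
    if (abs(det(transform)) < 1e-12) stopf("transform is not invertible")
    od <- out_dim %||% dim(image)
    h <- od[1]; w <- od[2]
    xs <- rep(0:(w - 1), each = h); ys <- rep(0:(h - 1), w)
    Ti <- solve(transform)
    p <- apply_planar(Ti, xs, ys)
    matrix(sampler(image, p$x, p$y), h, w)
  } else if (length(dim(transform)) == 3 && dim(transform)[3] == 2) {
    h <- dim(transform)[1]; w <- dim(transform)[2]
    xs <- rep(0:(w - 1), each = h) + as.vector(transform[, , 1])
    ys <- rep(0:(h - 1), w) + as.vector(transform[, , 2])
    matrix(sampler(image, xs, ys), h, w)
  } else stopf("transform must be 3x3 or an H x W x 2 field")
}

#' Adaptive SURF registration with an SSIM-ranked threshold search
#'
#' Keypoints and matches are computed once; a grid of candidate
#' (response, distance) threshold pairs is then scored: each node filters
#' the keypoint matches, estimates a planar transform, warps the moving
#' image onto the fixed grid and records the SSIM. The grid interval is
#' shrunk to the index span of the four best-SSIM nodes and re-divided;
#' rounds stop when the relative gain of the best-ever SSIM drops to `e1`
#' or `max_rounds` is reached. The best-ever transform is returned, so the
#' reported SSIM is non-decreasing across rounds.
#'
#' @param fixed,moving preprocessed single-channel images (masked,
#'   histogram-matched); sizes may differ
#' @param kind transform family ("affine", "similarity", "projective")
#' @param grid_i,grid_j node counts of the response / distance grid
#' @param e1 relative SSIM gain stopping threshold
#' @param max_rounds maximum search rounds
#' @param cfg configuration (SSIM and SURF parameter blocks)
#' @return list: `transform` (3 x 3 moving -> fixed), `warped`, `ssim`
#'   (best SSIM), `ssim_trace` (best-ever SSIM per round), `n_matches`
#' @export
adaptive_register <- function(fixed, moving, kind = "affine",
                              grid_i = 10L, grid_j = 10L, e1 = 0.01,
                              max_rounds = 5L, cfg = default_config()) {
  sp <- cfg$surf
  hrf <- hessian_response(fixed, sp$filter_sizes, sp$hessian_w, sp$hessian_w_mode)
  hrm <- hessian_response(moving, sp$filter_sizes, sp$hessian_w, sp$hessian_w_mode)
  kf <- detect_keypoints(hrf, 0)
  km <- detect_keypoints(hrm, 0)
  if (!nrow(kf) || !nrow(km))
    stopf("coarse registration failed: no keypoints detected")
  df <- surf_descriptors(fixed, kf)
  dm <- surf_descriptors(moving, km)
  matches <- describe_and_match(df, dm, Inf)
  if (nrow(matches) < 3)
    stopf("coarse registration failed: %d matches", nrow(matches))
  resp_f <- df$kps$response[matches$fixed_idx]
  resp_m <- dm$kps$response[matches$moving_idx]
  pair_resp <- pmin(resp_f, resp_m)   # a pair survives threshold c iff both do
  c_rng <- range(pair_resp); d_rng <- range(matches$distance)
  grid_nodes <- function(lo, hi, k) {
    if (hi <= lo) return(lo)
    seq(lo, hi, length.out = k + 2L)[2:(k + 1L)]
  }
  c_nodes <- grid_nodes(c_rng[1], c_rng[2], grid_i)
  d_nodes <- grid_nodes(d_rng[1], d_rng[2], grid_j)
  mask_u <- NULL
  if (isTRUE(cfg$ssim$on_foreground)) mask_u <- fixed > 0
  score_T <- function(T) {
    warped <- warp_image(moving, T, out_dim = dim(fixed))
    m <- mask_u
    if (!is.null(m)) m <- m | (warped > 0)
    list(ssim = ssim_from_config(fixed, warped, cfg, mask = m), warped = warped)
  }
  best <- list(ssim = -Inf, transform = NULL, warped = NULL)
  trace <- numeric(0)
  ## baseline for the round-1 stop check: similarity of the unregistered
  ## pair on the shared grid (0 when the grids differ)
  prev_best <- if (all(dim(fixed) == dim(moving))) {
    m0 <- mask_u
    if (!is.null(m0)) m0 <- m0 | (moving > 0)
    ssim_from_config(fixed, moving, cfg, mask = m0)
  } else 0
  for (round in seq_len(max_rounds)) {
    node_ssim <- matrix(NA_real_, length(c_nodes), length(d_nodes))
    seen <- new.env(parent = emptyenv())
    for (ci in seq_along(c_nodes)) for (dj in seq_along(d_nodes)) {
      keep <- pair_resp >= c_nodes[ci] & matches$distance <= d_nodes[dj]
      if (sum(keep) < 3) next
      key <- paste(which(keep), collapse = ",")
      if (!is.null(seen[[key]])) { node_ssim[ci, dj] <- seen[[key]]; next }
      T <- tryCatch(
        estimate_transform(
          cbind(dm$kps$x[matches$moving_idx[keep]],
                dm$kps$y[matches$moving_idx[keep]]),
          cbind(df$kps$x[matches$fixed_idx[keep]],
                df$kps$y[matches$fixed_idx[keep]]),
          kind, sp$ransac_iters, sp$ransac_tol_px),
        error = function(e) NULL)
      if (is.null(T)) { seen[[key]] <- NA_real_; next }
      sc <- score_T(T)
      node_ssim[ci, dj] <- sc$ssim
      seen[[key]] <- sc$ssim
      if (is.finite(sc$ssim) && sc$ssim > best$ssim)
        best <- list(ssim = sc$ssim, transform = T, warped = sc$warped)
    }
    trace <- c(trace, best$ssim)
    if (!is.finite(best$ssim))
      stopf("coarse registration failed: no threshold node yielded a transform")
    ## stopping rule on the relative gain of the best SSIM
    if (is.finite(prev_best) && prev_best > 0 &&
        (best$ssim - prev_best) / prev_best <= e1) break
    prev_best <- best$ssim
    if (round == max_rounds) break
    ## updating rule: index span of the top-4 nodes (ties -> smaller index)
    ord <- order(-as.vector(node_ssim),
                 rep(seq_along(c_nodes), times = length(d_nodes)),
                 rep(seq_along(d_nodes), each = length(c_nodes)))
    ord <- ord[is.finite(as.vector(node_ssim))[ord]]
    top <- head(ord, 4)
    ti <- (top - 1) %% length(c_nodes) + 1
    tj <- (top - 1) %/% length(c_nodes) + 1
    c_lo <- c_nodes[min(ti)]; c_hi <- c_nodes[max(ti)]
    d_lo <- d_nodes[min(tj)]; d_hi <- d_nodes[max(tj)]
    c_nodes <- if (c_hi > c_lo) seq(c_lo, c_hi, length.out = grid_i) else c_lo
    d_nodes <- if (d_hi > d_lo) seq(d_lo, d_hi, length.out = grid_j) else d_lo
  }
  list(transform = best$transform, warped = best$warped, ssim = best$ssim,
       ssim_trace = trace, n_matches = nrow(matches))
}
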