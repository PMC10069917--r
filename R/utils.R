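#' @keywords internal
"_PACKAGE"

#' @importFrom stats predict rnorm runif sd var coef quantile
#' @importFrom utils head read.csv write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_num_scalar <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Clamp values to a range
#' @param x numeric vector
#' @param lo,hi range limits
#' @return clamped vector
#' @keywords internal
clampv <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## ---- image sampling -------------------------------------------------------
## Images are H x W matrices; pixel (row r, col c) (1-based R indexing) has
## continuous coordinates x = c - 1, y = r - 1 (0-based, pixel centre at the
## integer). All sampling functions take 0-based (x, y).

## Keys cubic convolution kernel, a = -0.5 (the common "bicubic" kernel).
cubic_weights <- function(t) {
  ## t in [0,1): weights for samples at offsets -1, 0, 1, 2
  a <- -0.5
  w0 <- a * ((t + 1)^3) - 5 * a * ((t + 1)^2) + 8 * a * (t + 1) - 4 * a
  w1 <- (a + 2) * t^3 - (a + 3) * t^2 + 1
  t2 <- 1 - t
  w2 <- (a + 2) * t2^3 - (a + 3) * t2^2 + 1
  t3 <- 2 - t
  w3 <- a * t3^3 - 5 * a * t3^2 + 8 * a * t3 - 4 * a
  list(w0, w1, w2, w3)
}

#' Sample an image at arbitrary positions with bicubic interpolation
#'
#' Positions are 0-based pixel coordinates (x = column, y = row). Samples
#' falling outside the image return `fill`.
#'
#' @param img H x W numeric matrix
#' @param x,y numeric vectors of equal length, 0-based coordinates
#' @param fill value for out-of-frame samples (default 0)
#' @return numeric vector of sampled values
#' @export
sample_bicubic <- function(img, x, y, fill = 0) {
  h <- nrow(img); w <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  tx <- x - x0; ty <- y - y0
  inside <- x >= 0 & x <= (w - 1) & y >= 0 & y <= (h - 1)
  wx <- cubic_weights(tx); wy <- cubic_weights(ty)
  ## gather 4x4 neighbourhood with edge clamping
  out <- numeric(length(x))
  for (j in 0:3) {
    cj <- clampv(x0 + (j - 1), 0, w - 1)
    rowacc <- numeric(length(x))
    for (i in 0:3) {
      ri <- clampv(y0 + (i - 1), 0, h - 1)
      v <- img[cbind(ri + 1, cj + 1)]
      rowacc <- rowacc + wy[[i + 1]] * v
    }
    out <- out + wx[[j + 1]] * rowacc
  }
  out[!inside] <- fill
  out
}

#' Sample an image at arbitrary positions with bilinear interpolation
#' @inheritParams sample_bicubic
#' @return numeric vector of sampled values
#' @export
sample_bilinear <- function(img, x, y, fill = 0) {
  h <- nrow(img); w <- ncol(img)
  inside <- x >= 0 & x <= (w - 1) & y >= 0 & y <= (h - 1)
  x0 <- clampv(floor(x), 0, w - 1); y0 <- clampv(floor(y), 0, h - 1)
  x1 <- pmin(x0 + 1, w - 1); y1 <- pmin(y0 + 1, h - 1)
  tx <- clampv(x - x0, 0, 1); ty <- clampv(y - y0, 0, 1)
  v00 <- img[cbind(y0 + 1, x0 + 1)]; v01 <- img[cbind(y0 + 1, x1 + 1)]
  v10 <- img[cbind(y1 + 1, x0 + 1)]; v11 <- img[cbind(y1 + 1, x1 + 1)]
  out <- (1 - ty) * ((1 - tx) * v00 + tx * v01) + ty * ((1 - tx) * v10 + tx * v11)
  out[!inside] <- fill
  out
}

## ---- separable convolution ------------------------------------------------

## 1D correlation along matrix rows/cols with replicate padding, kernel k
## (odd length, centred).
conv_sep_replicate <- function(img, k) {
  r <- (length(k) - 1L) / 2L
  h <- nrow(img); w <- ncol(img)
  ## pad columns (x direction)
  idx <- clampv(seq_len(w + 2 * r) - r, 1, w)
  tmp <- img[, idx, drop = FALSE]
  out <- matrix(0, h, w)
  for (i in seq_along(k)) out <- out + k[i] * tmp[, i:(i + w - 1), drop = FALSE]
  idy <- clampv(seq_len(h + 2 * r) - r, 1, h)
  tmp <- out[idy, , drop = FALSE]
  out2 <- matrix(0, h, w)
  for (i in seq_along(k)) out2 <- out2 + k[i] * tmp[i:(i + h - 1), , drop = FALSE]
  out2
}

## "valid" 2D correlation with a separable kernel kx (cols) x ky (rows):
## output (h-|ky|+1) x (w-|kx|+1).
conv_sep_valid <- function(img, ky, kx) {
  h <- nrow(img); w <- ncol(img)
  nh <- h - length(ky) + 1L; nw <- w - length(kx) + 1L
  out <- matrix(0, nh, w)
  for (i in seq_along(ky)) out <- out + ky[i] * img[i:(i + nh - 1), , drop = FALSE]
  out2 <- matrix(0, nh, nw)
  for (i in seq_along(kx)) out2 <- out2 + kx[i] * out[, i:(i + nw - 1), drop = FALSE]
  out2
}

gaussian_kernel_1d <- function(sigma, radius = ceiling(3 * sigma)) {
  x <- (-radius):radius
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

#' Smooth a matrix with a Gaussian filter (replicate border)
#' @param img numeric matrix
#' @param sigma standard deviation in pixels
#' @return smoothed matrix of the same size
#' @export
gaussian_smooth <- function(img, sigma) {
  if (sigma <= 0) return(img)
  conv_sep_replicate(img, gaussian_kernel_1d(sigma))
}

## ---- integral image -------------------------------------------------------

## S has an extra leading row/col of zeros so that the sum of img over rows
## r1..r2, cols c1..c2 (1-based, inclusive) is
## S[r2+1,c2+1] - S[r1,c2+1] - S[r2+1,c1] + S[r1,c1].
integral_image <- function(img) {
  S <- matrix(0, nrow(img) + 1L, ncol(img) + 1L)
  S[-1, -1] <- t(apply(apply(img, 2, cumsum), 1, cumsum))
  S
}

## Vectorized box sum over the integral image. r1,r2,c1,c2 are 1-based
## inclusive row/col bounds (vectors); bounds are clamped to the image.
box_sum <- function(S, r1, r2, c1, c2) {
  h <- nrow(S) - 1L; w <- ncol(S) - 1L
  r1 <- clampv(r1, 1, h + 1); r2 <- clampv(r2, 0, h)
  c1 <- clampv(c1, 1, w + 1); c2 <- clampv(c2, 0, w)
  S[cbind(r2 + 1, c2 + 1)] - S[cbind(r1, c2 + 1)] -
    S[cbind(r2 + 1, c1)] + S[cbind(r1, c1)]
}

## normalize rows of a matrix to unit L2 norm (zero rows left as zero)
normalize_rows <- function(m) {
  n <- sqrt(rowSums(m^2))
  n[n == 0] <- 1
  m / n
}

vec_norm <- function(v) sqrt(sum(v^2))
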