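#' Structural similarity index (SSIM) between two images
#'
#' Windowed SSIM in the standard formulation: an 11 x 11 Gaussian window
#' (sigma 1.5) slides over both images; per-window luminance/contrast/
#' structure terms are combined and averaged. Stabilizing constants are
#' C1 = (k1 L)^2 and C2 = (k2 L)^2 with L the dynamic range.
#'
#' @param a,b numeric matrices of identical dimensions
#' @param window window side (odd)
#' @param sigma Gaussian window standard deviation (px)
#' @param k1,k2 stabilizing constants (defaults 0.01 and 0.03)
#' @param dynamic_range value range L of the inputs (1 for unit-scaled)
#' @param mask optional logical matrix; when given, the mean is taken over
#'   windows whose centre pixel is TRUE (e.g. the union of two foreground
#'   masks, so empty background does not inflate similarity)
#' @return scalar mean SSIM in `[-1, 1]`
#' @export
compute_ssim <- function(a, b, window = 11L, sigma = 1.5, k1 = 0.01,
                         k2 = 0.03, dynamic_range = 1, mask = NULL) {
  if (!all(dim(a) == dim(b))) stopf("SSIM inputs must share dimensions")
  if (min(dim(a)) < window) stopf("image smaller than the SSIM window")
  ssim_map <- ssim_local_map(a, b, window, sigma, k1, k2, dynamic_range)
  if (is.null(mask)) return(mean(ssim_map))
  if (!all(dim(mask) == dim(a))) stopf("mask dimensions must match images")
  r <- (window - 1L) / 2L
  h <- nrow(a); w <- ncol(a)
  core <- mask[(r + 1):(h - r), (r + 1):(w - r), drop = FALSE]
  if (!any(core)) return(mean(ssim_map))
  mean(ssim_map[core])
}

## Valid-window local SSIM map ((H-w+1) x (W-w+1)).
ssim_local_map <- function(a, b, window, sigma, k1, k2, L) {
  g <- gaussian_kernel_1d(sigma, radius = (window - 1L) / 2L)
  C1 <- (k1 * L)^2; C2 <- (k2 * L)^2
  mu_a <- conv_sep_valid(a, g, g)
  mu_b <- conv_sep_valid(b, g, g)
  saa <- conv_sep_valid(a * a, g, g) - mu_a^2
  sbb <- conv_sep_valid(b * b, g, g) - mu_b^2
  sab <- conv_sep_valid(a * b, g, g) - mu_a * mu_b
  ((2 * mu_a * mu_b + C1) * (2 * sab + C2)) /
    ((mu_a^2 + mu_b^2 + C1) * (saa + sbb + C2))
}

ssim_from_config <- function(a, b, cfg, mask = NULL) {
  s <- cfg$ssim
  if (!isTRUE(s$on_foreground)) mask <- NULL
  compute_ssim(a, b, window = s$window, sigma = s$sigma, k1 = s$k1,
               k2 = s$k2, dynamic_range = s$dynamic_range, mask = mask)
}

#' Mean per-viewpoint RMSE of reflectance spectra against ground truth
#'
#' For N viewpoint curves over M bands, computes the band-wise RMSE of each
#' curve against the ground-truth spectrum and averages over viewpoints:
#' (1/N) * sum_v sqrt((1/M) * sum_b (s_vb - s_gt_b)^2).
#'
#' @param curves N x M matrix of reflectance curves (one row per viewpoint)
#' @param truth length-M ground-truth spectrum
#' @return scalar RMSE
#' @export
spectra_rmse <- function(curves, truth) {
  curves <- as.matrix(curves)
  if (is.null(truth)) stopf("ground-truth spectrum is required")
  if (length(truth) != ncol(curves)) stopf("truth length != band count")
  mean(sqrt(rowMeans(sweep(curves, 2, truth)^2)))
}

#' Range of pairwise distances between multiview reflectance curves
#'
#' For every pair of viewpoints (m, n), the band-normalized Euclidean
#' distance d_mn = sqrt((1/M) * sum_b (s_mb - s_nb)^2) is computed; the
#' result is max - min over distinct pairs (the spread of the multiview
#' spectra), or the plain maximum with `mode = "max"`.
#'
#' @param curves N x M matrix, N >= 2
#' @param mode "range" (max - min) or "max"
#' @return scalar distance range
#' @export
spectra_range <- function(curves, mode = c("range", "max")) {
  mode <- match.arg(mode)
  curves <- as.matrix(curves)
  n <- nrow(curves)
  if (n < 2) stopf("at least 2 viewpoint curves are required")
  M <- ncol(curves)
  d2 <- as.matrix(stats::dist(curves))^2 / M
  d <- sqrt(d2[upper.tri(d2)])
  if (mode == "max") max(d) else max(d) - min(d)
}

#' Coefficient of determination and RMSE of predictions
#'
#' @param predicted,observed numeric vectors of equal length (>= 2)
#' @return named list with `r2` and `rmse`
#' @export
regression_metrics <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(observed) < 2)
    stopf("predicted/observed must have equal length >= 2")
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) stopf("observed values have zero variance; R2 undefined")
  ss_res <- sum((observed - predicted)^2)
  list(r2 = 1 - ss_res / ss_tot,
       rmse = sqrt(mean((observed - predicted)^2)))
}
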