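## Fine registration: Thirion-style Demons refinement of the coarse result,
## with the same relative-SSIM stopping rule, plus single-resampling
## application of the composed coarse + fine warp to all bands.

#' One Demons displacement increment
#'
#' Per pixel, with s the fixed image, m_warped the moving image under the
#' current displacement, and grad the spatial gradient of m_warped:
#' u = (s - m_warped) * grad / (|grad|^2 + alpha^2 (s - m_warped)^2).
#' Pixels whose denominator falls below `eps_den` get u = 0.
#'
#' @param s fixed image
#' @param m_warped moving image warped by the current displacement
#' @param grad list with `gx`, `gy` (gradient of `m_warped`)
#' @param alpha normalization weight (> 0)
#' @param eps_den denominator guard
#' @return list with `ux`, `uy` increments (px)
#' @export
demons_step <- function(s, m_warped, grad, alpha = 1.0, eps_den = 1e-9) {
  if (alpha <= 0) stopf("alpha must be > 0")
  diff <- s - m_warped
  den <- grad$gx^2 + grad$gy^2 + alpha^2 * diff^2
  f <- diff / den
  f[den < eps_den] <- 0
  list(ux = f * grad$gx, uy = f * grad$gy)
}

central_gradient <- function(img) {
  h <- nrow(img); w <- ncol(img)
  gx <- (img[, c(2:w, w), drop = FALSE] - img[, c(1, 1:(w - 1)), drop = FALSE]) / 2
  gy <- (img[c(2:h, h), , drop = FALSE] - img[c(1, 1:(h - 1)), , drop = FALSE]) / 2
  list(gx = gx, gy = gy)
}

#' Nonrigid Demons registration
#'
#' Iterates: warp the moving image by the current displacement (bicubic),
#' compute the Demons increment from the intensity mismatch and the warped
#' moving image's gradient, add it to the field and smooth the field with a
#' Gaussian of `sigma_d` px. Iterations stop when the relative gain of the
#' best-ever SSIM drops to `e2` or at `max_iters`; the field with the best
#' SSIM is returned. A collapse of SSIM to less than half its starting
#' value aborts with a diagnostic.
#'
#' @param fixed fixed image
#' @param moving moving image, already coarse-registered onto the fixed grid
#' @param alpha Demons normalization (default 1)
#' @param sigma_d field smoothing sigma per iteration (px)
#' @param e2 relative SSIM gain stopping threshold
#' @param max_iters iteration cap
#' @param cfg configuration (SSIM block and Demons guards)
#' @return list: `field` (H x W x 2), `warped`, `ssim`, `ssim_trace`
#' @export
demons_register <- function(fixed, moving, alpha = 1.0, sigma_d = 1.0,
                            e2 = 0.001, max_iters = 100L,
                            cfg = default_config()) {
  if (!all(dim(fixed) == dim(moving))) stopf("fixed/moving dimensions differ")
  h <- nrow(fixed); w <- ncol(fixed)
  tx <- matrix(0, h, w); ty <- matrix(0, h, w)
  mask_u <- NULL
  if (isTRUE(cfg$ssim$on_foreground)) mask_u <- (fixed > 0) | (moving > 0)
  score <- function(img) ssim_from_config(fixed, img, cfg, mask = mask_u)
  ssim0 <- score(moving)
  best <- list(ssim = ssim0, tx = tx, ty = ty, warped = moving)
  trace <- ssim0
  prev_best <- ssim0
  for (it in seq_len(max_iters)) {
    warped <- warp_image(moving, array(c(tx, ty), c(h, w, 2)))
    grad <- central_gradient(warped)
    u <- demons_step(fixed, warped, grad, alpha, cfg$demons$eps_den)
    tx <- gaussian_smooth(tx + u$ux, sigma_d)
    ty <- gaussian_smooth(ty + u$uy, sigma_d)
    warped2 <- warp_image(moving, array(c(tx, ty), c(h, w, 2)))
    s <- score(warped2)
    trace <- c(trace, max(s, best$ssim))
    if (s > best$ssim) best <- list(ssim = s, tx = tx, ty = ty, warped = warped2)
    if (s < 0.5 * ssim0 && ssim0 > 0)
      stopf("Demons diverged: SSIM fell from %.3f to %.3f at iteration %d",
            ssim0, s, it)
    if (prev_best > 0 && (best$ssim - prev_best) / prev_best <= e2) break
    prev_best <- best$ssim
  }
  list(field = array(c(best$tx, best$ty), c(h, w, 2)),
       warped = best$warped, ssim = best$ssim, ssim_trace = trace)
}

#' Apply the composed coarse + fine registration to a multispectral stack
#'
#' Every band is resampled once through the composed coordinate map
#' x -> T^-1(x + t(x)) (planar transform after the displacement field), so
#' interpolation blur is not compounded across the two stages. Output bands
#' live on the fixed image's grid.
#'
#' @param ms a [ms_stack] (original moving-geometry bands)
#' @param transform 3 x 3 planar transform (moving -> fixed)
#' @param field H x W x 2 Demons displacement on the fixed grid (or NULL)
#' @return [ms_stack] with all bands registered onto the fixed grid
#' @export
apply_full_registration <- function(ms, transform, field = NULL) {
  dn <- if (inherits(ms, "ms_stack")) ms$dn else ms
  if (is.null(field)) stopf("a displacement field (possibly zero) is required")
  h <- dim(field)[1]; w <- dim(field)[2]
  xs <- rep(0:(w - 1), each = h) + as.vector(field[, , 1])
  ys <- rep(0:(h - 1), w) + as.vector(field[, , 2])
  Ti <- solve(transform)
  p <- apply_planar(Ti, xs, ys)
  B <- dim(dn)[3]
  out <- array(0, c(h, w, B))
  for (b in seq_len(B))
    out[, , b] <- matrix(sample_bicubic(dn[, , b], p$x, p$y), h, w)
  if (inherits(ms, "ms_stack")) ms_stack(pmax(out, 0), ms$wavelengths) else out
}
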