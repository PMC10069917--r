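## Multi-page float32 TIFF writing. tiff::writeTIFF clamps data to [0, 1]
## (display convention), which cannot hold digital numbers, displacement
## fields or NaN-masked reflectance, so pages are emitted directly:
## little-endian, uncompressed, one strip per page, SampleFormat = IEEE
## float. tiff::readTIFF reads these (and arbitrary other) float TIFFs.

## 4-byte unsigned little-endian from a double
u32le <- function(x) {
  as.raw(c(x %% 256, floor(x / 256) %% 256,
           floor(x / 65536) %% 256, floor(x / 16777216) %% 256))
}
u16le <- function(x) as.raw(c(x %% 256, floor(x / 256) %% 256))

tiff_entry <- function(tag, type, count, value) {
  ## type 3 = SHORT, 4 = LONG; value fits in 4 bytes for all our tags
  val <- if (type == 3) c(u16le(value), as.raw(c(0, 0))) else u32le(value)
  c(u16le(tag), u16le(type), u32le(count), val)
}

#' Write a stack of float matrices as a multi-page 32-bit float TIFF
#'
#' @param pages list of H x W numeric matrices (NaN allowed), or an
#'   H x W x B array
#' @param path output path
#' @return `path`, invisibly
#' @export
write_float_tiff <- function(pages, path) {
  if (is.array(pages) && length(dim(pages)) == 3)
    pages <- lapply(seq_len(dim(pages)[3]), function(b) pages[, , b])
  if (is.matrix(pages)) pages <- list(pages)
  np <- length(pages)
  con <- file(path, "wb")
  ok <- FALSE
  on.exit({ close(con); if (!ok) unlink(path) })
  writeBin(c(charToRaw("II"), u16le(42)), con)
  ## offset bookkeeping: header(8) then per page [strip][IFD]
  offset <- 8
  ifd_offsets <- numeric(np)
  chunks <- vector("list", np)
  for (p in seq_len(np)) {
    m <- pages[[p]]
    h <- nrow(m); w <- ncol(m)
    strip <- writeBin(as.numeric(t(m)), raw(), size = 4, endian = "little")
    strip_off <- offset
    ifd_off <- strip_off + length(strip)
    entries <- list(
      tiff_entry(256, 4, 1, w),            # ImageWidth
      tiff_entry(257, 4, 1, h),            # ImageLength
      tiff_entry(258, 3, 1, 32),           # BitsPerSample
      tiff_entry(259, 3, 1, 1),            # Compression: none
      tiff_entry(262, 3, 1, 1),            # Photometric: BlackIsZero
      tiff_entry(273, 4, 1, strip_off),    # StripOffsets
      tiff_entry(277, 3, 1, 1),            # SamplesPerPixel
      tiff_entry(278, 4, 1, h),            # RowsPerStrip
      tiff_entry(279, 4, 1, length(strip)),# StripByteCounts
      tiff_entry(339, 3, 1, 3)             # SampleFormat: IEEE float
    )
    ifd <- c(u16le(length(entries)), do.call(c, entries))
    ifd_len <- length(ifd) + 4   # + next-IFD pointer
    chunks[[p]] <- list(strip = strip, ifd = ifd)
    ifd_offsets[p] <- ifd_off
    offset <- ifd_off + ifd_len
  }
  writeBin(u32le(ifd_offsets[1]), con)
  for (p in seq_len(np)) {
    writeBin(chunks[[p]]$strip, con)
    nxt <- if (p < np) ifd_offsets[p + 1] else 0
    writeBin(c(chunks[[p]]$ifd, u32le(nxt)), con)
  }
  ok <- TRUE
  invisible(path)
}

#' Read a multi-page TIFF into an H x W x B array
#'
#' @param path TIFF path
#' @return H x W x B numeric array
#' @export
read_tiff_stack <- function(path) {
  if (!file.exists(path)) stopf("TIFF not found: %s", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3) p[, , 1] else p)
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stopf("TIFF pages have inconsistent dimensions")
  array(unlist(pages), dim = c(dims[1, 1], dims[2, 1], length(pages)))
}

#' Read a paired depth / RGB / multispectral frame from disk
#'
#' @param depth_path 16-bit depth PNG (millimetres, 0 invalid)
#' @param rgb_path RGB PNG, pixel-registered with the depth image
#' @param ms_path multi-page TIFF of digital numbers, pages in ascending
#'   wavelength order
#' @param wavelengths band centres (nm), one per TIFF page
#' @param view_id label for the view
#' @return a [frame_pair]
#' @export
read_frame_pair <- function(depth_path, rgb_path, ms_path, wavelengths,
                            view_id = "view") {
  depth <- read_depth_png(depth_path)
  if (!file.exists(rgb_path)) stopf("RGB file not found: %s", rgb_path)
  rgb <- png::readPNG(rgb_path)
  if (length(dim(rgb)) == 2) rgb <- array(rgb, c(dim(rgb), 3))
  if (dim(rgb)[3] > 3) rgb <- rgb[, , 1:3]
  dn <- read_tiff_stack(ms_path)
  if (dim(dn)[3] != length(wavelengths))
    stopf("TIFF has %d pages but %d wavelengths were given",
          dim(dn)[3], length(wavelengths))
  frame_pair(rgb, depth, ms_stack(dn, wavelengths), view_id)
}

#' Write a reflectance cube with its mask as a float TIFF
#'
#' Masked pixels are stored as NaN on every page; the round trip through
#' [read_reflectance_cube()] is lossless up to float32 precision.
#'
#' @param cube H x W x B reflectance array
#' @param path output path
#' @param mask optional H x W logical matrix (TRUE = keep); masked-out
#'   pixels are stored as NaN
#' @return `path`, invisibly
#' @export
write_reflectance_cube <- function(cube, path, mask = NULL) {
  if (length(dim(cube)) != 3) stopf("cube must be H x W x B")
  if (!is.null(mask)) {
    cube[array(!mask, dim(cube))] <- NaN
  }
  write_float_tiff(cube, path)
}

#' Read a reflectance cube written by [write_reflectance_cube()]
#'
#' @param path TIFF path
#' @return list with `reflectance` (H x W x B, NaN = masked) and `mask`
#'   (H x W logical, TRUE where all bands are finite)
#' @export
read_reflectance_cube <- function(path) {
  cube <- read_tiff_stack(path)
  mask <- apply(is.finite(cube), c(1, 2), all)
  list(reflectance = cube, mask = mask)
}
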