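## 16-bit grayscale PNG writing. png::writePNG only emits 8-bit channels, so
## depth images (millimetres as uint16, 0 = invalid) are written by a minimal
## PNG encoder: zlib stream obtained from memCompress (gzip wrapper converted
## to a zlib wrapper), CRC32 table-driven, Adler-32 computed blockwise.
## Reading goes through png::readPNG, which handles 16-bit natively.

## 32-bit XOR on nonnegative doubles (values < 2^32); R integers are signed.
bitwXor_dbl <- function(a, b) {
  hi_a <- floor(a / 65536); lo_a <- a - hi_a * 65536
  hi_b <- floor(b / 65536); lo_b <- b - hi_b * 65536
  as.numeric(bitwXor(as.integer(hi_a), as.integer(hi_b))) * 65536 +
    as.numeric(bitwXor(as.integer(lo_a), as.integer(lo_b)))
}

## CRC-32 lookup table built on doubles.
.crc_table <- local({
  tab <- numeric(256)
  for (n in 0:255) {
    c <- n
    for (k in 1:8) {
      c <- if (c %% 2 == 1) bitwXor_dbl(3988292384, floor(c / 2)) else floor(c / 2)
    }
    tab[n + 1] <- c
  }
  tab
})

crc32_bytes <- function(bytes) {
  crc <- 4294967295  # 0xFFFFFFFF
  v <- as.integer(bytes)
  tab <- .crc_table
  for (b in v) {
    crc <- bitwXor_dbl(tab[(bitwXor_dbl(crc, b) %% 256) + 1], floor(crc / 256))
  }
  bitwXor_dbl(crc, 4294967295)
}

## Adler-32 (zlib checksum of the uncompressed stream), blockwise so the
## partial sums stay well inside double precision.
adler32_bytes <- function(bytes) {
  MOD <- 65521
  v <- as.numeric(as.integer(bytes))
  a <- 1; b <- 0
  n <- length(v); i <- 1
  while (i <= n) {
    j <- min(i + 4095, n)
    blk <- v[i:j]; L <- length(blk)
    b <- (b + L * a + sum((L - seq_len(L) + 1) * blk)) %% MOD
    a <- (a + sum(blk)) %% MOD
    i <- j + 1
  }
  b * 65536 + a
}

uint32_be <- function(x) {
  as.raw(c(floor(x / 16777216) %% 256, floor(x / 65536) %% 256,
           floor(x / 256) %% 256, x %% 256))
}

png_chunk <- function(type, data) {
  payload <- c(charToRaw(type), data)
  c(uint32_be(length(data)), payload, uint32_be(crc32_bytes(payload)))
}

## memCompress(type = "gzip") emits an RFC 1950 zlib stream (0x78 header,
## Adler-32 trailer), which is exactly what PNG IDAT requires. The Adler-32
## fallback covers any build that emits a bare gzip wrapper instead.
zlib_stream <- function(raw_bytes) {
  gz <- memCompress(raw_bytes, type = "gzip")
  if (gz[1] == as.raw(0x78)) return(gz)
  if (gz[1] == as.raw(0x1f) && gz[2] == as.raw(0x8b)) {
    deflate <- gz[11:(length(gz) - 8)]
    return(c(as.raw(c(0x78, 0x9c)), deflate, uint32_be(adler32_bytes(raw_bytes))))
  }
  stopf("unrecognized memCompress output")
}

#' Write a depth image as a 16-bit grayscale PNG (millimetres)
#'
#' Depth in metres is scaled to millimetres and stored as unsigned 16-bit;
#' invalid pixels (NA) are stored as 0, the conventional depth-camera
#' invalid sentinel.
#'
#' @param depth a [depth_image] or H x W matrix of metres (NA = invalid)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_depth_png <- function(depth, path) {
  v <- if (inherits(depth, "depth_image")) depth$values else depth
  mm <- round(v * 1000)
  mm[is.na(mm)] <- 0
  if (any(mm < 0 | mm > 65535)) stopf("depth out of uint16 millimetre range")
  h <- nrow(mm); w <- ncol(mm)
  ## scanlines: filter byte 0 + big-endian uint16 per pixel
  m <- t(mm)  # column-major t(mm): pixel order row by row
  hi <- as.raw(floor(m / 256)); lo <- as.raw(m %% 256)
  px <- as.vector(rbind(hi, lo))           # interleave hi/lo per pixel
  rows <- matrix(px, nrow = 2 * w)         # one column per scanline
  scan <- as.vector(rbind(as.raw(0), rows))
  ihdr <- c(uint32_be(w), uint32_be(h), as.raw(c(16, 0, 0, 0, 0)))
  idat <- zlib_stream(scan)
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)), con)
  writeBin(png_chunk("IHDR", ihdr), con)
  writeBin(png_chunk("IDAT", idat), con)
  writeBin(png_chunk("IEND", raw(0)), con)
  invisible(path)
}

#' Read a 16-bit depth PNG into a depth image (metres)
#'
#' @param path PNG path (single-channel 16-bit, millimetres, 0 = invalid)
#' @return a [depth_image] in metres with NA for invalid pixels
#' @export
read_depth_png <- function(path) {
  if (!file.exists(path)) stopf("depth file not found: %s", path)
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) stopf("depth PNG must be single-channel")
  mm <- round(img * 65535)
  m <- mm / 1000
  m[mm == 0] <- NA_real_
  depth_image(m)
}
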