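## PLY serialization of multispectral point clouds: per-vertex float
## properties x, y, z plus one refl_<wavelength> property per band (rounded
## integer nanometres, e.g. refl_740). Both ascii and binary_little_endian
## are supported and round-trip through read_multispectral_ply.

ply_property_names <- function(wavelengths)
  c("x", "y", "z", sprintf("refl_%d", round(wavelengths)))

#' Write a multispectral point cloud to PLY
#'
#' @param cloud a [ms_point_cloud]
#' @param path output path
#' @param mode "binary" (binary_little_endian, bit-exact float32 round trip)
#'   or "ascii"
#' @return `path`, invisibly
#' @export
write_multispectral_ply <- function(cloud, path, mode = c("binary", "ascii")) {
  mode <- match.arg(mode)
  stopifnot(inherits(cloud, "ms_point_cloud"))
  m <- cbind(cloud$points, cloud$reflectance)
  props <- ply_property_names(cloud$wavelengths)
  hdr <- c(
    "ply",
    sprintf("format %s 1.0",
            if (mode == "binary") "binary_little_endian" else "ascii"),
    "comment multispectral point cloud",
    sprintf("comment wavelengths_nm %s",
            paste(format(cloud$wavelengths, trim = TRUE), collapse = " ")),
    sprintf("element vertex %d", nrow(m)),
    sprintf("property float %s", props),
    "end_header"
  )
  con <- file(path, "wb"); on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  if (mode == "binary") {
    writeBin(as.numeric(t(m)), con, size = 4, endian = "little")
  } else {
    txt <- apply(m, 1, function(r) paste(formatC(r, format = "g", digits = 9),
                                         collapse = " "))
    writeLines(txt, con, sep = "\n")
  }
  invisible(path)
}

#' Read a PLY file written by [write_multispectral_ply()]
#'
#' @param path PLY path
#' @return a [ms_point_cloud]
#' @export
read_multispectral_ply <- function(path) {
  if (!file.exists(path)) stopf("PLY not found: %s", path)
  con <- file(path, "rb"); on.exit(close(con))
  ## read the header one byte at a time: readLines would buffer past
  ## end_header and swallow the binary payload
  read_line_raw <- function() {
    bytes <- raw(0)
    repeat {
      b <- readBin(con, "raw", 1)
      if (!length(b)) stopf("unterminated PLY header")
      if (b == as.raw(10L)) break
      bytes <- c(bytes, b)
    }
    rawToChar(bytes)
  }
  hdr <- character(0)
  repeat {
    line <- read_line_raw()
    hdr <- c(hdr, line)
    if (line == "end_header") break
  }
  fmt <- sub("^format (\\S+).*", "\\1", grep("^format", hdr, value = TRUE))
  nv <- as.integer(sub("^element vertex (\\d+).*", "\\1",
                       grep("^element vertex", hdr, value = TRUE)))
  props <- sub("^property float ", "", grep("^property float", hdr, value = TRUE))
  wl_line <- grep("^comment wavelengths_nm", hdr, value = TRUE)
  wl <- if (length(wl_line)) {
    as.numeric(strsplit(sub("^comment wavelengths_nm ", "", wl_line), " ")[[1]])
  } else {
    as.numeric(sub("refl_", "", grep("^refl_", props, value = TRUE)))
  }
  np <- length(props)
  if (fmt == "binary_little_endian") {
    vals <- readBin(con, numeric(), n = nv * np, size = 4, endian = "little")
    m <- matrix(vals, ncol = np, byrow = TRUE)
  } else {
    txt <- readLines(con, n = nv)
    m <- do.call(rbind, lapply(strsplit(txt, "\\s+"), as.numeric))
  }
  colnames(m) <- props
  ms_point_cloud(m[, 1:3, drop = FALSE], m[, -(1:3), drop = FALSE], wl)
}
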