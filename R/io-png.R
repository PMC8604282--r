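#' Raster file I/O
#'
#' Depth rasters are stored as 16-bit single-channel greyscale PNG in
#' millimetre units (invalid pixels = 0); colour images as ordinary 8-bit
#' 3-channel PNG. Reading goes through [png::readPNG()]. The installed png
#' library writes 8-bit only, so the 16-bit greyscale encoder (PNG chunk
#' framing around a zlib stream) lives here; round-trips are verified against
#' `png::readPNG` in the test suite.
#'
#' @name rgbd_io
NULL

# -- minimal 16-bit greyscale PNG encoder ------------------------------------

.crc32_table <- local({
  poly <- -306674912L # 0xEDB88320 as signed 32-bit
  vapply(0:255, function(n) {
    c <- as.integer(n)
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L) bitwXor(poly, bitwShiftR(c, 1L)) else bitwShiftR(c, 1L)
    }
    c
  }, integer(1))
})

crc32 <- function(bytes) {
  c <- -1L # 0xFFFFFFFF
  ints <- as.integer(bytes)
  for (b in ints) {
    c <- bitwXor(bitwShiftR(c, 8L), .crc32_table[bitwAnd(bitwXor(c, b), 255L) + 1L])
  }
  bitwXor(c, -1L)
}

int_to_be4 <- function(x) {
  x <- as.numeric(x) %% 2^32
  as.raw(c(x %/% 2^24, (x %/% 2^16) %% 256, (x %/% 256) %% 256, x %% 256))
}

png_chunk <- function(type, data) {
  payload <- c(charToRaw(type), data)
  crc <- crc32(payload) %% 2^32 # to unsigned via numeric
  c(int_to_be4(length(data)), payload, int_to_be4(crc))
}

#' Write a depth raster as 16-bit greyscale PNG
#'
#' @param depth a [depth_raster()] (values in mm, must fit in 0..65535).
#' @param path output file path.
#' @export
write_depth_png <- function(depth, path) {
  stopifnot(inherits(depth, "depth_raster"))
  v <- round(depth$values)
  if (any(v > 65535)) stop("write_depth_png(): depth exceeds 65535 mm, not storable in 16 bits")
  h <- nrow(v); w <- ncol(v)
  # scanlines: filter byte 0, then big-endian uint16 per pixel, row-major
  vt <- t(v)                                   # rows of the image contiguous
  hi <- as.raw(vt %/% 256); lo <- as.raw(vt %% 256)
  pix <- as.raw(rbind(hi, lo))                 # interleave high/low bytes
  dim(pix) <- NULL
  rows <- matrix(pix, nrow = 2 * w)
  scan <- as.raw(rbind(as.raw(0), rows))
  dim(scan) <- NULL
  ihdr <- c(int_to_be4(w), int_to_be4(h),
            as.raw(c(16, 0, 0, 0, 0)))         # 16-bit, greyscale
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", memCompress(scan, type = "gzip")),
           png_chunk("IEND", raw(0)))
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(out, con)
  invisible(path)
}

#' Read a depth PNG into a [depth_raster()]
#'
#' @param path file path to a single-channel depth PNG.
#' @export
read_depth_png <- function(path) {
  if (!file.exists(path)) stop("read_depth_png(): no such file: ", path)
  img <- png::readPNG(path, info = TRUE)
  info <- attr(img, "info")
  if (length(dim(img)) == 3L) stop("read_depth_png(): expected single-channel raster in ", path)
  scale <- 2^info$bit.depth - 1
  v <- round(img * scale)
  attributes(v) <- list(dim = dim(v))
  depth_raster(v)
}

#' Write / read an 8-bit colour image
#'
#' Colour rasters in the package are integer arrays `height x width x 3` with
#' values 0..255.
#'
#' @param rgb integer array `H x W x 3`, values in 0..255.
#' @param path file path (PNG).
#' @export
write_color_png <- function(rgb, path) {
  stopifnot(length(dim(rgb)) == 3L, dim(rgb)[3] == 3L)
  png::writePNG(rgb / 255, path)
  invisible(path)
}

#' @rdname write_color_png
#' @export
read_color_png <- function(path) {
  if (!file.exists(path)) stop("read_color_png(): no such file: ", path)
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]
  arr <- round(img * 255)
  storage.mode(arr) <- "integer"
  arr
}
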