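#' Read a raster image
#'
#' Reads an 8-bit PNG, JPG, TIFF or BMP image into a height x width x
#' channels array on the 0--255 scale (1 channel for gray-scale input,
#' 3 for RGB). Images with an alpha channel and indexed-color BMPs are
#' rejected, as is 16-bit PNG/TIFF input.
#'
#' @param path Image file path; the format is taken from the extension.
#' @return An object of class `eye_image`: a list with `data` (numeric
#'   array, 0--255), `format` (`"png"`, `"jpg"`, `"tiff"` or `"bmp"`) and
#'   `path`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("input image not found: %s", path))
  fmt <- image_format(path)
  a <- switch(fmt,
    png = {
      x <- png::readPNG(path, info = TRUE)
      info <- attr(x, "info")
      if (!is.null(info) && !is.null(info$bit.depth) && info$bit.depth > 8)
        stop("only 8-bit-per-channel PNG input is supported")
      x * 255
    },
    jpg = jpeg::readJPEG(path) * 255,
    tiff = {
      x <- tiff::readTIFF(path, info = TRUE)
      info <- attributes(x)
      if (!is.null(info$bits.per.sample) && any(info$bits.per.sample > 8))
        stop("only 8-bit-per-channel TIFF input is supported")
      x * 255
    },
    bmp = read_bmp(path)
  )
  a <- array(as.vector(a), if (length(dim(a)) == 2L) c(dim(a), 1L) else dim(a))
  nc <- dim(a)[3]
  if (nc %in% c(2L, 4L))
    stop(sprintf("image has an alpha channel (%d channels); %s", nc,
                 "flatten it before processing"))
  if (!nc %in% c(1L, 3L))
    stop(sprintf("unsupported channel count: %d", nc))
  structure(list(data = unname(a), format = fmt, path = path),
            class = "eye_image")
}

#' Write a raster image
#'
#' Writes a 0--255 array (height x width x channels, 1 or 3 channels) as an
#' 8-bit PNG, JPG, TIFF (uncompressed) or BMP (24-bit). JPEG output uses the
#' encoder's default quality and is lossy; a note is emitted.
#'
#' @param img Numeric array or matrix on the 0--255 scale, or an
#'   `eye_image` / `eye_mosaic` object.
#' @param path Output path; the format is taken from the extension unless
#'   `format` is given.
#' @param format Optional explicit format (`"png"`, `"jpg"`, `"tiff"`,
#'   `"bmp"`).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, format = NULL) {
  if (inherits(img, "eye_image")) img <- img$data
  if (inherits(img, "eye_mosaic")) img <- img$image
  if (is.matrix(img)) dim(img) <- c(dim(img), 1L)
  fmt <- if (is.null(format)) image_format(path) else match.arg(
    format, c("png", "jpg", "tiff", "bmp"))
  x <- pmin(pmax(img, 0), 255) / 255
  if (dim(x)[3] == 1L) dim(x) <- dim(x)[1:2]
  ok <- switch(fmt,
    png = png::writePNG(x, path),
    jpg = {
      message("note: JPEG output is lossy (encoder default quality)")
      jpeg::writeJPEG(x, path)
    },
    tiff = tiff::writeTIFF(x, path, bits.per.sample = 8L,
                           compression = "none"),
    bmp = write_bmp(img, path)
  )
  invisible(path)
}

image_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = "png", jpg = "jpg", jpeg = "jpg",
         tif = "tiff", tiff = "tiff", bmp = "bmp",
         stop(sprintf("unsupported image format: '%s' %s", ext,
                      "(supported: png, jpg, tiff, bmp)")))
}

# --- minimal BMP support (no installed package reads/writes BMP) ---------
# Uncompressed Windows BMPs only: 24-bit truecolor is read and written;
# 32-bit (alpha) and palette-based (indexed-color) files are rejected.

read_bmp <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 54 || rawToChar(raw[1:2]) != "BM")
    stop("not a BMP file")
  u32 <- function(off) sum(as.integer(raw[off + 1:4]) * 256^(0:3))
  u16 <- function(off) sum(as.integer(raw[off + 1:2]) * 256^(0:1))
  offbits <- u32(10)
  hdrsz <- u32(14)
  if (hdrsz < 40) stop("unsupported BMP header")
  w <- u32(18)
  hraw <- u32(22)
  topdown <- FALSE
  h <- hraw
  if (hraw > 2^31 - 1) { # negative height: top-down rows
    topdown <- TRUE
    h <- 2^32 - hraw
  }
  bpp <- u16(28)
  compression <- u32(30)
  if (compression != 0) stop("compressed BMP input is not supported")
  if (bpp <= 8)
    stop("indexed-color (palette) BMP images are not accepted")
  if (bpp == 32)
    stop("image has an alpha channel (32-bit BMP); flatten it before processing")
  if (bpp != 24) stop(sprintf("unsupported BMP bit depth: %d", bpp))
  stride <- (w * 3 + 3) %/% 4 * 4
  px <- as.integer(raw[offbits + seq_len(stride * h)])
  a <- array(0, c(h, w, 3))
  for (r in seq_len(h)) {
    row <- px[(r - 1) * stride + seq_len(w * 3)]
    i <- if (topdown) r else h - r + 1
    a[i, , 3] <- row[seq(1, w * 3, 3)] # stored order is B, G, R
    a[i, , 2] <- row[seq(2, w * 3, 3)]
    a[i, , 1] <- row[seq(3, w * 3, 3)]
  }
  a
}

write_bmp <- function(img, path) {
  if (is.matrix(img)) dim(img) <- c(dim(img), 1L)
  h <- dim(img)[1]; w <- dim(img)[2]
  if (dim(img)[3] == 1L) img <- array(img[, , 1], c(h, w, 3))
  v <- as.integer(round(pmin(pmax(img, 0), 255)))
  dim(v) <- c(h, w, 3)
  stride <- (w * 3 + 3) %/% 4 * 4
  datasz <- stride * h
  p32 <- function(x) as.raw(c(x %% 256, x %/% 256 %% 256,
                              x %/% 256^2 %% 256, x %/% 256^3 %% 256))
  p16 <- function(x) as.raw(c(x %% 256, x %/% 256 %% 256))
  hdr <- c(charToRaw("BM"), p32(54 + datasz), p32(0), p32(54),
           p32(40), p32(w), p32(h), p16(1), p16(24), p32(0), p32(datasz),
           p32(2835), p32(2835), p32(0), p32(0))
  body <- raw(datasz)
  for (r in seq_len(h)) {
    i <- h - r + 1 # bottom-up
    row <- integer(w * 3)
    row[seq(1, w * 3, 3)] <- v[i, , 3]
    row[seq(2, w * 3, 3)] <- v[i, , 2]
    row[seq(3, w * 3, 3)] <- v[i, , 1]
    body[(r - 1) * stride + seq_len(w * 3)] <- as.raw(row)
  }
  writeBin(c(hdr, body), path)
  TRUE
}

#' @export
print.eye_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("eye_image: %d x %d px, %d channel(s), %s\n",
              d[2], d[1], d[3], x$format))
  invisible(x)
}
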