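# Shared raster conventions: an RGB image is an integer array h x w x 3 with
# values in [0,255]; a gray image a matrix with the same range; a binary mask
# a matrix holding only 0 and 255. Coordinates are (row, col), 0-based in all
# user-facing corner/rectangle positions, origin at the top-left.

assertRgb <- function(img, what = "img") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop(what, " must be an h x w x 3 array", call. = FALSE)
  if (dim(img)[1] < 1L || dim(img)[2] < 1L)
    stop(what, " must have positive dimensions", call. = FALSE)
  r <- range(img)
  if (is.na(r[1]) || r[1] < 0 || r[2] > 255)
    stop(what, " intensities must lie in [0, 255]", call. = FALSE)
  invisible(TRUE)
}

assertGray <- function(img, what = "img") {
  if (!is.matrix(img) || nrow(img) < 1L || ncol(img) < 1L)
    stop(what, " must be a non-empty matrix", call. = FALSE)
  r <- range(img)
  if (is.na(r[1]) || r[1] < 0 || r[2] > 255)
    stop(what, " intensities must lie in [0, 255]", call. = FALSE)
  invisible(TRUE)
}

assertMask <- function(mask, what = "mask") {
  if (!is.matrix(mask)) stop(what, " must be a matrix", call. = FALSE)
  if (!all(mask %in% c(0, 255)))
    stop(what, " may contain only the values 0 and 255", call. = FALSE)
  invisible(TRUE)
}

clamp255 <- function(x) pmin(pmax(x, 0), 255)

#' HSV image
#'
#' Planar hue/saturation/value representation: hue in degrees [0, 360),
#' saturation as a fraction in [0, 1], value as an integer in [0, 255]. The
#' value channel is kept on the 0-255 lattice so intensity transfers are plain
#' look-up tables.
#'
#' @slot hue,saturation,value numeric matrices of identical dimensions.
#' @export
setClass("HsvImage", representation(
  hue = "matrix", saturation = "matrix", value = "matrix"
))

setValidity("HsvImage", function(object) {
  d <- dim(object@hue)
  if (!identical(d, dim(object@saturation)) || !identical(d, dim(object@value)))
    return("hue, saturation and value must share dimensions")
  if (any(object@hue < 0 | object@hue >= 360)) return("hue must lie in [0, 360)")
  if (any(object@saturation < 0 | object@saturation > 1))
    return("saturation must lie in [0, 1]")
  if (any(object@value < 0 | object@value > 255))
    return("value must lie in [0, 255]")
  TRUE
})

setMethod("show", "HsvImage", function(object) {
  cat(sprintf("HsvImage %d x %d (V mean %.1f)\n", nrow(object@hue),
              ncol(object@hue), mean(object@value)))
  invisible(NULL)
})

#' Convert an RGB image to gray
#'
#' BT.601 luma: 0.299 R + 0.587 G + 0.114 B, rounded to the nearest integer.
#'
#' @param img h x w x 3 integer array in [0, 255].
#' @return Integer matrix of the same height/width.
#' @examples
#' img <- array(c(255, 0, 0), c(1, 1, 3))
#' rgbToGray(img)  # 76
#' @export
rgbToGray <- function(img) {
  assertRgb(img)
  g <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  matrix(as.integer(round(g)), nrow = dim(img)[1])
}

#' RGB to HSV and back
#'
#' Standard hexcone conversions. The round trip
#' \code{hsvToRgb(rgbToHsv(x))} reproduces \code{x} within one intensity step
#' per channel.
#'
#' @param img for \code{rgbToHsv} an h x w x 3 array in [0, 255]; for
#'   \code{hsvToRgb} an \code{\link{HsvImage}}.
#' @return \code{rgbToHsv}: an \code{HsvImage}; \code{hsvToRgb}: an integer
#'   h x w x 3 array.
#' @export
rgbToHsv <- function(img) {
  assertRgb(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  m <- grDevices::rgb2hsv(rbind(as.vector(img[, , 1]),
                                as.vector(img[, , 2]),
                                as.vector(img[, , 3])),
                          maxColorValue = 255)
  hue <- m[1, ] * 360
  hue[hue >= 360] <- 0
  new("HsvImage",
      hue = matrix(hue, h, w),
      saturation = matrix(m[2, ], h, w),
      value = matrix(as.integer(round(m[3, ] * 255)), h, w))
}

#' @rdname rgbToHsv
#' @export
hsvToRgb <- function(img) {
  stopifnot(is(img, "HsvImage"))
  validObject(img)
  hh <- as.vector(img@hue) / 60
  s <- as.vector(img@saturation)
  v <- as.vector(img@value)
  i <- floor(hh) %% 6
  f <- hh - floor(hh)
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  d <- dim(img@hue)
  out <- array(0L, c(d[1], d[2], 3))
  out[, , 1] <- as.integer(round(r))
  out[, , 2] <- as.integer(round(g))
  out[, , 3] <- as.integer(round(b))
  out
}

# ---- file I/O ---------------------------------------------------------------

#' Read and write 8-bit RGB images
#'
#' PNG, JPEG and TIFF go through EBImage; uncompressed 24-bit BMP (the PH2
#' dermoscopy format) is handled natively. Images are returned as h x w x 3
#' integer arrays in [0, 255].
#'
#' @param path file path; format chosen by extension.
#' @param img h x w x 3 integer array in [0, 255].
#' @return \code{readImageRGB}: the image array. \code{writeImageRGB}: the
#'   path, invisibly.
#' @export
readImageRGB <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (grepl("\\.bmp$", path, ignore.case = TRUE)) return(readBmp(path))
  dat <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(dat)) == 2L) dat <- array(rep(dat, 3), c(dim(dat), 3))
  if (dim(dat)[3] > 3L) dat <- dat[, , 1:3, drop = FALSE]
  # EBImage stores (x, y, c); transpose to (row, col, c)
  aperm(array(as.integer(round(dat * 255)), dim(dat)), c(2, 1, 3))
}

#' @rdname readImageRGB
#' @export
writeImageRGB <- function(img, path) {
  assertRgb(img)
  if (grepl("\\.bmp$", path, ignore.case = TRUE)) return(writeBmp(img, path))
  ebi <- EBImage::Image(aperm(img / 255, c(2, 1, 3)), colormode = "Color")
  EBImage::writeImage(ebi, path)
  invisible(path)
}

#' Read and write binary masks
#'
#' Masks are single-channel PNG files; on read, any value above 127 maps to
#' lesion (255).
#'
#' @param path file path (PNG).
#' @param mask matrix with values in \{0, 255\}.
#' @return \code{readMaskImage}: a 0/255 integer matrix;
#'   \code{writeMaskImage}: the path, invisibly.
#' @export
readMaskImage <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  dat <- png::readPNG(path)
  if (length(dim(dat)) == 3L) dat <- dat[, , 1]
  matrix(ifelse(dat > 127 / 255, 255L, 0L), nrow(dat), ncol(dat))
}

#' @rdname readMaskImage
#' @export
writeMaskImage <- function(mask, path) {
  assertMask(mask)
  png::writePNG(mask / 255, path)
  invisible(path)
}

# Minimal uncompressed 24-bit BMP support (bottom-up rows, BGR byte order,
# rows padded to 4 bytes).
readBmp <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (rawToChar(raw[1:2]) != "BM") stop("not a BMP file: ", path, call. = FALSE)
  u32 <- function(off) sum(as.integer(raw[off + 1:4]) * 256^(0:3))
  u16 <- function(off) sum(as.integer(raw[off + 1:2]) * 256^(0:1))
  dataOff <- u32(10L)
  w <- u32(18L); hRaw <- u32(22L)
  topDown <- hRaw > 2^31
  h <- if (topDown) 2^32 - hRaw else hRaw
  bpp <- u16(28L); comp <- u32(30L)
  if (bpp != 24L || comp != 0L)
    stop("only uncompressed 24-bit BMP is supported", call. = FALSE)
  stride <- ((w * 3 + 3) %/% 4) * 4
  px <- as.integer(raw[dataOff + seq_len(stride * h)])
  img <- array(0L, c(h, w, 3))
  for (rowFile in seq_len(h)) {
    base <- (rowFile - 1) * stride
    row <- if (topDown) rowFile else h - rowFile + 1  # bottom-up storage
    idx <- base + seq(1L, by = 3L, length.out = w)
    img[row, , 3] <- px[idx]       # B
    img[row, , 2] <- px[idx + 1L]  # G
    img[row, , 1] <- px[idx + 2L]  # R
  }
  img
}

writeBmp <- function(img, path) {
  assertRgb(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  stride <- ((w * 3 + 3) %/% 4) * 4
  le <- function(x, n) as.raw((x %/% 256^(0:(n - 1))) %% 256)
  dataSize <- stride * h
  header <- c(charToRaw("BM"), le(54 + dataSize, 4), le(0, 4), le(54, 4),
              le(40, 4), le(w, 4), le(h, 4), le(1, 2), le(24, 2), le(0, 4),
              le(dataSize, 4), le(2835, 4), le(2835, 4), le(0, 4), le(0, 4))
  body <- raw(dataSize)
  for (rowFile in seq_len(h)) {
    row <- h - rowFile + 1
    base <- (rowFile - 1) * stride
    idx <- base + seq(1L, by = 3L, length.out = w)
    body[idx] <- as.raw(img[row, , 3])
    body[idx + 1L] <- as.raw(img[row, , 2])
    body[idx + 2L] <- as.raw(img[row, , 1])
  }
  writeBin(c(header, body), path)
  invisible(path)
}
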