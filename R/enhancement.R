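# Contrast enhancement on the HSV value channel only: hue and saturation pass
# through untouched. The default transfer is built from a modified histogram
# (blended toward uniform) whose cumulative distribution is passed through a
# logarithmic weighting that lifts dark levels (never below the identity),
# then re-stretched by a power curve that widens the bright tail, and
# normalized so the look-up table spans the full [0, 255] lattice.

#' Build the log-exp intensity transfer
#'
#' Three steps: (1) the value-channel histogram is blended toward uniform by
#' \code{strength}, smoothing the distribution without discarding levels;
#' (2) the cumulative distribution is passed through a log weighting
#' \eqn{\log(1+\lambda c)/\log(1+\lambda)} that raises dark-region output and
#' compresses bright-region gains, floored at the identity so no level is
#' ever darkened; (3) a nonlinear normalization (power 1.5) re-stretches the
#' bright tail that the log weighting compressed, and the curve is rescaled
#' so the table runs 0 to 255. The result is a monotone non-decreasing
#' look-up table with fixed endpoints.
#'
#' @param vHistogram integer vector of 256 counts of the value channel.
#' @param cfg an \code{\link{enhanceConfig}}.
#' @return Integer vector \code{lut} of length 256 mapping V to V'.
#' @export
buildLogExpTransfer <- function(vHistogram, cfg = enhanceConfig()) {
  if (length(vHistogram) != 256L || any(vHistogram < 0))
    stop("vHistogram must be 256 non-negative counts", call. = FALSE)
  total <- sum(vHistogram)
  if (total <= 0) stop("empty histogram", call. = FALSE)
  s <- cfg@strength
  hmod <- (1 - s) * vHistogram / total + s / 256
  cdf <- cumsum(hmod)
  lambda <- 9    # dark-lift gain of the log weighting
  lcurve <- log1p(lambda * cdf) / log1p(lambda)
  k <- (0:255) / 255
  f <- pmax(lcurve, k)^1.5  # identity floor, then bright-tail re-stretch
  f <- cummax(f)            # guard monotonicity
  if (f[256] - f[1] < .Machine$double.eps) {
    lut <- 0:255
  } else {
    lut <- as.integer(round(255 * (f - f[1]) / (f[256] - f[1])))
  }
  lut[1] <- 0L
  lut[256] <- 255L
  cummax(lut)
}

histeqTransfer <- function(vHistogram) {
  total <- sum(vHistogram)
  cdf <- cumsum(vHistogram) / total
  lut <- as.integer(round(255 * (cdf - cdf[1]) / max(cdf[256] - cdf[1],
                                                     .Machine$double.eps)))
  lut[1] <- 0L; lut[256] <- 255L
  cummax(lut)
}

#' Apply a look-up table to an intensity matrix
#'
#' @param v integer matrix in [0, 255].
#' @param lut integer vector of length 256.
#' @return Integer matrix.
#' @export
applyTransfer <- function(v, lut) {
  stopifnot(length(lut) == 256L)
  matrix(lut[v + 1L], nrow(v))
}

#' Enhance an RGB image through its value channel
#'
#' Converts to HSV, replaces V by the configured transfer (log-exp by default;
#' histogram equalization and CLAHE are available for ablation; "none" passes
#' through), keeps H and S bit-identical, and converts back. All transfers
#' except CLAHE are pointwise look-ups, so pixel ordering in V is preserved.
#'
#' @param img h x w x 3 integer array in [0, 255].
#' @param cfg an \code{\link{enhanceConfig}}.
#' @return Integer h x w x 3 array.
#' @export
enhanceImage <- function(img, cfg = enhanceConfig()) {
  assertRgb(img)
  hsv <- rgbToHsv(img)
  v <- hsv@value
  v2 <- switch(cfg@method,
    none = v,
    log_exp = {
      hist <- tabulate(as.vector(v) + 1L, nbins = 256L)
      applyTransfer(v, buildLogExpTransfer(hist, cfg))
    },
    histeq = {
      hist <- tabulate(as.vector(v) + 1L, nbins = 256L)
      applyTransfer(v, histeqTransfer(hist))
    },
    clahe = {
      # EBImage expects (x, y) order and [0,1] range
      cl <- EBImage::clahe(t(v) / 255, nx = 8, ny = 8)
      matrix(as.integer(round(clamp255(t(cl) * 255))), nrow(v))
    })
  hsv@value <- v2
  hsvToRgb(hsv)
}
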