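# Corner-border detection and detachment. Round dermatoscope lenses leave
# near-black borders in the image corners; segmenters confuse them with lesion
# tissue. The detector binarizes at a low gray threshold, records the extreme
# outer endpoints of corner-touching dark components, then walks each corner
# diagonal inward to locate the extreme inner contour; the ring between the
# two rectangles is detached by cropping to the inner rectangle's interior.

#' Extreme outer endpoints of corner borders
#'
#' Binarizes the gray image at the configured threshold, labels the connected
#' dark components, and for every image corner whose pixel belongs to a dark
#' component records that component's extreme position toward the corner. For
#' edge-touching borders these are the image corners themselves.
#'
#' @param gray integer matrix in [0, 255].
#' @param cfg a \code{\link{borderConfig}}.
#' @return Numeric k x 2 matrix of 0-based (row, col) endpoint positions in
#'   corner order TL, TR, BR, BL; zero rows when no corner-touching dark
#'   component exists.
#' @export
detectOuterContour <- function(gray, cfg = borderConfig()) {
  assertGray(gray)
  h <- nrow(gray); w <- ncol(gray)
  dark <- gray < cfg@grayThreshold
  if (!any(dark)) return(matrix(numeric(0), 0, 2))
  lab <- EBImage::bwlabel(dark)
  corners <- rbind(TL = c(1, 1), TR = c(1, w), BR = c(h, w), BL = c(h, 1))
  out <- NULL
  for (k in seq_len(nrow(corners))) {
    id <- lab[corners[k, 1], corners[k, 2]]
    if (id == 0) next
    idx <- which(lab == id, arr.ind = TRUE)
    r <- if (corners[k, 1] == 1) min(idx[, 1]) else max(idx[, 1])
    cc <- if (corners[k, 2] == 1) min(idx[, 2]) else max(idx[, 2])
    out <- rbind(out, c(r - 1, cc - 1))
  }
  if (is.null(out)) matrix(numeric(0), 0, 2) else unname(out)
}

# orientation reflections: map search coordinates (both counted from the
# corner being examined) back to original 0-based image coordinates
reflectCorner <- function(d, orientation, h, w) {
  switch(orientation,
         TL = c(d, d),
         TR = c(d, w - 1 - d),
         BL = c(h - 1 - d, d),
         BR = c(h - 1 - d, w - 1 - d))
}

#' Locate one inner corner of the border ring
#'
#' Walks the corner diagonal inward from \code{estimatedExtent} toward the
#' image corner, testing at each position (i, i) whether the pixel and its two
#' diagonal predecessors are all below the gray threshold; the first position
#' passing the test is the inner corner. Positions with fewer than two
#' predecessors cannot pass, so the walk reports "not found" once it moves
#' below index 2.
#'
#' @param gray integer matrix in [0, 255].
#' @param cfg a \code{\link{borderConfig}}.
#' @param orientation one of "TL", "TR", "BL", "BR"; coordinates are reflected
#'   so every corner is searched with the same top-left walk.
#' @return list with \code{row}, \code{col} (0-based, original frame) and
#'   \code{found}.
#' @export
findInnerCorner <- function(gray, cfg = borderConfig(),
                            orientation = c("TL", "TR", "BL", "BR")) {
  assertGray(gray)
  orientation <- match.arg(orientation)
  h <- nrow(gray); w <- ncol(gray)
  ext <- cfg@estimatedExtent
  if (h < ext + 1L || w < ext + 1L)
    stop("image smaller than the border search window (",
         ext + 1L, " px)", call. = FALSE)
  at <- function(d) {
    p <- reflectCorner(d, orientation, h, w)
    gray[p[1] + 1L, p[2] + 1L]
  }
  T <- cfg@grayThreshold
  for (d in seq(ext, 2L)) {
    if (at(d) < T && at(d - 1L) < T && at(d - 2L) < T) {
      p <- reflectCorner(d, orientation, h, w)
      return(list(row = p[1], col = p[2], found = TRUE))
    }
  }
  list(row = -1L, col = -1L, found = FALSE)
}

#' Detect the inner border rectangle
#'
#' Runs \code{\link{findInnerCorner}} for the top-left corner first; when that
#' search fails the image is declared border-free and no further corner is
#' searched. Otherwise the remaining three corners are located and the inner
#' rectangle assembled; a corner that is not found leaves its side at the
#' image edge.
#'
#' @inheritParams detectOuterContour
#' @return A \code{\link{CornerRects-class}} object.
#' @export
detectInnerRectangle <- function(gray, cfg = borderConfig()) {
  assertGray(gray)
  outer <- detectOuterContour(gray, cfg)
  inner <- matrix(-1L, 4, 2, dimnames = list(c("TL", "TR", "BL", "BR"), NULL))
  found <- logical(4)
  tl <- findInnerCorner(gray, cfg, "TL")
  searches <- 1L
  if (!tl$found)
    return(new("CornerRects", outer = outer, inner = inner, found = found,
               bordersPresent = FALSE, searches = searches))
  inner[1, ] <- c(tl$row, tl$col); found[1] <- TRUE
  for (k in 2:4) {
    ori <- c("TL", "TR", "BL", "BR")[k]
    p <- findInnerCorner(gray, cfg, ori)
    searches <- searches + 1L
    if (p$found) {
      inner[k, ] <- c(p$row, p$col)
      found[k] <- TRUE
    }
  }
  new("CornerRects", outer = outer, inner = inner, found = found,
      bordersPresent = TRUE, searches = searches)
}

# crop bounds (0-based, inclusive) strictly inside the inner rectangle;
# unfound corners leave their side at the image edge
cropBounds <- function(rects, h, w) {
  inner <- rects@inner; found <- rects@found
  rowOf <- function(k) inner[k, 1]; colOf <- function(k) inner[k, 2]
  top <- max(c(if (found[1]) rowOf(1), if (found[2]) rowOf(2), -1))
  bottom <- min(c(if (found[3]) rowOf(3), if (found[4]) rowOf(4), h))
  left <- max(c(if (found[1]) colOf(1), if (found[3]) colOf(3), -1))
  right <- min(c(if (found[2]) colOf(2), if (found[4]) colOf(4), w))
  c(top = top + 1, bottom = bottom - 1, left = left + 1, right = right - 1)
}

#' Detach the border ring
#'
#' Crops the image to the interior of the inner rectangle (the ring between
#' the outer and inner contours is discarded). The returned offset re-embeds
#' downstream masks into the original frame. Without borders the image is
#' returned unchanged with offset (0, 0).
#'
#' @param img h x w x 3 integer array in [0, 255].
#' @param rects a \code{\link{CornerRects-class}} computed from the grayscale
#'   of \code{img}.
#' @return list with \code{image} (the crop; pixels bit-identical to the
#'   original) and \code{offset}, the 0-based (row, col) of the crop's origin
#'   in the original frame.
#' @export
removeBorders <- function(img, rects) {
  assertRgb(img)
  stopifnot(is(rects, "CornerRects"))
  if (!rects@bordersPresent)
    return(list(image = img, offset = c(0L, 0L)))
  h <- dim(img)[1]; w <- dim(img)[2]
  b <- cropBounds(rects, h, w)
  if (b["bottom"] - b["top"] < 2 || b["right"] - b["left"] < 2)
    stop("border removal failed: inner rectangle interior is degenerate",
         call. = FALSE)
  crop <- img[(b["top"]:b["bottom"]) + 1L, (b["left"]:b["right"]) + 1L, ,
              drop = FALSE]
  list(image = crop, offset = c(as.integer(b["top"]), as.integer(b["left"])))
}

#' Re-embed a cropped-frame mask into the original frame
#'
#' Pixels on the detached ring are set to 0 (non-lesion).
#'
#' @param mask 0/255 matrix in the cropped frame.
#' @param offset 0-based (row, col) crop origin from \code{\link{removeBorders}}.
#' @param height,width original frame dimensions.
#' @return 0/255 integer matrix of size \code{height} x \code{width}.
#' @export
embedMask <- function(mask, offset, height, width) {
  assertMask(mask)
  out <- matrix(0L, height, width)
  out[offset[1] + seq_len(nrow(mask)), offset[2] + seq_len(ncol(mask))] <- mask
  out
}
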