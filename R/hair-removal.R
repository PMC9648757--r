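# Hair removal in three steps: (1) hair contours by a closing difference
# (grayscale closing with a structuring element larger than any hair width,
# minus the image, lights up thin dark structures); (2) a binary in-paint
# mask by gray-level slicing of the contour image; (3) fast-marching
# inpainting that fills masked pixels in order of arrival time from the mask
# boundary, each pixel as a normalized weighted sum of first-order
# extrapolations from its known neighbors.

makeKernel <- function(cfg) {
  k <- cfg@kernelSize
  switch(cfg@kernelShape,
         cross = {
           m <- matrix(0L, k, k)
           m[(k + 1L) %/% 2L, ] <- 1L
           m[, (k + 1L) %/% 2L] <- 1L
           m
         },
         box = matrix(1L, k, k),
         disc = EBImage::makeBrush(k, shape = "disc"))
}

#' Hair contour image
#'
#' Morphological closing of the gray image by the structuring element, minus
#' the image, clamped to [0, 255]. Structures thinner than the element (hairs,
#' 1-5 px at dermoscopy scale) produce bright responses; wider structures are
#' untouched by the closing and respond zero.
#'
#' @param gray integer matrix in [0, 255].
#' @param cfg a \code{\link{hairConfig}}.
#' @return Integer matrix in [0, 255].
#' @export
hairContour <- function(gray, cfg = hairConfig()) {
  assertGray(gray)
  if (cfg@kernelSize > nrow(gray) || cfg@kernelSize > ncol(gray))
    stop("structuring element larger than the image", call. = FALSE)
  closed <- EBImage::closing(gray / 255, makeKernel(cfg)) * 255
  matrix(as.integer(round(clamp255(closed - gray))), nrow(gray))
}

#' Gray-level slicing into a hair mask
#'
#' Pointwise transform of the contour image: values below the slice threshold
#' map to 0, all others to 255. An all-zero mask signals a hair-free image and
#' the pipeline skips inpainting entirely.
#'
#' @param contour integer matrix from \code{\link{hairContour}}.
#' @param cfg a \code{\link{hairConfig}}.
#' @return list with \code{mask} (0/255 matrix) and \code{hairsPresent}.
#' @export
makeHairMask <- function(contour, cfg = hairConfig()) {
  assertGray(contour, "contour")
  mask <- matrix(ifelse(contour < cfg@sliceThreshold, 0L, 255L),
                 nrow(contour))
  list(mask = mask, hairsPresent = any(mask == 255L))
}

# ---- fast-marching inpainting ----------------------------------------------

#' Inpainting weight of a known neighbor
#'
#' Product of three terms: \code{dir}, the projection of the unit p-q vector
#' on the boundary normal at p (clamped at zero so weights stay non-negative;
#' when the normal vanishes the term drops out); \code{dst}, the inverse
#' squared geometric distance d0^2/|p-q|^2 with d0 = 1; and \code{lev}, the
#' level-set proximity T0/(1 + |T(p)-T(q)|) with T0 = 1, where T is the
#' fast-marching distance map.
#'
#' @param p,q length-2 (row, col) positions; q must differ from p.
#' @param tP,tQ distance-map values at p and q.
#' @param normal length-2 boundary normal at p (need not be unit; zero means
#'   unknown).
#' @return Non-negative scalar weight.
#' @export
inpaintWeight <- function(p, q, tP, tQ, normal) {
  d <- c(p[1] - q[1], p[2] - q[2])
  len2 <- sum(d^2)
  if (len2 == 0) stop("p and q must differ", call. = FALSE)
  nn <- sqrt(sum(normal^2))
  dir <- if (nn == 0) 1 else max(0, sum(d * normal) / (sqrt(len2) * nn))
  dst <- 1 / len2
  lev <- 1 / (1 + abs(tP - tQ))
  dir * dst * lev
}

# binary min-heap keyed by arrival time, values are linear pixel indices;
# stale entries are skipped at pop time
heapNew <- function(cap = 1024L) {
  e <- new.env(parent = emptyenv())
  e$key <- numeric(cap); e$val <- integer(cap); e$n <- 0L
  e
}

heapPush <- function(e, key, val) {
  n <- e$n + 1L
  if (n > length(e$key)) {
    e$key <- c(e$key, numeric(length(e$key)))
    e$val <- c(e$val, integer(length(e$val)))
  }
  e$key[n] <- key; e$val[n] <- val; e$n <- n
  while (n > 1L) {
    p <- n %/% 2L
    if (e$key[p] <= e$key[n]) break
    tmpk <- e$key[p]; e$key[p] <- e$key[n]; e$key[n] <- tmpk
    tmpv <- e$val[p]; e$val[p] <- e$val[n]; e$val[n] <- tmpv
    n <- p
  }
  invisible(NULL)
}

heapPop <- function(e) {
  if (e$n == 0L) return(NULL)
  out <- c(e$key[1L], e$val[1L])
  n <- e$n
  e$key[1L] <- e$key[n]; e$val[1L] <- e$val[n]; e$n <- n - 1L
  n <- n - 1L
  i <- 1L
  repeat {
    l <- 2L * i; r <- l + 1L; s <- i
    if (l <= n && e$key[l] < e$key[s]) s <- l
    if (r <= n && e$key[r] < e$key[s]) s <- r
    if (s == i) break
    tmpk <- e$key[s]; e$key[s] <- e$key[i]; e$key[i] <- tmpk
    tmpv <- e$val[s]; e$val[s] <- e$val[i]; e$val[i] <- tmpv
    i <- s
  }
  out
}

# upwind solution of the unit-speed arrival equation at one pixel, using
# KNOWN neighbors only
solveArrival <- function(Tm, known, r, c, h, w) {
  tx <- Inf
  if (r > 1L && known[r - 1L, c]) tx <- Tm[r - 1L, c]
  if (r < h && known[r + 1L, c]) tx <- min(tx, Tm[r + 1L, c])
  ty <- Inf
  if (c > 1L && known[r, c - 1L]) ty <- Tm[r, c - 1L]
  if (c < w && known[r, c + 1L]) ty <- min(ty, Tm[r, c + 1L])
  if (is.infinite(tx) && is.infinite(ty)) return(Inf)
  if (is.finite(tx) && is.finite(ty) && abs(tx - ty) < 1) {
    (tx + ty + sqrt(2 - (tx - ty)^2)) / 2
  } else {
    min(tx, ty) + 1
  }
}

#' Fast-marching inpainting
#'
#' Fills masked pixels in non-decreasing order of arrival time from the mask
#' boundary (the arrival map solves the unit-speed eikonal equation by fast
#' marching). Each pixel is reconstructed per channel as the normalized
#' weighted sum of first-order extrapolations \eqn{I(q) + \nabla I(q)\cdot(p-q)}
#' over already-known pixels q in its neighborhood, with weights from
#' \code{\link{inpaintWeight}}. Unmasked pixels are returned bit-identical.
#'
#' @param img h x w x 3 integer array in [0, 255].
#' @param mask 0/255 matrix; 255 marks pixels to fill.
#' @param radius neighborhood half-width (default 2).
#' @return Integer h x w x 3 array.
#' @export
inpaintTelea <- function(img, mask, radius = 2L) {
  assertRgb(img)
  assertMask(mask)
  h <- dim(img)[1]; w <- dim(img)[2]
  stopifnot(nrow(mask) == h, ncol(mask) == w)
  if (!any(mask == 255L)) return(img)
  radius <- as.integer(radius)

  work <- array(as.numeric(img), dim(img))
  inside <- mask == 255L
  known <- !inside
  Tm <- matrix(0, h, w)
  Tm[inside] <- 1e6

  hp <- heapNew()
  inHeap <- matrix(FALSE, h, w)
  # seed the narrow band with known pixels bordering the fill region
  shift <- function(m, dr, dc) {
    out <- matrix(FALSE, h, w)
    rs <- max(1, 1 + dr):min(h, h + dr)
    cs <- max(1, 1 + dc):min(w, w + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  nearInside <- shift(inside, 1, 0) | shift(inside, -1, 0) |
    shift(inside, 0, 1) | shift(inside, 0, -1)
  band <- which(known & nearInside)
  for (idx in band) heapPush(hp, 0, idx)
  inHeap[band] <- TRUE

  offs <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  odr <- offs$dr; odc <- offs$dc

  fillPixel <- function(r, c) {
    rr <- r + odr; cc <- c + odc
    ok <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
    rr <- rr[ok]; cc <- cc[ok]
    qi <- (cc - 1L) * h + rr
    ok2 <- known[qi]
    if (!any(ok2)) return(invisible(NULL))  # unreachable under FMM ordering
    rr <- rr[ok2]; cc <- cc[ok2]; qi <- qi[ok2]
    dr <- r - rr; dc <- c - cc
    len2 <- dr^2 + dc^2

    # boundary normal: gradient of the arrival map at p over known pixels
    gradAxis <- function(rp, rm, cp, cm) {
      hasP <- rp >= 1L && rp <= h && cp >= 1L && cp <= w && known[rp, cp]
      hasM <- rm >= 1L && rm <= h && cm >= 1L && cm <= w && known[rm, cm]
      if (hasP && hasM) (Tm[rp, cp] - Tm[rm, cm]) / 2
      else if (hasP) Tm[rp, cp] - Tm[r, c]
      else if (hasM) Tm[r, c] - Tm[rm, cm]
      else 0
    }
    nR <- gradAxis(r + 1L, r - 1L, c, c)
    nC <- gradAxis(r, r, c + 1L, c - 1L)
    nn <- sqrt(nR^2 + nC^2)
    if (nn > 0) {
      dirw <- pmax(0, (dr * nR + dc * nC) / (sqrt(len2) * nn))
    } else {
      dirw <- rep(1, length(qi))
    }
    dstw <- 1 / len2
    levw <- 1 / (1 + abs(Tm[r, c] - Tm[qi]))
    wgt <- dirw * dstw * levw
    if (sum(wgt) <= 1e-12) wgt <- dstw * levw

    # central-difference image gradient at each q over known pixels
    up <- qi - 1L; dn <- qi + 1L
    lf <- qi - h; rt <- qi + h
    okV <- rr > 1L & rr < h & known[pmax(up, 1L)] & known[pmin(dn, h * w)]
    okH <- cc > 1L & cc < w & known[pmax(lf, 1L)] & known[pmin(rt, h * w)]
    tot <- sum(wgt)
    for (ch in 1:3) {
      plane <- work[, , ch]
      gR <- ifelse(okV, (plane[pmin(dn, h * w)] - plane[pmax(up, 1L)]) / 2, 0)
      gC <- ifelse(okH, (plane[pmin(rt, h * w)] - plane[pmax(lf, 1L)]) / 2, 0)
      est <- plane[qi] + gR * dr + gC * dc
      work[r, c, ch] <<- min(255, max(0, sum(wgt * est) / tot))
    }
    invisible(NULL)
  }

  while (!is.null(pp <- heapPop(hp))) {
    idx <- as.integer(pp[2])
    if (known[idx]) {
      # stale entry unless this is a seed band pixel not yet expanded
      if (!inHeap[idx]) next
      inHeap[idx] <- FALSE
    } else {
      c0 <- (idx - 1L) %/% h + 1L
      r0 <- idx - (c0 - 1L) * h
      fillPixel(r0, c0)
      known[idx] <- TRUE
      inHeap[idx] <- FALSE
    }
    c0 <- (idx - 1L) %/% h + 1L
    r0 <- idx - (c0 - 1L) * h
    for (k in 1:4) {
      r1 <- r0 + c(-1L, 1L, 0L, 0L)[k]
      c1 <- c0 + c(0L, 0L, -1L, 1L)[k]
      if (r1 < 1L || r1 > h || c1 < 1L || c1 > w) next
      if (known[r1, c1]) next
      tNew <- solveArrival(Tm, known, r1, c1, h, w)
      if (tNew < Tm[r1, c1]) {
        Tm[r1, c1] <- tNew
        heapPush(hp, tNew, (c1 - 1L) * h + r1)
        inHeap[r1, c1] <- TRUE
      }
    }
  }

  out <- img
  fillIdx <- which(inside)
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[fillIdx] <- as.integer(round(work[, , ch][fillIdx]))
    out[, , ch] <- plane
  }
  out
}

#' Detect and remove hairs
#'
#' Runs the closing-difference contour, gray-level slicing, optional mask
#' cleaning/dilation, and fast-marching inpainting. When the sliced mask is
#' empty the image is returned bit-identical and inpainting is skipped.
#'
#' @param img h x w x 3 integer array in [0, 255].
#' @param cfg a \code{\link{hairConfig}}.
#' @return list with \code{image}, \code{hairsPresent}, \code{mask} (the mask
#'   actually inpainted) and \code{contour}.
#' @export
removeHairs <- function(img, cfg = hairConfig()) {
  assertRgb(img)
  gray <- rgbToGray(img)
  contour <- hairContour(gray, cfg)
  sliced <- makeHairMask(contour, cfg)
  if (!sliced$hairsPresent)
    return(list(image = img, hairsPresent = FALSE, mask = sliced$mask,
                contour = contour))
  mask <- sliced$mask
  if (cfg@cleanMask > 0L) {
    lab <- EBImage::bwlabel(mask == 255L)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= cfg@cleanMask)
    mask <- matrix(ifelse(lab %in% keep & lab > 0, 255L, 0L), nrow(mask))
  }
  if (cfg@dilateMask) {
    mask <- matrix(as.integer(
      EBImage::dilate(mask / 255, matrix(1L, 3, 3)) * 255), nrow(mask))
  }
  list(image = inpaintTelea(img, mask, cfg@inpaintRadius),
       hairsPresent = TRUE, mask = mask, contour = contour)
}
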