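# Seeded synthetic dermoscopy fixtures: a noisy skin background with a mild
# illumination gradient, an irregular darker lesion (ellipse with
# low-frequency radial perturbation and a smoothed edge), optional thin dark
# hair strokes, and optional dark corner borders touching the image corners
# -- each layer with a paired ground-truth mask, so every pipeline stage is
# testable without downloading a dermoscopy dataset.

#' Fixture specification
#'
#' @slot seed integer; one RNG stream per fixture is derived from it, and the
#'   global RNG state is left untouched.
#' @slot height,width frame size in pixels (default 512 x 512).
#' @slot skinColor RGB mean of the skin background.
#' @slot skinNoiseSd per-pixel texture noise sd; the noise is clipped at
#'   1.5 sd so the skin's peak-to-trough stays below the hair-slicing
#'   threshold (texture must not register as hair).
#' @slot illumAmplitude amplitude of the low-frequency illumination gradient.
#' @slot lesionColor RGB mean of the lesion.
#' @slot lesionAxes semi-axes as fractions of the smaller frame dimension;
#'   \code{NA} draws them from [0.20, 0.26].
#' @slot lesionPerturb radial perturbation amplitude (fraction of radius);
#'   two low-frequency lobes (2 and 3 cycles) keep the border irregular but
#'   smooth at dermoscopy scale.
#' @slot lesionEdgeSigma Gaussian softness of the lesion border in pixels
#'   (default 6): real lesion borders fade gradually, and together with the
#'   bounded texture noise this keeps artifact-free skin below the
#'   hair-slicing threshold at the default frame size.
#' @slot borders logical; \code{borderThickness} in [4, 20] px;
#'   \code{borderIntensity} must stay below the detection threshold 4;
#'   \code{borderStyle} "wedge" (corner triangles) or "frame" (uniform ring).
#' @slot hairs logical; \code{hairCount} strokes of width 1 to
#'   \code{hairWidth} px at \code{hairIntensity}, drawn as random quadratic
#'   curves; \code{hairCurvature} scales the control-point offset.
#' @export
setClass("FixtureSpec", representation(
  seed = "integer", height = "integer", width = "integer",
  skinColor = "numeric", skinNoiseSd = "numeric", illumAmplitude = "numeric",
  lesionColor = "numeric", lesionAxes = "numeric", lesionPerturb = "numeric",
  lesionEdgeSigma = "numeric",
  borders = "logical", borderThickness = "integer",
  borderIntensity = "integer", borderStyle = "character",
  hairs = "logical", hairCount = "integer", hairWidth = "integer",
  hairIntensity = "integer", hairCurvature = "numeric"
))

setValidity("FixtureSpec", function(object) {
  if (object@height < 32L || object@width < 32L)
    return("frame must be at least 32 x 32")
  if (length(object@skinColor) != 3L || length(object@lesionColor) != 3L)
    return("skinColor and lesionColor must be RGB triples")
  if (object@borders) {
    if (object@borderThickness < 4L || object@borderThickness > 20L)
      return("borderThickness must lie in [4, 20]")
    if (object@borderIntensity >= 4L)
      return("borderIntensity must stay below the detection threshold 4")
    if (!object@borderStyle %in% c("wedge", "frame"))
      return("borderStyle must be wedge or frame")
  }
  if (object@hairs && (object@hairWidth < 1L || object@hairWidth > 3L))
    return("hairWidth must lie in [1, 3]")
  TRUE
})

#' @param seed,height,width,skinColor,skinNoiseSd,illumAmplitude,lesionColor,lesionAxes,lesionPerturb,lesionEdgeSigma,borders,borderThickness,borderIntensity,borderStyle,hairs,hairCount,hairWidth,hairIntensity,hairCurvature
#'   see slot documentation.
#' @return A \code{FixtureSpec}.
#' @rdname FixtureSpec-class
#' @export
fixtureSpec <- function(seed = 0L, height = 512L, width = 512L,
                        skinColor = c(205, 165, 150), skinNoiseSd = 1.5,
                        illumAmplitude = 10,
                        lesionColor = c(115, 78, 68),
                        lesionAxes = c(NA_real_, NA_real_),
                        lesionPerturb = 0.10, lesionEdgeSigma = 6,
                        borders = FALSE, borderThickness = 12L,
                        borderIntensity = 2L, borderStyle = "wedge",
                        hairs = FALSE, hairCount = 12L, hairWidth = 2L,
                        hairIntensity = 40L, hairCurvature = 0.25) {
  new("FixtureSpec", seed = as.integer(seed), height = as.integer(height),
      width = as.integer(width), skinColor = skinColor,
      skinNoiseSd = skinNoiseSd, illumAmplitude = illumAmplitude,
      lesionColor = lesionColor, lesionAxes = lesionAxes,
      lesionPerturb = lesionPerturb, lesionEdgeSigma = lesionEdgeSigma,
      borders = borders,
      borderThickness = as.integer(borderThickness),
      borderIntensity = as.integer(borderIntensity),
      borderStyle = borderStyle, hairs = hairs,
      hairCount = as.integer(hairCount), hairWidth = as.integer(hairWidth),
      hairIntensity = as.integer(hairIntensity),
      hairCurvature = hairCurvature)
}

#' Synthetic fixture
#'
#' @slot image h x w x 3 integer array.
#' @slot lesionTruth,borderTruth,hairTruth 0/255 matrices in the image frame.
#' @slot spec the generating \code{\link{FixtureSpec}}.
#' @export
setClass("Fixture", representation(
  image = "array", lesionTruth = "matrix", borderTruth = "matrix",
  hairTruth = "matrix", spec = "FixtureSpec"
))

setMethod("show", "Fixture", function(object) {
  cat(sprintf("Fixture %d x %d (seed %d): lesion %d px, borders %s, hairs %s\n",
              dim(object@image)[1], dim(object@image)[2], object@spec@seed,
              sum(object@lesionTruth == 255L),
              if (object@spec@borders) "on" else "off",
              if (object@spec@hairs) "on" else "off"))
  invisible(NULL)
})

#' @param x a \code{Fixture}.
#' @return \code{fixtureImage}: the RGB array; the truth accessors return
#'   0/255 matrices.
#' @rdname Fixture-class
#' @export
fixtureImage <- function(x) { stopifnot(is(x, "Fixture")); x@image }
#' @rdname Fixture-class
#' @export
lesionTruth <- function(x) { stopifnot(is(x, "Fixture")); x@lesionTruth }
#' @rdname Fixture-class
#' @export
borderTruth <- function(x) { stopifnot(is(x, "Fixture")); x@borderTruth }
#' @rdname Fixture-class
#' @export
hairTruth <- function(x) { stopifnot(is(x, "Fixture")); x@hairTruth }

withFixtureRng <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate one synthetic dermoscopy fixture
#'
#' Layers are composited in order skin, lesion, hairs, corner borders;
#' generation is bit-deterministic given the spec.
#'
#' @param spec a \code{\link{fixtureSpec}}.
#' @return A \code{\link{Fixture-class}}.
#' @export
generateFixture <- function(spec = fixtureSpec()) {
  validObject(spec)
  withFixtureRng(spec@seed, {
    h <- spec@height; w <- spec@width
    rows <- matrix(seq_len(h), h, w)
    cols <- matrix(seq_len(w), h, w, byrow = TRUE)

    # skin with a low-frequency illumination gradient
    phi <- stats::runif(2, 0, 2 * pi)
    illum <- spec@illumAmplitude *
      sin(2 * pi * rows / h / 2 + phi[1]) * cos(2 * pi * cols / w / 2 + phi[2])
    clipNoise <- function(n, sd) {
      if (sd <= 0) return(numeric(n))
      pmin(pmax(stats::rnorm(n, sd = sd), -1.5 * sd), 1.5 * sd)
    }
    img <- array(0, c(h, w, 3))
    for (ch in 1:3)
      img[, , ch] <- spec@skinColor[ch] + illum +
        clipNoise(h * w, spec@skinNoiseSd)

    # lesion: perturbed ellipse, smoothed edge
    cen <- c(h, w) / 2 + stats::runif(2, -0.03, 0.03) * c(h, w)
    ax <- spec@lesionAxes
    if (anyNA(ax)) ax <- stats::runif(2, 0.20, 0.26)
    ax <- ax * min(h, w)
    dr <- rows - cen[1]; dc <- cols - cen[2]
    theta <- atan2(dc, dr)
    pphi <- stats::runif(2, 0, 2 * pi)
    rad <- 1 + spec@lesionPerturb *
      (0.6 * sin(2 * theta + pphi[1]) + 0.4 * sin(3 * theta + pphi[2]))
    inside <- (dr / ax[1])^2 + (dc / ax[2])^2 <= rad^2
    lesionTruth <- matrix(ifelse(inside, 255L, 0L), h, w)
    alphaMap <- EBImage::gblur(inside * 1, sigma = spec@lesionEdgeSigma)
    alphaMap <- pmin(pmax(alphaMap, 0), 1)
    lesionNoise <- clipNoise(h * w, spec@skinNoiseSd)
    for (ch in 1:3)
      img[, , ch] <- img[, , ch] * (1 - alphaMap) +
        (spec@lesionColor[ch] + lesionNoise) * alphaMap

    # hairs: random quadratic curves, width 1..hairWidth
    hairTruth <- matrix(0L, h, w)
    if (spec@hairs && spec@hairCount > 0L) {
      for (k in seq_len(spec@hairCount)) {
        edgePoint <- function() {
          side <- sample.int(4L, 1L)
          switch(side,
                 c(1, stats::runif(1, 1, w)),
                 c(h, stats::runif(1, 1, w)),
                 c(stats::runif(1, 1, h), 1),
                 c(stats::runif(1, 1, h), w))
        }
        p0 <- edgePoint(); p2 <- edgePoint()
        if (sum((p0 - p2)^2) < (min(h, w) / 4)^2) p2 <- c(h + 1 - p0[1], w + 1 - p0[2])
        mid <- (p0 + p2) / 2 +
          stats::runif(2, -1, 1) * spec@hairCurvature * c(h, w)
        tt <- seq(0, 1, length.out = 3L * max(h, w))
        pr <- (1 - tt)^2 * p0[1] + 2 * (1 - tt) * tt * mid[1] + tt^2 * p2[1]
        pc <- (1 - tt)^2 * p0[2] + 2 * (1 - tt) * tt * mid[2] + tt^2 * p2[2]
        wk <- sample.int(spec@hairWidth, 1L)
        rad <- (wk - 1) / 2
        offs <- expand.grid(dr = -ceiling(rad):ceiling(rad),
                            dc = -ceiling(rad):ceiling(rad))
        offs <- offs[offs$dr^2 + offs$dc^2 <= max(rad, 0.5)^2, ]
        for (o in seq_len(nrow(offs))) {
          rr <- round(pr) + offs$dr[o]; cc <- round(pc) + offs$dc[o]
          ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
          hairTruth[cbind(rr[ok], cc[ok])] <- 255L
        }
      }
      hIdx <- which(hairTruth == 255L)
      shade <- spec@hairIntensity + stats::rnorm(length(hIdx), sd = 3)
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[hIdx] <- shade + (ch - 2) * 2  # slight warm tint
        img[, , ch] <- plane
      }
    }

    # corner borders touch the four image corners
    borderTruth <- matrix(0L, h, w)
    if (spec@borders) {
      t <- spec@borderThickness
      bmask <- if (spec@borderStyle == "frame") {
        rows <= t | rows > h - t | cols <= t | cols > w - t
      } else {
        r0 <- rows - 1; c0 <- cols - 1
        (r0 + c0 < 2 * t) | (r0 + (w - 1 - c0) < 2 * t) |
          ((h - 1 - r0) + c0 < 2 * t) | ((h - 1 - r0) + (w - 1 - c0) < 2 * t)
      }
      borderTruth <- matrix(ifelse(bmask, 255L, 0L), h, w)
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[bmask] <- spec@borderIntensity
        img[, , ch] <- plane
      }
      lesionTruth[bmask] <- 0L
      if (any(lesionTruth == 255L & borderTruth == 255L))
        stop("lesion overlaps the corner borders", call. = FALSE)
    }

    out <- array(0L, c(h, w, 3))
    for (ch in 1:3)
      out[, , ch] <- as.integer(round(clamp255(img[, , ch])))
    new("Fixture", image = out, lesionTruth = lesionTruth,
        borderTruth = borderTruth, hairTruth = hairTruth, spec = spec)
  })
}

specToKv <- function(spec) {
  c(seed = spec@seed, height = spec@height, width = spec@width,
    skinColor = paste(spec@skinColor, collapse = ","),
    skinNoiseSd = spec@skinNoiseSd, illumAmplitude = spec@illumAmplitude,
    lesionColor = paste(spec@lesionColor, collapse = ","),
    lesionAxes = paste(spec@lesionAxes, collapse = ","),
    lesionPerturb = spec@lesionPerturb,
    lesionEdgeSigma = spec@lesionEdgeSigma,
    borders = spec@borders, borderThickness = spec@borderThickness,
    borderIntensity = spec@borderIntensity, borderStyle = spec@borderStyle,
    hairs = spec@hairs, hairCount = spec@hairCount,
    hairWidth = spec@hairWidth, hairIntensity = spec@hairIntensity,
    hairCurvature = spec@hairCurvature)
}

kvToSpec <- function(kv) {
  num3 <- function(s) {
    v <- strsplit(s, ",")[[1]]
    ifelse(v == "NA", NA_real_, as.numeric(ifelse(v == "NA", "0", v)))
  }
  fixtureSpec(seed = as.integer(kv[["seed"]]),
              height = as.integer(kv[["height"]]),
              width = as.integer(kv[["width"]]),
              skinColor = num3(kv[["skinColor"]]),
              skinNoiseSd = as.numeric(kv[["skinNoiseSd"]]),
              illumAmplitude = as.numeric(kv[["illumAmplitude"]]),
              lesionColor = num3(kv[["lesionColor"]]),
              lesionAxes = num3(kv[["lesionAxes"]]),
              lesionPerturb = as.numeric(kv[["lesionPerturb"]]),
              lesionEdgeSigma = as.numeric(kv[["lesionEdgeSigma"]]),
              borders = as.logical(kv[["borders"]]),
              borderThickness = as.integer(kv[["borderThickness"]]),
              borderIntensity = as.integer(kv[["borderIntensity"]]),
              borderStyle = kv[["borderStyle"]],
              hairs = as.logical(kv[["hairs"]]),
              hairCount = as.integer(kv[["hairCount"]]),
              hairWidth = as.integer(kv[["hairWidth"]]),
              hairIntensity = as.integer(kv[["hairIntensity"]]),
              hairCurvature = as.numeric(kv[["hairCurvature"]]))
}

#' Generate a fixture suite on disk
#'
#' Writes n fixtures (seeds base .. base + n - 1) as a PNG image plus three
#' ground-truth masks each, and a plain-text key-value manifest from which the
#' suite can be regenerated bit-identically.
#'
#' @param n number of fixtures (>= 1).
#' @param baseSpec spec whose seed anchors the suite.
#' @param outDir output directory (created if missing).
#' @return data.frame manifest with one row per fixture (id, seed, files).
#' @export
generateSuite <- function(n, baseSpec = fixtureSpec(), outDir) {
  stopifnot(n >= 1)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outDir)) stop("cannot create ", outDir, call. = FALSE)
  lines <- character(0)
  man <- NULL
  for (k in seq_len(n)) {
    spec <- baseSpec
    spec@seed <- baseSpec@seed + k - 1L
    id <- sprintf("fixture_%03d", spec@seed)
    fx <- generateFixture(spec)
    writeImageRGB(fx@image, file.path(outDir, paste0(id, "_image.png")))
    writeMaskImage(fx@lesionTruth, file.path(outDir, paste0(id, "_lesion.png")))
    writeMaskImage(fx@borderTruth, file.path(outDir, paste0(id, "_border.png")))
    writeMaskImage(fx@hairTruth, file.path(outDir, paste0(id, "_hair.png")))
    kv <- specToKv(spec)
    lines <- c(lines, paste0("[", id, "]"),
               paste0(names(kv), "=", unname(kv)), "")
    man <- rbind(man, data.frame(id = id, seed = spec@seed,
                                 image = paste0(id, "_image.png"),
                                 lesion = paste0(id, "_lesion.png"),
                                 stringsAsFactors = FALSE))
  }
  writeLines(lines, file.path(outDir, "manifest.txt"))
  man
}

#' Read a suite manifest back into fixture specs
#'
#' @param path manifest.txt written by \code{\link{generateSuite}}.
#' @return Named list of \code{\link{FixtureSpec}} objects.
#' @export
readManifest <- function(path) {
  lines <- readLines(path)
  out <- list()
  cur <- NULL; kv <- character(0)
  flush <- function() if (!is.null(cur)) out[[cur]] <<- kvToSpec(kv)
  for (ln in lines) {
    if (grepl("^\\[", ln)) {
      flush()
      cur <- sub("^\\[(.*)\\]$", "\\1", ln)
      kv <- character(0)
    } else if (nzchar(ln)) {
      p <- sub("=.*$", "", ln)
      kv[p] <- sub("^[^=]*=", "", ln)
    }
  }
  flush()
  out
}
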