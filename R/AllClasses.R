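#' @import methods
NULL

# ---- configuration classes --------------------------------------------------

#' Corner-border search configuration
#'
#' Parameters for locating the extreme inner contour of dark corner borders.
#' The search binarizes at \code{grayThreshold} and walks each corner diagonal
#' inward starting from \code{estimatedExtent}, the assumed maximal border
#' thickness in pixels.
#'
#' @slot grayThreshold integer, gray level T below which a pixel counts as
#'   border-dark. Default 4.
#' @slot estimatedExtent integer, maximal border length/width in pixels
#'   (default 20); the diagonal walk starts here. Must be at least 3 so the
#'   two diagonal predecessors of the walk test exist.
#' @export
setClass("BorderConfig", representation(
  grayThreshold = "integer",
  estimatedExtent = "integer"
))

setValidity("BorderConfig", function(object) {
  t <- object@grayThreshold
  e <- object@estimatedExtent
  if (length(t) != 1L || is.na(t) || t <= 0L || t >= 255L)
    return("grayThreshold must be a single integer in (0, 255)")
  if (length(e) != 1L || is.na(e) || e < 3L)
    return("estimatedExtent must be >= 3 (the walk needs two diagonal predecessors)")
  TRUE
})

#' @param grayThreshold,estimatedExtent see slot documentation.
#' @return A \code{BorderConfig} object.
#' @rdname BorderConfig-class
#' @export
borderConfig <- function(grayThreshold = 4L, estimatedExtent = 20L) {
  new("BorderConfig", grayThreshold = as.integer(grayThreshold),
      estimatedExtent = as.integer(estimatedExtent))
}

#' Hair-removal configuration
#'
#' @slot kernelSize integer, odd side length of the structuring element used in
#'   the closing difference (default 17). Hairs must be strictly thinner than
#'   the kernel to respond.
#' @slot kernelShape "cross", "box" or "disc".
#' @slot sliceThreshold integer; contour values below it slice to 0, all
#'   others to 255 (default 10).
#' @slot inpaintRadius integer, neighborhood half-width used by the
#'   fast-marching inpainting (default 2).
#' @slot dilateMask logical, dilate the hair mask by one pixel before
#'   inpainting to cover anti-aliased fringes (default TRUE).
#' @slot cleanMask integer, remove mask speckles smaller than this many pixels
#'   before inpainting; 0 (default) disables cleaning.
#' @export
setClass("HairConfig", representation(
  kernelSize = "integer",
  kernelShape = "character",
  sliceThreshold = "integer",
  inpaintRadius = "integer",
  dilateMask = "logical",
  cleanMask = "integer"
))

setValidity("HairConfig", function(object) {
  if (object@kernelSize < 3L || object@kernelSize %% 2L == 0L)
    return("kernelSize must be odd and >= 3")
  if (!object@kernelShape %in% c("cross", "box", "disc"))
    return("kernelShape must be one of cross, box, disc")
  if (object@sliceThreshold <= 0L || object@sliceThreshold >= 255L)
    return("sliceThreshold must lie in (0, 255)")
  if (object@inpaintRadius < 1L)
    return("inpaintRadius must be >= 1")
  if (object@cleanMask < 0L)
    return("cleanMask must be >= 0")
  TRUE
})

#' @param kernelSize,kernelShape,sliceThreshold,inpaintRadius,dilateMask,cleanMask
#'   see slot documentation.
#' @return A \code{HairConfig} object.
#' @rdname HairConfig-class
#' @export
hairConfig <- function(kernelSize = 17L, kernelShape = "cross",
                       sliceThreshold = 10L, inpaintRadius = 2L,
                       dilateMask = TRUE, cleanMask = 0L) {
  new("HairConfig", kernelSize = as.integer(kernelSize),
      kernelShape = kernelShape, sliceThreshold = as.integer(sliceThreshold),
      inpaintRadius = as.integer(inpaintRadius), dilateMask = dilateMask,
      cleanMask = as.integer(cleanMask))
}

#' Contrast-enhancement configuration
#'
#' @slot method "log_exp" (default), "clahe", "histeq" or "none".
#' @slot strength numeric in [0,1]; blend of the value-channel histogram toward
#'   uniform before the transfer is built (default 0.5).
#' @export
setClass("EnhanceConfig", representation(
  method = "character",
  strength = "numeric"
))

setValidity("EnhanceConfig", function(object) {
  if (!object@method %in% c("log_exp", "clahe", "histeq", "none"))
    return("method must be one of log_exp, clahe, histeq, none")
  if (object@strength < 0 || object@strength > 1)
    return("strength must lie in [0, 1]")
  TRUE
})

#' @param method,strength see slot documentation.
#' @return An \code{EnhanceConfig} object.
#' @rdname EnhanceConfig-class
#' @export
enhanceConfig <- function(method = "log_exp", strength = 0.5) {
  new("EnhanceConfig", method = method, strength = strength)
}

#' GrabCut configuration
#'
#' @slot startPct,endPct numeric percentages defining the automatic
#'   initialization rectangle: the start corner sits startPct% in from the
#'   top-left, the end corner endPct% in from the bottom-right (defaults 5, 7).
#' @slot nComponents integer, Gaussian components per mixture (default 5).
#' @slot maxIters integer, iteration cap (default 5).
#' @slot convergenceTol numeric, stop once the fraction of pixels changing
#'   label falls below this (default 0.001).
#' @slot gamma numeric, smoothness weight on neighbor links (default 50).
#' @slot seed integer seed for the k-means mixture initialization (default 0).
#' @export
setClass("GrabCutConfig", representation(
  startPct = "numeric",
  endPct = "numeric",
  nComponents = "integer",
  maxIters = "integer",
  convergenceTol = "numeric",
  gamma = "numeric",
  seed = "integer"
))

setValidity("GrabCutConfig", function(object) {
  if (object@startPct <= 0 || object@startPct >= 50 ||
      object@endPct <= 0 || object@endPct >= 50)
    return("startPct and endPct must lie in (0, 50)")
  if (object@nComponents < 1L) return("nComponents must be >= 1")
  if (object@maxIters < 1L) return("maxIters must be >= 1")
  if (object@convergenceTol < 0) return("convergenceTol must be >= 0")
  if (object@gamma < 0) return("gamma must be >= 0")
  TRUE
})

#' @param startPct,endPct,nComponents,maxIters,convergenceTol,gamma,seed see
#'   slot documentation.
#' @return A \code{GrabCutConfig} object.
#' @rdname GrabCutConfig-class
#' @export
grabCutConfig <- function(startPct = 5, endPct = 7, nComponents = 5L,
                          maxIters = 5L, convergenceTol = 0.001,
                          gamma = 50, seed = 0L) {
  new("GrabCutConfig", startPct = startPct, endPct = endPct,
      nComponents = as.integer(nComponents), maxIters = as.integer(maxIters),
      convergenceTol = convergenceTol, gamma = gamma, seed = as.integer(seed))
}

#' Whole-pipeline configuration
#'
#' Bundles the per-stage configurations with independent stage toggles.
#'
#' @slot border,hair,enhance,grabcut stage configurations.
#' @slot doBorder,doHair,doEnhance logical stage toggles (segmentation always
#'   runs).
#' @export
setClass("PipelineConfig", representation(
  border = "BorderConfig",
  hair = "HairConfig",
  enhance = "EnhanceConfig",
  grabcut = "GrabCutConfig",
  doBorder = "logical",
  doHair = "logical",
  doEnhance = "logical"
))

#' @param border,hair,enhance,grabcut,doBorder,doHair,doEnhance see slot
#'   documentation.
#' @return A \code{PipelineConfig} object.
#' @rdname PipelineConfig-class
#' @export
pipelineConfig <- function(border = borderConfig(), hair = hairConfig(),
                           enhance = enhanceConfig(), grabcut = grabCutConfig(),
                           doBorder = TRUE, doHair = TRUE, doEnhance = TRUE) {
  new("PipelineConfig", border = border, hair = hair, enhance = enhance,
      grabcut = grabcut, doBorder = doBorder, doHair = doHair,
      doEnhance = doEnhance)
}

# ---- result classes ---------------------------------------------------------

#' Corner rectangles located by the border detector
#'
#' @slot outer numeric matrix (k x 2) of extreme outer endpoint positions in
#'   0-based (row, col) order TL, TR, BR, BL (rows for corners without a dark
#'   component are omitted).
#' @slot inner integer matrix (4 x 2), 0-based inner-corner positions in row
#'   order TL, TR, BL, BR; -1 where not found.
#' @slot found logical(4), per-corner found flags (TL, TR, BL, BR).
#' @slot bordersPresent logical, TRUE when the top-left search succeeded.
#' @slot searches integer, number of corner searches actually executed (the
#'   detector exits after one failed top-left search).
#' @export
setClass("CornerRects", representation(
  outer = "matrix",
  inner = "matrix",
  found = "logical",
  bordersPresent = "logical",
  searches = "integer"
))

setMethod("show", "CornerRects", function(object) {
  cat("CornerRects: borders", if (object@bordersPresent) "present" else "absent",
      sprintf("(%d corner search%s run)\n", object@searches,
              if (object@searches == 1L) "" else "es"))
  if (object@bordersPresent) {
    lab <- c("TL", "TR", "BL", "BR")
    for (i in 1:4) {
      if (object@found[i])
        cat(sprintf("  inner %s: (%d, %d)\n", lab[i],
                    object@inner[i, 1], object@inner[i, 2]))
      else cat(sprintf("  inner %s: not found (side defaults to image edge)\n", lab[i]))
    }
  }
  invisible(NULL)
})

#' GrabCut iteration result
#'
#' @slot alpha integer matrix of per-pixel labels (0 background, 1 foreground).
#' @slot iterations integer, iterations actually run.
#' @slot energyBefore,energyAfter numeric vectors: Gibbs energy before and
#'   after each iteration's min-cut, evaluated under that iteration's mixture
#'   models.
#' @slot changedFrac numeric vector, per-iteration fraction of pixels whose
#'   label flipped.
#' @slot converged logical.
#' @slot degenerate logical, TRUE when the two mixtures collapsed to the same
#'   density and the unknown region resolved to background.
#' @export
setClass("GrabCutResult", representation(
  alpha = "matrix",
  iterations = "integer",
  energyBefore = "numeric",
  energyAfter = "numeric",
  changedFrac = "numeric",
  converged = "logical",
  degenerate = "logical"
))

setMethod("show", "GrabCutResult", function(object) {
  cat(sprintf("GrabCutResult: %d iteration(s), %s, %d foreground pixel(s)\n",
              object@iterations,
              if (object@converged) "converged" else "iteration cap reached",
              sum(object@alpha == 1L)))
  invisible(NULL)
})

#' End-to-end segmentation result
#'
#' @slot mask integer matrix in the original image frame, 255 on lesion.
#' @slot log list of stage observations: \code{bordersPresent},
#'   \code{hairsPresent}, \code{rect}, \code{offset}, \code{iterations},
#'   \code{stages}, and per-stage detail.
#' @slot config the \code{PipelineConfig} used.
#' @export
setClass("SegmentationResult", representation(
  mask = "matrix",
  log = "list",
  config = "PipelineConfig"
))

setMethod("show", "SegmentationResult", function(object) {
  lg <- object@log
  cat("SegmentationResult\n")
  cat(sprintf("  stages: %s\n", paste(lg$stages, collapse = " -> ")))
  cat(sprintf("  borders present: %s | hairs present: %s\n",
              lg$bordersPresent, lg$hairsPresent))
  cat(sprintf("  mask: %d x %d, %d lesion pixel(s)\n",
              nrow(object@mask), ncol(object@mask), sum(object@mask == 255L)))
  invisible(NULL)
})

#' @param x a \code{SegmentationResult}.
#' @return \code{lesionMask} returns the binary mask matrix (0/255) in the
#'   original image frame; \code{stageLog} returns the stage-observation list.
#' @rdname SegmentationResult-class
#' @export
lesionMask <- function(x) {
  stopifnot(is(x, "SegmentationResult"))
  x@mask
}

#' @rdname SegmentationResult-class
#' @export
stageLog <- function(x) {
  stopifnot(is(x, "SegmentationResult"))
  x@log
}
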