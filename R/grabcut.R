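# GrabCut lesion extraction. The initialization rectangle is computed
# automatically (start 5% in from the top-left, end 7% in from the
# bottom-right, truncating-integer arithmetic); pixels outside it are hard
# background, pixels inside are unknown and initially foreground. Two
# Gaussian mixtures (background / foreground) over RGB are refined by
# alternating component assignment, maximum-likelihood refit, and a graph
# min-cut whose data terms are negative mixture log-likelihoods and whose
# smoothness terms follow the standard contrast-sensitive 8-neighbor model.

#' Automatic initialization rectangle
#'
#' start = (int(h * startPct/100), int(w * startPct/100)); end = (h - int(h *
#' endPct/100), w - int(w * endPct/100)); int truncates toward zero. The
#' rectangle is half-open: start inclusive, end exclusive, 0-based.
#'
#' @param height,width image extent in pixels (each at least 20).
#' @param cfg a \code{\link{grabCutConfig}}.
#' @return list with \code{start} and \code{end}, 0-based (row, col) pairs.
#' @examples
#' autoRect(430, 430)  # start (21, 21), end (400, 400)
#' @export
autoRect <- function(height, width, cfg = grabCutConfig()) {
  if (height < 20L || width < 20L)
    stop("image must be at least 20 px in each dimension", call. = FALSE)
  start <- c(trunc(height * cfg@startPct / 100),
             trunc(width * cfg@startPct / 100))
  end <- c(height - trunc(height * cfg@endPct / 100),
           width - trunc(width * cfg@endPct / 100))
  if (any(start >= end))
    stop("degenerate initialization rectangle", call. = FALSE)
  list(start = as.integer(start), end = as.integer(end))
}

#' Initialize the tri-map
#'
#' Pixels outside the rectangle are hard background (0), pixels inside are
#' unknown (1); the hard-foreground class (2) is empty at initialization.
#'
#' @param rect rectangle from \code{\link{autoRect}}.
#' @param height,width image extent.
#' @return Integer matrix of labels 0 (background), 1 (unknown), 2
#'   (foreground).
#' @export
initTrimap <- function(rect, height, width) {
  if (any(rect$start < 0) || any(rect$end > c(height, width)) ||
      any(rect$start >= rect$end))
    stop("rectangle outside the image", call. = FALSE)
  tm <- matrix(0L, height, width)
  tm[(rect$start[1] + 1L):rect$end[1], (rect$start[2] + 1L):rect$end[2]] <- 1L
  tm
}

# ---- Gaussian mixture over RGB ---------------------------------------------

fitGmm <- function(x, assign, K) {
  comps <- vector("list", K)
  n <- nrow(x)
  for (k in seq_len(K)) {
    xi <- x[assign == k, , drop = FALSE]
    if (nrow(xi) < 4L) {
      comps[[k]] <- NULL
      next
    }
    mu <- colMeans(xi)
    sig <- stats::cov(xi) + diag(0.01, 3)  # regularize: colors are discrete
    ch <- tryCatch(chol(sig), error = function(e) {
      chol(sig + diag(1, 3))
    })
    comps[[k]] <- list(pi = nrow(xi) / n, mu = mu, chol = ch,
                       logdet = 2 * sum(log(diag(ch))))
  }
  comps <- comps[!vapply(comps, is.null, logical(1))]
  if (length(comps) == 0L) {
    # degenerate class: fall back to one regularized Gaussian over all pixels
    mu <- colMeans(x)
    sig <- diag(1, 3)
    if (nrow(x) > 1L) sig <- stats::cov(x) + diag(0.01, 3)
    ch <- chol(sig)
    comps <- list(list(pi = 1, mu = mu, chol = ch,
                       logdet = 2 * sum(log(diag(ch)))))
  }
  comps
}

# n x K matrix of per-component log pi_k + log N(x; mu_k, Sigma_k)
gmmCompLogLik <- function(x, gmm) {
  n <- nrow(x)
  out <- matrix(-Inf, n, length(gmm))
  for (k in seq_along(gmm)) {
    g <- gmm[[k]]
    d <- sweep(x, 2, g$mu)
    z <- backsolve(g$chol, t(d), transpose = TRUE)
    maha <- colSums(z^2)
    out[, k] <- log(g$pi) - 0.5 * (3 * log(2 * pi) + g$logdet + maha)
  }
  out
}

# negative mixture log-likelihood (data term)
gmmNegLogLik <- function(x, gmm) {
  ll <- gmmCompLogLik(x, gmm)
  m <- apply(ll, 1, max)
  -(m + log(rowSums(exp(ll - m))))
}

gibbsEnergy <- function(dataBg, dataFg, alphaVec, pair) {
  unary <- sum(ifelse(alphaVec == 1L, dataFg, dataBg))
  cut <- alphaVec[pair$i] != alphaVec[pair$j]
  unary + sum(pair$w[cut])
}

#' Iterative GrabCut refinement
#'
#' Alternates (a) assignment of each pixel to its most likely mixture
#' component, (b) maximum-likelihood refit of both mixtures from the current
#' labels, (c) graph construction (negative mixture log-likelihood data terms;
#' contrast-sensitive smoothness \eqn{\gamma\,\exp(-\beta\|z_p-z_q\|^2)/d(p,q)}
#' on 8-neighbors with \eqn{\beta = 1/(2\,E\|z_p-z_q\|^2)}; hard background
#' links outside the rectangle), (d) min-cut, and (e) label update on the
#' unknown region. Stops when the changed-label fraction drops below the
#' convergence tolerance or the iteration cap is hit. Mixtures are initialized
#' by seeded k-means, so results are reproducible.
#'
#' @param img h x w x 3 integer array in [0, 255].
#' @param trimap label matrix from \code{\link{initTrimap}}.
#' @param cfg a \code{\link{grabCutConfig}}.
#' @return A \code{\link{GrabCutResult-class}}.
#' @export
grabCutIterate <- function(img, trimap, cfg = grabCutConfig()) {
  assertRgb(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  stopifnot(nrow(trimap) == h, ncol(trimap) == w)
  if (!any(trimap == 1L)) stop("empty unknown region", call. = FALSE)

  n <- h * w
  x <- cbind(as.numeric(img[, , 1]), as.numeric(img[, , 2]),
             as.numeric(img[, , 3]))
  tb <- as.vector(trimap) == 0L
  tu <- !tb
  alpha <- as.integer(tu)  # unknown starts as foreground

  # contrast weight beta over all 8-neighbor pairs
  pairIdx <- function(dr, dc) {
    rs <- seq_len(h - abs(dr)); cs <- seq_len(w - abs(dc))
    r1 <- if (dr >= 0) rs else rs + abs(dr)
    c1 <- if (dc >= 0) cs else cs + abs(dc)
    i <- as.vector(outer(r1, c1 - 1L, function(r, cb) r + cb * h))
    j <- as.vector(outer(r1 + dr, c1 + dc - 1L, function(r, cb) r + cb * h))
    list(i = i, j = j)
  }
  nb <- list(pairIdx(1, 0), pairIdx(0, 1), pairIdx(1, 1), pairIdx(-1, 1))
  dist <- c(1, 1, sqrt(2), sqrt(2))
  i <- unlist(lapply(nb, `[[`, "i"))
  j <- unlist(lapply(nb, `[[`, "j"))
  dvec <- rep(dist, times = vapply(nb, function(p) length(p$i), integer(1)))
  diff2 <- rowSums((x[i, , drop = FALSE] - x[j, , drop = FALSE])^2)
  mbeta <- mean(diff2)
  beta <- if (mbeta > 0) 1 / (2 * mbeta) else 0
  pairW <- cfg@gamma * exp(-beta * diff2) / dvec
  pair <- list(i = i, j = j, w = pairW)

  kmAssign <- function(xi, K) {
    K <- min(K, nrow(unique(xi)))
    if (K <= 1L) return(rep(1L, nrow(xi)))
    km <- suppressWarnings(stats::kmeans(xi, centers = K, nstart = 1L,
                                         iter.max = 30L))
    km$cluster
  }

  K <- cfg@nComponents
  set.seed(cfg@seed)
  assign <- integer(n)
  assign[tb | alpha == 0L] <- kmAssign(x[tb | alpha == 0L, , drop = FALSE], K)
  fgSet <- alpha == 1L
  if (any(fgSet)) assign[fgSet] <- kmAssign(x[fgSet, , drop = FALSE], K)

  energyBefore <- energyAfter <- changedFrac <- numeric(0)
  converged <- FALSE
  degenerate <- FALSE
  BIG <- 1e9
  iter <- 0L

  for (it in seq_len(cfg@maxIters)) {
    iter <- it
    bgSet <- alpha == 0L
    gmmBg <- fitGmm(x[bgSet, , drop = FALSE],
                    assign[bgSet], K)
    fgSet <- alpha == 1L
    gmmFg <- if (any(fgSet))
      fitGmm(x[fgSet, , drop = FALSE], assign[fgSet], K) else list()
    if (length(gmmFg) == 0L) gmmFg <- gmmBg

    dataBg <- gmmNegLogLik(x, gmmBg)
    dataFg <- gmmNegLogLik(x, gmmFg)

    if (max(abs(dataBg - dataFg)) < 1e-9) {
      # both mixtures collapsed to the same density: unknown region resolves
      # to background, deterministically
      newAlpha <- integer(n)
      degenerate <- TRUE
      message("grabcut: mixtures degenerate; unknown region set to background")
    } else {
      # reassign components within each pixel's current class
      llBg <- gmmCompLogLik(x, gmmBg)
      llFg <- gmmCompLogLik(x, gmmFg)
      assign[alpha == 0L] <- max.col(llBg[alpha == 0L, , drop = FALSE])
      if (any(alpha == 1L))
        assign[alpha == 1L] <- max.col(llFg[alpha == 1L, , drop = FALSE])

      eBefore <- gibbsEnergy(dataBg, dataFg, alpha, pair)

      # negative log-likelihoods may dip below zero for tight mixtures; shift
      # both terminal capacities per pixel (adds a constant per pixel to every
      # cut, so the argmin is unchanged) to keep capacities non-negative
      offset <- pmin(dataBg, dataFg, 0)
      capSrc <- ifelse(tb, 0, dataBg - offset)    # cut when labeled background
      capSnk <- ifelse(tb, BIG, dataFg - offset)  # cut when labeled foreground
      src <- n + 1L; snk <- n + 2L
      from <- c(rep(src, n), 1:n, pair$i)
      to <- c(1:n, rep(snk, n), pair$j)
      caps <- c(capSrc, capSnk, pair$w)
      keep <- caps > 0
      side <- .dinicMinCut(from[keep], to[keep], caps[keep],
                           n + 2L, src, snk)
      newAlpha <- as.integer(side[1:n])  # source side = foreground
      newAlpha[tb] <- 0L
      eAfter <- gibbsEnergy(dataBg, dataFg, newAlpha, pair)
      energyBefore <- c(energyBefore, eBefore)
      energyAfter <- c(energyAfter, eAfter)
    }

    ch <- mean(newAlpha != alpha)
    changedFrac <- c(changedFrac, ch)
    alpha <- newAlpha
    if (degenerate) { converged <- TRUE; break }
    if (ch < cfg@convergenceTol) { converged <- TRUE; break }
  }

  new("GrabCutResult", alpha = matrix(alpha, h, w), iterations = iter,
      energyBefore = energyBefore, energyAfter = energyAfter,
      changedFrac = changedFrac, converged = converged,
      degenerate = degenerate)
}

#' Segment the lesion
#'
#' Automatic rectangle, tri-map initialization and GrabCut refinement; the
#' mask is 255 where the final label is foreground. Foreground can never
#' escape the rectangle because outside pixels are hard background.
#'
#' @param img h x w x 3 integer array in [0, 255] (typically post-enhancement).
#' @param cfg a \code{\link{grabCutConfig}}.
#' @param details if TRUE, return a list with the mask, the rectangle and the
#'   \code{GrabCutResult}; otherwise just the mask.
#' @return 0/255 integer matrix, or a list when \code{details = TRUE}.
#' @export
segmentLesion <- function(img, cfg = grabCutConfig(), details = FALSE) {
  assertRgb(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  rect <- autoRect(h, w, cfg)
  trimap <- initTrimap(rect, h, w)
  res <- grabCutIterate(img, trimap, cfg)
  mask <- matrix(ifelse(res@alpha == 1L, 255L, 0L), h, w)
  if (details) list(mask = mask, rect = rect, result = res) else mask
}
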