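# Mask scoring: pixelwise confusion counts feed the Jaccard index
# TP/(TP+FP+FN) and the Dice index 2TP/((FP+TP)+(TP+FN)); batch evaluation
# emits a CSV report with per-image rows and mean summary rows.

#' Pixelwise confusion counts
#'
#' 255 marks lesion, 0 non-lesion, in both masks.
#'
#' @param pred,truth 0/255 matrices of identical dimensions.
#' @return list with integer \code{TP}, \code{FP}, \code{FN}, \code{TN}
#'   (TN is tracked so accuracy-style metrics can be added without re-reading
#'   masks).
#' @export
confusionCounts <- function(pred, truth) {
  assertMask(pred, "pred")
  assertMask(truth, "truth")
  if (!identical(dim(pred), dim(truth)))
    stop("pred and truth dimensions differ", call. = FALSE)
  p <- pred == 255
  t <- truth == 255
  list(TP = sum(p & t), FP = sum(p & !t), FN = sum(!p & t), TN = sum(!p & !t))
}

bothEmptyValue <- function(emptyAs, what) {
  if (emptyAs == "one") {
    warning("both masks empty; ", what, " reported as 1", call. = FALSE)
    1
  } else NaN
}

#' Jaccard and Dice overlap indices
#'
#' Jaccard = TP/(TP+FP+FN); Dice = 2TP/((FP+TP)+(TP+FN)). They obey the
#' identity J = D/(2-D). Undefined when TP = FP = FN = 0 (both masks empty);
#' by default that case reports 1 with a warning so negative controls do not
#' abort batch runs, or NaN with \code{emptyAs = "nan"}.
#'
#' @param counts list from \code{\link{confusionCounts}}.
#' @param emptyAs "one" (default) or "nan".
#' @return Scalar in [0, 1] (or NaN).
#' @export
jaccardIndex <- function(counts, emptyAs = c("one", "nan")) {
  emptyAs <- match.arg(emptyAs)
  d <- counts$TP + counts$FP + counts$FN
  if (d == 0) return(bothEmptyValue(emptyAs, "jaccard"))
  counts$TP / d
}

#' @rdname jaccardIndex
#' @export
diceIndex <- function(counts, emptyAs = c("one", "nan")) {
  emptyAs <- match.arg(emptyAs)
  d <- (counts$FP + counts$TP) + (counts$TP + counts$FN)
  if (d == 0) return(bothEmptyValue(emptyAs, "dice"))
  2 * counts$TP / d
}

#' Batch mask evaluation
#'
#' Scores each (prediction, truth) pair and appends mean rows. Unreadable or
#' shape-mismatched pairs are reported in the \code{error} column and excluded
#' from the means. Rows are ordered by image id.
#'
#' @param pred character vector of prediction mask paths (or a list of
#'   matrices).
#' @param truth character vector of ground-truth mask paths (or a list of
#'   matrices), parallel to \code{pred}.
#' @param ids image identifiers; defaults to prediction file names.
#' @param reportPath optional CSV output path.
#' @return data.frame with columns \code{image_id}, \code{jaccard},
#'   \code{dice}, \code{error}; the final rows are \code{mean_jaccard} and
#'   \code{mean_dice}.
#' @export
evaluateBatch <- function(pred, truth, ids = NULL, reportPath = NULL) {
  stopifnot(length(pred) == length(truth))
  if (length(pred) == 0L) {
    rep0 <- data.frame(image_id = character(0), jaccard = numeric(0),
                       dice = numeric(0), error = character(0))
    if (!is.null(reportPath)) utils::write.csv(rep0, reportPath,
                                               row.names = FALSE)
    return(rep0)
  }
  if (is.null(ids)) {
    ids <- if (is.character(pred)) basename(unlist(pred))
           else sprintf("image_%03d", seq_along(pred))
  }
  rows <- data.frame(image_id = as.character(ids), jaccard = NA_real_,
                     dice = NA_real_, error = "", stringsAsFactors = FALSE)
  getMask <- function(x) if (is.character(x)) readMaskImage(x) else x
  for (k in seq_along(pred)) {
    res <- tryCatch({
      cc <- confusionCounts(getMask(pred[[k]]), getMask(truth[[k]]))
      c(jaccardIndex(cc), diceIndex(cc))
    }, error = function(e) e, warning = function(w) {
      cc <- suppressWarnings(confusionCounts(getMask(pred[[k]]),
                                             getMask(truth[[k]])))
      suppressWarnings(c(jaccardIndex(cc), diceIndex(cc)))
    })
    if (inherits(res, "error")) {
      rows$error[k] <- conditionMessage(res)
    } else {
      rows$jaccard[k] <- res[1]
      rows$dice[k] <- res[2]
    }
  }
  rows <- rows[order(rows$image_id), , drop = FALSE]
  ok <- rows$error == ""
  if (nrow(rows) > 0 && any(ok)) {
    rows <- rbind(rows,
      data.frame(image_id = "mean_jaccard", jaccard = mean(rows$jaccard[ok]),
                 dice = NA_real_, error = ""),
      data.frame(image_id = "mean_dice", jaccard = NA_real_,
                 dice = mean(rows$dice[ok]), error = ""))
  }
  rownames(rows) <- NULL
  if (!is.null(reportPath))
    utils::write.csv(rows, reportPath, row.names = FALSE)
  rows
}
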