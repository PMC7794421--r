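# Assembly of patch predictions into whole-slide masks and computation of
# dice, precision, recall, F1 and accuracy.

#' Assemble per-cell patch labels into a whole-slide binary mask
#'
#' Each patchSize x patchSize block of the output is all-1 iff its grid
#' cell is labelled tumor.
#'
#' @param grid a \linkS4class{TileGrid}.
#' @param labels character vector of per-cell predictions ("tumor" /
#'   "non_tumor"), ordered like \code{gridCells(grid)}, or a data.frame
#'   with a \code{label} column (e.g. the output of
#'   \code{\link{predictPatches}}).
#' @return a \linkS4class{MaskImage} of the tiled dimensions.
#' @export
assembleMask <- function(grid, labels) {
  if (is.data.frame(labels)) labels <- labels$label
  cells <- grid@cells
  if (length(labels) != nrow(cells)) {
    have <- seq_len(min(length(labels), nrow(cells)))
    missing <- setdiff(seq_len(nrow(cells)), have)[1]
    stop("missing prediction for cell (", cells[missing, "row"], ", ",
         cells[missing, "col"], ")")
  }
  ps <- grid@patchSize
  m <- matrix(0L, grid@nRows * ps, grid@nCols * ps)
  tumor <- which(labels == "tumor")
  for (i in tumor) {
    r0 <- cells[i, "row"] * ps
    c0 <- cells[i, "col"] * ps
    m[(r0 + 1L):(r0 + ps), (c0 + 1L):(c0 + ps)] <- 1L
  }
  maskImage(m, slideId = grid@slideId, magnification = "20x")
}

#' Block-quantize a ground-truth mask to the tile grid
#'
#' Applies the patch labelling rule per grid cell and re-expands to pixel
#' resolution: the mask a perfect patch classifier would assemble. Used for
#' pipeline self-tests.
#'
#' @param mask a \linkS4class{MaskImage}.
#' @param grid a \linkS4class{TileGrid} over the same slide.
#' @param threshold tumor coverage threshold of the labelling rule.
#' @return a \linkS4class{MaskImage} of the tiled dimensions.
#' @export
blockQuantizeMask <- function(mask, grid, threshold = 0.30) {
  ps <- grid@patchSize
  cells <- grid@cells
  labels <- character(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    r0 <- cells[i, "row"] * ps
    c0 <- cells[i, "col"] * ps
    labels[i] <- labelPatch(mask@pixels[(r0 + 1L):(r0 + ps),
                                        (c0 + 1L):(c0 + ps)],
                            threshold)$label
  }
  assembleMask(grid, labels)
}

#' Dice similarity between two binary masks
#'
#' \eqn{2|A \cap B| / (|A| + |B|)}. Two empty masks are defined to have
#' dice 1 (perfect-agreement limit).
#'
#' @param a,b \linkS4class{MaskImage}s or binary matrices of equal shape.
#' @return scalar in [0, 1].
#' @export
dice <- function(a, b) {
  ma <- if (is(a, "MaskImage")) a@pixels else a
  mb <- if (is(b, "MaskImage")) b@pixels else b
  if (!identical(dim(ma), dim(mb))) stop("dice: shape mismatch")
  sa <- sum(ma)
  sb <- sum(mb)
  if (sa + sb == 0) return(1)
  2 * sum(ma * mb) / (sa + sb)
}

#' Per-class precision/recall/F1, accuracy and confusion counts
#'
#' Precision = TP/(TP+FP), recall = TP/(TP+FN), F1 their harmonic mean,
#' computed for each class in turn; accuracy = (TP+TN)/total. A ratio with
#' zero denominator is reported as 0 and flagged.
#'
#' @param trueLabels,predLabels character vectors ("tumor"/"non_tumor") of
#'   equal length.
#' @param maskDice optional dice value of assembled masks to carry in the
#'   report.
#' @return a \linkS4class{MetricsReport}
#' @export
classificationReport <- function(trueLabels, predLabels,
                                 maskDice = NA_real_) {
  if (length(trueLabels) == 0L) stop("empty input")
  if (length(trueLabels) != length(predLabels))
    stop("label vectors must have equal length")
  classes <- c("non_tumor", "tumor")
  conf <- table(factor(trueLabels, classes), factor(predLabels, classes))
  perClass <- do.call(rbind, lapply(classes, function(cl) {
    tp <- conf[cl, cl]
    fp <- sum(conf[, cl]) - tp
    fn <- sum(conf[cl, ]) - tp
    flagged <- FALSE
    prec <- if (tp + fp > 0) tp / (tp + fp) else { flagged <- TRUE; 0 }
    rec <- if (tp + fn > 0) tp / (tp + fn) else { flagged <- TRUE; 0 }
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else {
      flagged <- TRUE; 0
    }
    data.frame(class = cl, precision = prec, recall = rec, f1 = f1,
               flagged = flagged, stringsAsFactors = FALSE)
  }))
  rownames(perClass) <- classes
  new("MetricsReport", perClass = perClass,
      accuracy = sum(diag(conf)) / length(trueLabels),
      confusion = unclass(conf), dice = maskDice)
}

#' Evaluate a predicted whole-slide mask against the ground truth
#'
#' Dice is computed against the original ground-truth mask by default,
#' matching slide-level evaluation; set \code{blockQuantized = TRUE} to
#' compare against the block-quantized truth (pipeline self-test). When a
#' grid is supplied the per-patch labels of both masks are also compared
#' for the classification metrics.
#'
#' @param predMask predicted \linkS4class{MaskImage}.
#' @param trueMask ground-truth \linkS4class{MaskImage}.
#' @param grid optional \linkS4class{TileGrid}; enables per-patch metrics
#'   and block quantization.
#' @param blockQuantized compare against the block-quantized truth.
#' @param threshold patch labelling threshold.
#' @return a \linkS4class{MetricsReport}
#' @export
evaluateMask <- function(predMask, trueMask, grid = NULL,
                         blockQuantized = FALSE, threshold = 0.30) {
  ref <- trueMask
  if (!is.null(grid) && blockQuantized)
    ref <- blockQuantizeMask(trueMask, grid, threshold)
  tp <- predMask@pixels
  rp <- ref@pixels
  if (!identical(dim(tp), dim(rp))) {
    # predicted mask covers the tiled region only; crop the reference
    rp <- rp[seq_len(nrow(tp)), seq_len(ncol(tp))]
  }
  d <- dice(tp, rp)
  if (is.null(grid)) {
    lab <- function(m) ifelse(m > 0, "tumor", "non_tumor")
    return(classificationReport(lab(as.vector(rp)), lab(as.vector(tp)),
                                maskDice = d))
  }
  ps <- grid@patchSize
  cellLab <- function(m) {
    vapply(seq_len(nrow(grid@cells)), function(i) {
      r0 <- grid@cells[i, "row"] * ps
      c0 <- grid@cells[i, "col"] * ps
      labelPatch(m[(r0 + 1L):(r0 + ps), (c0 + 1L):(c0 + ps)],
                 threshold)$label
    }, character(1))
  }
  classificationReport(cellLab(rp), cellLab(tp), maskDice = d)
}
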