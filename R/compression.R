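# Gigapixel slide compression: the spatially arranged grid of bottleneck
# encodings stands in for the pixel data at 1/12 the element count.

#' Compress a slide into its grid of bottleneck feature maps
#'
#' The slide is tiled by the \code{\link{tileSlide}} contract and each
#' patch p_ij is encoded independently; cell (i, j) of the result holds
#' exactly encode(p_ij). For 256 x 256 x 3 patches and 16 x 16 x 64
#' feature maps the per-patch element-count ratio is 196608 / 16384 = 12.
#'
#' @param slide a \linkS4class{SlideImage}.
#' @param model a trained \linkS4class{CAEModel} (its encoder is used).
#' @param patchSize patch edge length; defaults to the model's input size.
#' @return a \linkS4class{CompressedSlide}
#' @export
compressSlide <- function(slide, model, patchSize = model@spec$inputSize) {
  if (patchSize != model@spec$inputSize)
    stop("patchSize must equal the model input size (",
         model@spec$inputSize, ")")
  tiled <- tileSlide(slide, patchSize = patchSize)
  if (nrow(tiled$grid@cells) == 0L)
    stop("slide smaller than one patch; nothing to compress")
  feats <- encodePatches(model, tiled$patches)
  new("CompressedSlide", slideId = slide@slideId,
      nRows = tiled$grid@nRows, nCols = tiled$grid@nCols,
      patchSize = as.integer(patchSize),
      magnification = slide@magnification,
      features = feats,
      fingerprint = .encoderFingerprint(model@spec))
}

#' Reconstruct a slide from its compressed representation
#'
#' Each feature map is decoded and the patches are stitched back with the
#' original tiling geometry. When the original slide is supplied, the
#' report lists the per-patch SSIM between original and reconstruction.
#'
#' @param comp a \linkS4class{CompressedSlide}.
#' @param model the \linkS4class{CAEModel} whose encoder produced the maps
#'   (fingerprints must match).
#' @param original optional original \linkS4class{SlideImage} for the SSIM
#'   report.
#' @param ssimCfg an \linkS4class{SSIMConfig} for the report.
#' @return list with elements \code{slide} (reconstructed
#'   \linkS4class{SlideImage} over the tiled region) and \code{report}
#'   (data.frame with one row per cell: row, col, ssim — NA without
#'   originals).
#' @export
reconstructSlide <- function(comp, model, original = NULL,
                             ssimCfg = ssimConfig()) {
  fp <- .encoderFingerprint(model@spec)
  if (!identical(fp, comp@fingerprint))
    stop("model fingerprint ", fp, " does not match the compressed slide (",
         comp@fingerprint, ")")
  ps <- comp@patchSize
  Z <- nnStack(comp@features)
  Y <- nnPredictChunked(model@decoder, Z)
  recon <- nnUnstack(Y, ps, ps, 3L)
  out <- array(0, c(comp@nRows * ps, comp@nCols * ps, 3L))
  n <- length(recon)
  rows <- rep(0:(comp@nRows - 1L), times = comp@nCols)
  cols <- rep(0:(comp@nCols - 1L), each = comp@nRows)
  ord <- order(rows, cols)  # row-major, matching tileSlide cell order
  rows <- rows[ord]; cols <- cols[ord]
  svals <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    r0 <- rows[i] * ps
    c0 <- cols[i] * ps
    out[(r0 + 1L):(r0 + ps), (c0 + 1L):(c0 + ps), ] <- recon[[i]]
    if (!is.null(original)) {
      orig <- original@pixels[(r0 + 1L):(r0 + ps), (c0 + 1L):(c0 + ps), ,
                              drop = FALSE]
      svals[i] <- ssim(orig, recon[[i]], ssimCfg)
    }
  }
  list(slide = slideImage(pmin(pmax(out, 0), 1), slideId = comp@slideId,
                          magnification = comp@magnification),
       report = data.frame(row = rows, col = cols, ssim = svals))
}

#' Element-count compression ratio of a CompressedSlide
#'
#' Ratio of tiled pixel elements to stored feature elements; 12 for the
#' reference 256 -> 16 x 16 x 64 configuration, independent of content.
#'
#' @param comp a \linkS4class{CompressedSlide}.
#' @return numeric scalar.
#' @export
compressionRatio <- function(comp) {
  pixelElems <- as.numeric(comp@patchSize)^2 * 3
  featElems <- prod(dim(comp@features[[1]]))
  pixelElems / featElems
}

#' Write/read a CompressedSlide
#'
#' Serialized with R's native format; cells remain indexed by (row, col)
#' through the grid dimensions.
#'
#' @param comp a \linkS4class{CompressedSlide}.
#' @param path file path (conventionally .rds).
#' @return \code{writeCompressedSlide}: the path, invisibly;
#'   \code{readCompressedSlide}: the \linkS4class{CompressedSlide}.
#' @export
writeCompressedSlide <- function(comp, path) {
  saveRDS(comp, path)
  invisible(path)
}

#' @rdname writeCompressedSlide
#' @export
readCompressedSlide <- function(path) {
  obj <- readRDS(path)
  stopifnot(is(obj, "CompressedSlide"))
  obj
}
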