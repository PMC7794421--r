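# User-facing constructors for the value classes, plus show() methods.

#' Construct a SlideImage
#'
#' @param pixels H x W x 3 numeric array in [0, 1], or an H x W matrix that
#'   is replicated over three channels.
#' @param slideId slide identifier.
#' @param magnification one of "5x", "10x", "20x".
#' @return a \linkS4class{SlideImage}
#' @export
slideImage <- function(pixels, slideId = "slide", magnification = "20x") {
  if (is.matrix(pixels))
    pixels <- array(rep(pixels, 3L), c(dim(pixels), 3L))
  new("SlideImage", pixels = pixels, slideId = slideId,
      magnification = magnification)
}

#' Construct a MaskImage
#'
#' @param pixels H x W binary matrix (1 = viable tumor).
#' @param slideId slide identifier.
#' @param magnification one of "5x", "10x", "20x".
#' @return a \linkS4class{MaskImage}
#' @export
maskImage <- function(pixels, slideId = "slide", magnification = "20x") {
  storage.mode(pixels) <- "integer"
  new("MaskImage", pixels = pixels, slideId = slideId,
      magnification = magnification)
}

#' Construct an SSIMConfig
#'
#' @param windowSize odd window edge length, pixels.
#' @param windowKind "gaussian" or "uniform".
#' @param gaussianSigma Gaussian window standard deviation, pixels.
#' @param dynamicRange dynamic range L of the intensities.
#' @param k1,k2 stabiliser coefficients.
#' @param expL,expC,expS component exponents.
#' @param channelMode "per_channel_mean" or "luma".
#' @return an \linkS4class{SSIMConfig}
#' @export
ssimConfig <- function(windowSize = 11L, windowKind = "gaussian",
                       gaussianSigma = 1.5, dynamicRange = 1,
                       k1 = 0.01, k2 = 0.03,
                       expL = 1, expC = 1, expS = 1,
                       channelMode = "per_channel_mean") {
  new("SSIMConfig", windowSize = as.integer(windowSize),
      windowKind = windowKind, gaussianSigma = gaussianSigma,
      dynamicRange = dynamicRange, k1 = k1, k2 = k2,
      expL = expL, expC = expC, expS = expS, channelMode = channelMode)
}

#' Construct a LossConfig
#'
#' @param alpha,beta,gamma nonnegative weights of the MSE, SSIM-loss and MAE
#'   terms (defaults 0.5 each).
#' @param mseMode "per_pixel_mean" (training default) or "literal_sum"
#'   (the raw double-sum form).
#' @param ssim an \linkS4class{SSIMConfig}.
#' @return a \linkS4class{LossConfig}
#' @export
lossConfig <- function(alpha = 0.5, beta = 0.5, gamma = 0.5,
                       mseMode = "per_pixel_mean", ssim = ssimConfig()) {
  new("LossConfig", alpha = alpha, beta = beta, gamma = gamma,
      mseMode = mseMode, ssim = ssim)
}

#' Construct a TrainConfig
#'
#' The slide-scale defaults follow the reference protocol: 200 epochs,
#' batch 64, ADAM with learning rate 1e-4 and beta1 = 0.05, dropout 0.7,
#' five-fold cross-validation, flip/rotation augmentation. Desk-scale runs
#' typically override \code{epochs} and \code{learningRate}.
#'
#' @param epochs,batchSize training schedule.
#' @param learningRate,beta1,beta2 ADAM settings.
#' @param dropoutRate dropout probability for fully connected layers.
#' @param augment apply random 90-degree rotations and flips.
#' @param cvFolds number of cross-validation folds.
#' @param seed integer seed for all randomness.
#' @param mrLossWeights named weights (reconstruction, classification) for
#'   multi-task multi-resolution training.
#' @return a \linkS4class{TrainConfig}
#' @export
trainConfig <- function(epochs = 200L, batchSize = 64L,
                        learningRate = 1e-4, beta1 = 0.05, beta2 = 0.999,
                        dropoutRate = 0.7, augment = TRUE, cvFolds = 5L,
                        seed = 1L,
                        mrLossWeights = c(reconstruction = 1,
                                          classification = 1)) {
  new("TrainConfig", epochs = as.integer(epochs),
      batchSize = as.integer(batchSize), learningRate = learningRate,
      beta1 = beta1, beta2 = beta2, dropoutRate = dropoutRate,
      augment = augment, cvFolds = as.integer(cvFolds),
      seed = as.integer(seed), mrLossWeights = mrLossWeights)
}

#' Construct a SynthSpec
#'
#' Defaults describe the desk-scale study fixture: a 2048 x 2048 20x slide
#' (a 64 x 64 grid of 32-pixel patches), target tumor fraction 0.30, and a
#' tissue/tumor texture gap wide enough that the two classes are separable
#' by construction.
#'
#' @param seed integer seed.
#' @param dims slide edge length at 20x, pixels.
#' @param nBlobs maximum number of tumor blobs.
#' @param radiusRange blob radius range at 20x, pixels; defaults to
#'   \code{dims * c(0.04, 0.107)} (80--220 px on the default 2048 slide) so
#'   blob geometry scales with slide size.
#' @param tumorFraction target tumor area fraction in (0, 1).
#' @param tissueColor,tumorColor base RGB triples.
#' @param noiseAmp additive noise amplitude.
#' @param patchSize patch edge length, pixels.
#' @return a \linkS4class{SynthSpec}
#' @export
synthSpec <- function(seed = 7L, dims = 2048L, nBlobs = 40L,
                      radiusRange = NULL, tumorFraction = 0.30,
                      tissueColor = c(0.85, 0.72, 0.82),
                      tumorColor = c(0.52, 0.40, 0.62),
                      noiseAmp = 0.06, patchSize = 32L) {
  if (is.null(radiusRange)) radiusRange <- dims * c(0.04, 0.107)
  new("SynthSpec", seed = as.integer(seed), dims = as.integer(dims),
      nBlobs = as.integer(nBlobs), radiusRange = radiusRange,
      tumorFraction = tumorFraction, tissueColor = tissueColor,
      tumorColor = tumorColor, noiseAmp = noiseAmp,
      patchSize = as.integer(patchSize))
}

setMethod("show", "SlideImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("SlideImage '%s' (%s): %d x %d x %d, range [%.3f, %.3f]\n",
              object@slideId, object@magnification, d[1], d[2], d[3],
              min(object@pixels), max(object@pixels)))
})

setMethod("show", "MaskImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("MaskImage '%s' (%s): %d x %d, tumor fraction %.3f\n",
              object@slideId, object@magnification, d[1], d[2],
              mean(object@pixels)))
})

setMethod("show", "TileGrid", function(object) {
  cat(sprintf(
    "TileGrid '%s': %d x %d cells, patch %d px, stride %d px\n",
    object@slideId, object@nRows, object@nCols, object@patchSize,
    object@stride))
})

setMethod("show", "PatchSet", function(object) {
  cat(sprintf("PatchSet: %d patches of %d px\n", length(object@pixels),
              object@patchSize))
  if (nrow(object@info) > 0L) print(table(object@info$label))
})

setMethod("show", "CompressedSlide", function(object) {
  d <- dim(object@features[[1]])
  cat(sprintf(
    "CompressedSlide '%s': %d x %d cells of %s features (patch %d px)\n",
    object@slideId, object@nRows, object@nCols,
    paste(d, collapse = " x "), object@patchSize))
})

setMethod("show", "MetricsReport", function(object) {
  cat("MetricsReport\n")
  cat(sprintf("  accuracy: %.4f\n", object@accuracy))
  if (!is.na(object@dice)) cat(sprintf("  dice:     %.4f\n", object@dice))
  print(round(object@perClass[, c("precision", "recall", "f1")], 4))
})

# ---- accessors -------------------------------------------------------------

#' Pixel data of a slide or mask
#' @param x a SlideImage or MaskImage
#' @return the pixel array/matrix
#' @export
pixels <- function(x) x@pixels

#' Patch metadata table of a PatchSet
#' @param x a PatchSet
#' @return data.frame of per-patch metadata
#' @export
patchInfo <- function(x) x@info

#' Occupied cells of a TileGrid
#' @param x a TileGrid
#' @return integer matrix of 0-based (row, col) positions
#' @export
gridCells <- function(x) x@cells

#' Grid dimensions of a TileGrid or CompressedSlide
#' @param x a TileGrid or CompressedSlide
#' @return integer (nRows, nCols)
#' @export
gridDims <- function(x) c(x@nRows, x@nCols)

#' Per-class metric table of a MetricsReport
#' @param x a MetricsReport
#' @return data.frame with precision, recall, f1 per class
#' @export
perClassMetrics <- function(x) x@perClass

#' Overall accuracy of a MetricsReport
#' @param x a MetricsReport
#' @return numeric scalar
#' @export
accuracy <- function(x) x@accuracy
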