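#' @import methods
#' @importFrom stats rnorm runif sd var
#' @importFrom utils read.csv write.csv head
NULL

.MAGNIFICATIONS <- c("5x", "10x", "20x")

#' SlideImage: an RGB slide (or pyramid level) with intensities in [0, 1]
#'
#' Container for one magnification level of a (possibly gigapixel) slide.
#' Pixels are stored as an H x W x 3 numeric array normalised to [0, 1]
#' regardless of the source bit depth, so that reconstruction losses operate
#' on a fixed dynamic range.
#'
#' @slot pixels numeric H x W x 3 array, values in [0, 1].
#' @slot slideId character scalar identifying the slide.
#' @slot magnification one of "5x", "10x", "20x".
#' @export
setClass("SlideImage",
  representation(pixels = "array", slideId = "character",
                 magnification = "character"))

setValidity("SlideImage", function(object) {
  p <- object@pixels
  if (length(dim(p)) != 3L || dim(p)[3] != 3L)
    return("pixels must be an H x W x 3 array")
  if (dim(p)[1] < 1L || dim(p)[2] < 1L) return("empty image")
  rng <- range(p)
  if (rng[1] < 0 || rng[2] > 1) return("intensities must lie in [0, 1]")
  if (!object@magnification %in% .MAGNIFICATIONS)
    return("magnification must be one of 5x/10x/20x")
  TRUE
})

#' MaskImage: a binary viable-tumor mask aligned with a SlideImage
#'
#' @slot pixels integer/numeric H x W matrix with values in {0, 1}
#'   (1 = viable tumor).
#' @slot slideId character scalar.
#' @slot magnification one of "5x", "10x", "20x".
#' @export
setClass("MaskImage",
  representation(pixels = "matrix", slideId = "character",
                 magnification = "character"))

setValidity("MaskImage", function(object) {
  p <- object@pixels
  if (!all(p %in% c(0, 1))) return("mask values must be 0/1")
  if (!object@magnification %in% .MAGNIFICATIONS)
    return("magnification must be one of 5x/10x/20x")
  TRUE
})

#' TileGrid: the uniform non-overlapping patch grid over a slide
#'
#' Cells are (row, col) positions, 0-based, row-major, top-left origin;
#' every cell corresponds to a patch fully contained in the slide (border
#' strips narrower than \code{patchSize} are dropped).
#'
#' @slot slideId character scalar.
#' @slot patchSize patch edge length in pixels.
#' @slot stride grid stride in pixels; equal to \code{patchSize}.
#' @slot nRows,nCols grid dimensions.
#' @slot cells integer matrix with columns \code{row}, \code{col} (0-based).
#' @export
setClass("TileGrid",
  representation(slideId = "character", patchSize = "integer",
                 stride = "integer", nRows = "integer", nCols = "integer",
                 cells = "matrix"))

setValidity("TileGrid", function(object) {
  if (object@stride != object@patchSize)
    return("stride must equal patchSize (non-overlapping tiling)")
  if (nrow(object@cells) != object@nRows * object@nCols)
    return("cells must enumerate the full nRows x nCols grid")
  TRUE
})

#' PatchSet: a collection of patches with grid positions and labels
#'
#' @slot pixels list of patchSize x patchSize x 3 arrays in [0, 1].
#' @slot info data.frame with columns slideId, row, col, magnification,
#'   tumorFraction, label (one of "tumor", "non_tumor", "unlabeled").
#' @slot patchSize patch edge length in pixels.
#' @export
setClass("PatchSet",
  representation(pixels = "list", info = "data.frame", patchSize = "integer"))

setValidity("PatchSet", function(object) {
  if (length(object@pixels) != nrow(object@info))
    return("one info row per patch required")
  need <- c("slideId", "row", "col", "magnification", "tumorFraction", "label")
  if (!all(need %in% names(object@info)))
    return(paste("info must have columns:", paste(need, collapse = ", ")))
  if (!all(object@info$label %in% c("tumor", "non_tumor", "unlabeled")))
    return("labels must be tumor/non_tumor/unlabeled")
  tf <- object@info$tumorFraction
  if (any(!is.na(tf) & (tf < 0 | tf > 1)))
    return("tumorFraction must lie in [0, 1]")
  TRUE
})

#' MultiResSample: co-registered 5x/10x/20x patches at one location
#'
#' The three patches share one pixel size and are centered at the same
#' physical location; the 10x (5x) center is the 20x center divided by
#' 2 (4), rounded toward zero.
#'
#' @slot pixels named list of three patch arrays ("5x", "10x", "20x").
#' @slot center integer (x, y) center coordinate at 20x.
#' @slot label label taken at 20x.
#' @slot info data.frame with per-magnification label and tumorFraction.
#' @export
setClass("MultiResSample",
  representation(pixels = "list", center = "integer", label = "character",
                 info = "data.frame"))

setValidity("MultiResSample", function(object) {
  if (!identical(sort(names(object@pixels)), sort(.MAGNIFICATIONS)))
    return("pixels must be a named list with elements 5x, 10x, 20x")
  sz <- vapply(object@pixels, function(p) dim(p)[1], integer(1))
  if (length(unique(sz)) != 1L)
    return("all three patches must share one patch size")
  TRUE
})

#' CompressedSlide: grid of bottleneck feature maps representing a slide
#'
#' Each occupied tile of the source slide is represented by the encoder's
#' bottleneck feature map (16 x 16 x 64 for 256 x 256 x 3 patches), arranged
#' by the original grid so cell (i, j) encodes patch (i, j). The element
#' count is 1/12 of the tiled pixel count.
#'
#' @slot slideId character scalar.
#' @slot nRows,nCols grid dimensions.
#' @slot patchSize source patch edge length in pixels.
#' @slot magnification source magnification.
#' @slot features list of feature-map arrays, row-major by grid cell.
#' @slot fingerprint character fingerprint of the encoder spec that
#'   produced the maps; checked against the decoder at reconstruction.
#' @export
setClass("CompressedSlide",
  representation(slideId = "character", nRows = "integer", nCols = "integer",
                 patchSize = "integer", magnification = "character",
                 features = "list", fingerprint = "character"))

setValidity("CompressedSlide", function(object) {
  if (length(object@features) != object@nRows * object@nCols)
    return("features must hold one map per grid cell")
  d <- lapply(object@features, dim)
  if (length(unique(d)) != 1L) return("all feature maps must share one shape")
  TRUE
})

#' MetricsReport: per-class classification metrics and mask dice
#'
#' @slot perClass data.frame with rows non_tumor/tumor and columns
#'   precision, recall, f1, flagged (TRUE when a zero denominator was
#'   reported as 0).
#' @slot accuracy overall accuracy in [0, 1].
#' @slot confusion 2 x 2 table of counts (true x predicted).
#' @slot dice dice similarity of assembled masks, or NA when no masks were
#'   compared.
#' @export
setClass("MetricsReport",
  representation(perClass = "data.frame", accuracy = "numeric",
                 confusion = "matrix", dice = "numeric"))

setValidity("MetricsReport", function(object) {
  if (object@accuracy < 0 || object@accuracy > 1)
    return("accuracy must lie in [0, 1]")
  if (!is.na(object@dice) && (object@dice < 0 || object@dice > 1))
    return("dice must lie in [0, 1]")
  TRUE
})

# ---- configuration value classes -------------------------------------------

#' SSIMConfig: parameters of the structural similarity index
#'
#' Defaults follow the standard reference parameterisation: 11 x 11 Gaussian
#' window with sigma 1.5, k1 = 0.01, k2 = 0.03, dynamic range L = 1 (images
#' are stored in [0, 1]), unit exponents, per-channel SSIM averaged over RGB.
#'
#' @slot windowSize odd window edge length >= 3.
#' @slot windowKind "gaussian" or "uniform".
#' @slot gaussianSigma standard deviation of the Gaussian window, pixels.
#' @slot dynamicRange dynamic range L of the intensities.
#' @slot k1,k2 stabiliser coefficients; C1 = (k1 L)^2, C2 = (k2 L)^2,
#'   C3 = C2 / 2.
#' @slot expL,expC,expS exponents of the luminance, contrast and structure
#'   comparison terms.
#' @slot channelMode "per_channel_mean" (SSIM per RGB channel, averaged) or
#'   "luma" (SSIM of the luma image).
#' @export
setClass("SSIMConfig",
  representation(windowSize = "integer", windowKind = "character",
                 gaussianSigma = "numeric", dynamicRange = "numeric",
                 k1 = "numeric", k2 = "numeric",
                 expL = "numeric", expC = "numeric", expS = "numeric",
                 channelMode = "character"))

setValidity("SSIMConfig", function(object) {
  if (object@windowSize < 3L || object@windowSize %% 2L == 0L)
    return("windowSize must be odd and >= 3")
  if (object@dynamicRange <= 0) return("dynamicRange must be > 0")
  if (object@k1 <= 0 || object@k2 <= 0) return("k1, k2 must be > 0")
  if (!object@windowKind %in% c("gaussian", "uniform"))
    return("windowKind must be gaussian or uniform")
  if (!object@channelMode %in% c("per_channel_mean", "luma"))
    return("channelMode must be per_channel_mean or luma")
  TRUE
})

#' LossConfig: weights of the joint reconstruction loss
#'
#' The joint reconstruction loss is
#' \deqn{l_R = \alpha\, l_{MSE} + \beta\, l_{SSIM} + \gamma\, l_{MAE}}
#' with default weights \eqn{\alpha = \beta = \gamma = 0.5}. Zeroing weights
#' expresses the seven single/pairwise/triple loss variants. \code{mseMode}
#' selects between the raw double-sum form of the MSE and its per-pixel
#' mean; training defaults to the per-pixel mean so the three terms stay on
#' commensurate scales.
#'
#' @slot alpha,beta,gamma nonnegative weights for the MSE, SSIM-loss and MAE
#'   terms; not all zero.
#' @slot mseMode "per_pixel_mean" or "literal_sum".
#' @slot ssim an \linkS4class{SSIMConfig}.
#' @export
setClass("LossConfig",
  representation(alpha = "numeric", beta = "numeric", gamma = "numeric",
                 mseMode = "character", ssim = "SSIMConfig"))

setValidity("LossConfig", function(object) {
  w <- c(object@alpha, object@beta, object@gamma)
  if (any(w < 0)) return("loss weights must be nonnegative")
  if (all(w == 0)) return("at least one loss weight must be positive")
  if (!object@mseMode %in% c("per_pixel_mean", "literal_sum"))
    return("mseMode must be per_pixel_mean or literal_sum")
  TRUE
})

#' TrainConfig: optimisation settings for the two training phases
#'
#' @slot epochs number of epochs (>= 1).
#' @slot batchSize mini-batch size (>= 1).
#' @slot learningRate ADAM learning rate.
#' @slot beta1,beta2 ADAM moment decays. \code{beta1} defaults to 0.05
#'   (the single "beta" of the optimiser configuration); \code{beta2} is
#'   left at 0.999.
#' @slot dropoutRate dropout probability for the fully connected layers,
#'   in [0, 1).
#' @slot augment logical; apply random 90-degree rotations and horizontal/
#'   vertical flips on the fly.
#' @slot cvFolds number of cross-validation folds.
#' @slot seed integer seed governing every source of randomness.
#' @slot mrLossWeights named numeric, weights \code{reconstruction} and
#'   \code{classification} for multi-task multi-resolution training.
#' @export
setClass("TrainConfig",
  representation(epochs = "integer", batchSize = "integer",
                 learningRate = "numeric", beta1 = "numeric",
                 beta2 = "numeric", dropoutRate = "numeric",
                 augment = "logical", cvFolds = "integer", seed = "integer",
                 mrLossWeights = "numeric"))

setValidity("TrainConfig", function(object) {
  if (object@epochs < 1L) return("epochs must be >= 1")
  if (object@batchSize < 1L) return("batchSize must be >= 1")
  if (object@dropoutRate < 0 || object@dropoutRate >= 1)
    return("dropoutRate must lie in [0, 1)")
  if (!all(c("reconstruction", "classification") %in%
           names(object@mrLossWeights)))
    return("mrLossWeights needs elements reconstruction and classification")
  TRUE
})

#' SynthSpec: parameters of the synthetic multi-resolution slide generator
#'
#' @slot seed integer seed; generation is fully deterministic given it.
#' @slot dims slide edge length in pixels at 20x; must be divisible by
#'   4 * patchSize so all pyramid levels tile cleanly.
#' @slot nBlobs maximum number of tumor blobs drawn per slide.
#' @slot radiusRange blob radius range in pixels at 20x.
#' @slot tumorFraction target tumor area fraction in (0, 1).
#' @slot tissueColor,tumorColor base RGB triples of the two textures.
#' @slot noiseAmp amplitude of the additive pixel noise.
#' @slot patchSize patch edge length the fixture is tiled at.
#' @export
setClass("SynthSpec",
  representation(seed = "integer", dims = "integer", nBlobs = "integer",
                 radiusRange = "numeric", tumorFraction = "numeric",
                 tissueColor = "numeric", tumorColor = "numeric",
                 noiseAmp = "numeric", patchSize = "integer"))

setValidity("SynthSpec", function(object) {
  if (object@tumorFraction <= 0 || object@tumorFraction >= 1)
    return("tumorFraction must lie in (0, 1)")
  if (object@dims %% (4L * object@patchSize) != 0L)
    return("dims must be divisible by 4 * patchSize")
  if (length(object@tissueColor) != 3L || length(object@tumorColor) != 3L)
    return("texture colors must be RGB triples")
  TRUE
})

# ---- model classes ---------------------------------------------------------

#' CAEModel: encoder/decoder pair for patch reconstruction
#'
#' The encoder has four convolutional stages (depths 16, 32, 64, 64), each a
#' stride-1 3x3 convolution with ReLU and batch normalisation followed by a
#' stride-2 3x3 convolution with ReLU and batch normalisation, so each stage
#' halves the spatial dimensions without pooling. The bottleneck for a
#' 256 x 256 x 3 input is 16 x 16 x 64. The decoder mirrors it with four
#' transposed-convolution stages and a final 1x1 sigmoid convolution to
#' [0, 1].
#'
#' @slot encoder,decoder internal layer lists.
#' @slot spec list describing input shape and layer depths.
#' @export
setClass("CAEModel",
  representation(encoder = "list", decoder = "list", spec = "list"))

#' PatchClassifier: encoder plus softmax classifier head
#'
#' The head applies one 3x3 stride-2 convolution with ReLU and batch
#' normalisation to the bottleneck map, flattens, applies dropout (rate 0.7)
#' and a single dense layer with a 2-class softmax.
#'
#' @slot encoder,head internal layer lists.
#' @slot spec list describing shapes.
#' @export
setClass("PatchClassifier",
  representation(encoder = "list", head = "list", spec = "list"))

#' MRClassifier: three-branch multi-resolution fusion classifier
#'
#' One encoder (and decoder, for multi-task training) per magnification;
#' each bottleneck map passes through four stride-2 convolutions of depths
#' 128, 256, 512, 512, is flattened to a length-512 vector, the three
#' vectors are concatenated to length 1536, and three dense layers (ReLU,
#' batch normalisation, dropout 0.7) feed a 2-class softmax.
#'
#' @slot encoders,decoders,branches named lists (5x/10x/20x) of layer lists.
#' @slot head internal layer list operating on the concatenated vector.
#' @slot spec list describing shapes.
#' @export
setClass("MRClassifier",
  representation(encoders = "list", decoders = "list", branches = "list",
                 head = "list", spec = "list"))
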