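# Model construction: encoder h_E, decoder h_D, single-resolution
# classifier head h_C, and the three-branch multi-resolution fusion
# classifier, with exact shape contracts.

.DEPTHS <- c(16L, 32L, 64L, 64L)
.MR_DEPTHS <- c(128L, 256L, 512L, 512L)
.MR_DENSE <- c(512L, 256L, 64L)

.checkInputSize <- function(inputSize) {
  if (inputSize %% 16L != 0L)
    stop("input dims must be divisible by 16 (four halving stages); ",
         "valid sizes include 64, 128, 256, 512")
}

.encoderFingerprint <- function(spec) {
  paste0("in", spec$inputSize, "/k", spec$kernel, "/d",
         paste(spec$depths, collapse = "-"))
}

#' Build the four-stage strided-convolution encoder h_E
#'
#' Each stage is a stride-1 3x3 convolution (ReLU, batch normalisation)
#' followed by a stride-2 3x3 convolution (ReLU, batch normalisation), so
#' spatial dimensions halve once per stage without pooling. Stage depths
#' default to 16, 32, 64, 64; a 256 x 256 x 3 input maps to a 16 x 16 x 64
#' bottleneck.
#'
#' @param inputSize input edge length in pixels; must be divisible by 16.
#' @param depths channel depth of each of the 4 stages.
#' @param kernel convolution kernel edge length.
#' @return an internal layer list (use inside \code{\link{buildCAE}} or
#'   \code{\link{buildPatchClassifier}}).
#' @export
buildEncoder <- function(inputSize = 256L, depths = .DEPTHS, kernel = 3L) {
  inputSize <- as.integer(inputSize)
  .checkInputSize(inputSize)
  stopifnot(length(depths) == 4L)
  layers <- list()
  H <- inputSize
  C <- 3L
  for (d in depths) {
    layers <- c(layers, list(
      nnConv(H, H, C, d, k = kernel, stride = 1L, act = "relu"),
      nnBatchNorm(H * H, d),
      nnConv(H, H, d, d, k = kernel, stride = 2L, act = "relu"),
      nnBatchNorm((H %/% 2L)^2, d)))
    H <- H %/% 2L
    C <- d
  }
  attr(layers, "inShape") <- c(inputSize, inputSize, 3L)
  attr(layers, "outShape") <- c(H, H, C)
  layers
}

#' Build the mirrored transposed-convolution decoder h_D
#'
#' Four stages of stride-2 transposed convolution (ReLU, batch
#' normalisation) each followed by a stride-1 convolution (ReLU, batch
#' normalisation), mirroring the encoder, then a final 1x1 convolution with
#' sigmoid squashing so outputs lie in [0, 1].
#'
#' @param bottleneckSize spatial edge length of the bottleneck map.
#' @param depths encoder stage depths being mirrored.
#' @param kernel convolution kernel edge length.
#' @return an internal layer list.
#' @export
buildDecoder <- function(bottleneckSize = 16L, depths = .DEPTHS,
                         kernel = 3L) {
  H <- as.integer(bottleneckSize)
  layers <- list()
  C <- depths[4]
  for (i in 4:1) {
    nextC <- if (i > 1L) depths[i - 1L] else depths[1]
    layers <- c(layers, list(
      nnDeconv(H, H, C, depths[i], k = kernel, stride = 2L, act = "relu"),
      nnBatchNorm((2L * H)^2, depths[i]),
      nnConv(2L * H, 2L * H, depths[i], nextC, k = kernel, stride = 1L,
             act = "relu"),
      nnBatchNorm((2L * H)^2, nextC)))
    H <- 2L * H
    C <- nextC
  }
  layers <- c(layers, list(
    nnConv(H, H, C, 3L, k = 1L, stride = 1L, act = "sigmoid")))
  attr(layers, "inShape") <- c(bottleneckSize, bottleneckSize, depths[4])
  attr(layers, "outShape") <- c(H, H, 3L)
  layers
}

#' Build the single-resolution classifier head h_C
#'
#' One 3x3 stride-2 convolution (ReLU, batch normalisation) on the
#' bottleneck map, flatten, dropout (rate 0.7) on the fully connected
#' input, one dense layer, 2-class softmax.
#'
#' @param bottleneck integer (h, w, channels) shape of the bottleneck map.
#' @param nFilters filter count of the head convolution.
#' @param dropoutRate dropout probability.
#' @return an internal layer list.
#' @export
buildClassifierHead <- function(bottleneck = c(16L, 16L, 64L),
                                nFilters = 64L, dropoutRate = 0.7) {
  h <- as.integer(bottleneck[1])
  w <- as.integer(bottleneck[2])
  C <- as.integer(bottleneck[3])
  oh <- as.integer(ceiling(h / 2))
  ow <- as.integer(ceiling(w / 2))
  layers <- list(
    nnConv(h, w, C, nFilters, k = 3L, stride = 2L, act = "relu"),
    nnBatchNorm(oh * ow, nFilters),
    nnFlatten(),
    nnDropout(dropoutRate),
    nnDense(oh * ow * nFilters, 2L, act = "linear"),
    nnSoftmax())
  attr(layers, "inShape") <- c(h, w, C)
  attr(layers, "outShape") <- 2L
  layers
}

#' Build the three-branch multi-resolution fusion classifier
#'
#' Each bottleneck map passes through four 3x3 stride-2 convolutions of
#' depths 128, 256, 512, 512 (ReLU, batch normalisation) and is flattened;
#' at the reference scale the spatial trace is 16 -> 8 -> 4 -> 2 -> 1 so
#' each branch flattens to length 512 and the concatenation of the three
#' branches has length 1536. Three dense layers (ReLU, batch normalisation,
#' dropout) feed the final 2-class softmax. The 512/1536 lengths are
#' asserted at build time from the actual shapes.
#'
#' @param bottleneck integer (h, w, channels) shape of each branch input.
#' @param branchDepths depths of the four branch convolutions.
#' @param denseWidths widths of the three dense layers.
#' @param dropoutRate dropout probability.
#' @return list with elements \code{branches} (list of 3 layer lists),
#'   \code{head} (layer list on the concatenated vector),
#'   \code{branchFlattenLength} and \code{concatLength}.
#' @export
buildMRClassifier <- function(bottleneck = c(16L, 16L, 64L),
                              branchDepths = .MR_DEPTHS,
                              denseWidths = .MR_DENSE,
                              dropoutRate = 0.7) {
  h <- as.integer(bottleneck[1])
  C <- as.integer(bottleneck[3])
  mkBranch <- function() {
    layers <- list()
    hh <- h
    cc <- C
    for (d in branchDepths) {
      oh <- as.integer(ceiling(hh / 2))
      layers <- c(layers, list(
        nnConv(hh, hh, cc, d, k = 3L, stride = 2L, act = "relu"),
        nnBatchNorm(oh * oh, d)))
      hh <- oh
      cc <- d
    }
    attr(layers, "flatLen") <- hh * hh * cc
    layers
  }
  branches <- list(mkBranch(), mkBranch(), mkBranch())
  flatLen <- attr(branches[[1]], "flatLen")
  concatLen <- 3L * flatLen
  if (h == 16L && (flatLen != 512L || concatLen != 1536L))
    stop("branch shape contract violated: flatten ", flatLen,
         ", concat ", concatLen)
  layers <- list()
  fin <- concatLen
  for (wd in denseWidths) {
    layers <- c(layers, list(
      nnDense(fin, wd, act = "relu"),
      nnBatchNorm(1L, wd),
      nnDropout(dropoutRate)))
    fin <- wd
  }
  layers <- c(layers, list(nnDense(fin, 2L, act = "linear"), nnSoftmax()))
  list(branches = branches, head = layers,
       branchFlattenLength = flatLen, concatLength = concatLen)
}

#' Build a complete encoder/decoder autoencoder model
#'
#' @param inputSize input edge length in pixels (divisible by 16).
#' @param depths encoder stage depths.
#' @param kernel convolution kernel edge length.
#' @param seed integer seed for weight initialisation.
#' @return a \linkS4class{CAEModel}
#' @export
buildCAE <- function(inputSize = 256L, depths = .DEPTHS, kernel = 3L,
                     seed = 1L) {
  set.seed(seed)
  enc <- buildEncoder(inputSize, depths, kernel)
  dec <- buildDecoder(inputSize %/% 16L, depths, kernel)
  spec <- list(inputSize = as.integer(inputSize),
               depths = as.integer(depths), kernel = as.integer(kernel))
  new("CAEModel", encoder = enc, decoder = dec, spec = spec)
}

#' Build an encoder + classifier-head patch classifier
#'
#' @inheritParams buildCAE
#' @param nFilters head convolution filter count.
#' @param dropoutRate dropout probability of the fully connected layers.
#' @return a \linkS4class{PatchClassifier}
#' @export
buildPatchClassifier <- function(inputSize = 256L, depths = .DEPTHS,
                                 kernel = 3L, nFilters = 64L,
                                 dropoutRate = 0.7, seed = 1L) {
  set.seed(seed)
  enc <- buildEncoder(inputSize, depths, kernel)
  head <- buildClassifierHead(attr(enc, "outShape"), nFilters, dropoutRate)
  spec <- list(inputSize = as.integer(inputSize),
               depths = as.integer(depths), kernel = as.integer(kernel),
               nFilters = as.integer(nFilters), dropoutRate = dropoutRate)
  new("PatchClassifier", encoder = enc, head = head, spec = spec)
}

#' Transfer trained autoencoder encoder weights into a classifier
#'
#' Copies every encoder parameter (convolution weights and biases,
#' batch-norm scale/shift and running statistics) bit-identically from a
#' trained \linkS4class{CAEModel} into a \linkS4class{PatchClassifier}.
#' Nothing is frozen: all transferred parameters remain trainable.
#'
#' @param cae a trained \linkS4class{CAEModel}.
#' @param classifier a \linkS4class{PatchClassifier} with an identical
#'   encoder spec.
#' @return the classifier with the encoder initialised from the CAE.
#' @export
transferEncoderWeights <- function(cae, classifier) {
  a <- cae@spec
  b <- classifier@spec
  if (!identical(a$depths, b$depths)) {
    i <- which(a$depths != b$depths)[1]
    stop("encoder spec mismatch at stage ", i, ": depths ", a$depths[i],
         " vs ", b$depths[i])
  }
  if (a$inputSize != b$inputSize)
    stop("encoder spec mismatch: input size ", a$inputSize, " vs ",
         b$inputSize)
  if (a$kernel != b$kernel)
    stop("encoder spec mismatch: kernel ", a$kernel, " vs ", b$kernel)
  classifier@encoder <- nnCopyParams(cae@encoder, classifier@encoder)
  classifier
}

# ---- forward helpers -------------------------------------------------------

# PatchSet or list of arrays -> (H*W*C) x B matrix
.patchMatrix <- function(patches) {
  if (is(patches, "PatchSet")) patches <- patches@pixels
  if (is.list(patches)) nnStack(patches) else patches
}

#' Encode patches to bottleneck feature maps
#'
#' @param model a \linkS4class{CAEModel} or \linkS4class{PatchClassifier}.
#' @param patches a \linkS4class{PatchSet}, list of patch arrays, or batch
#'   matrix.
#' @return list of bottleneck arrays (h x w x 64), one per patch.
#' @export
encodePatches <- function(model, patches) {
  enc <- model@encoder
  X <- .patchMatrix(patches)
  if (nrow(X) != prod(attr(enc, "inShape")))
    stop("patch shape does not match the model input (",
         paste(attr(enc, "inShape"), collapse = " x "), ")")
  Z <- nnPredictChunked(enc, X)
  os <- attr(enc, "outShape")
  nnUnstack(Z, os[1], os[2], os[3])
}

#' Reconstruct patches through the autoencoder
#'
#' @param model a \linkS4class{CAEModel}.
#' @param patches a \linkS4class{PatchSet}, list of arrays, or batch matrix.
#' @return list of reconstructed (H x W x 3) arrays with values in [0, 1].
#' @export
reconstructPatches <- function(model, patches) {
  X <- .patchMatrix(patches)
  Z <- nnPredictChunked(model@encoder, X)
  Y <- nnPredictChunked(model@decoder, Z)
  os <- attr(model@decoder, "outShape")
  nnUnstack(Y, os[1], os[2], os[3])
}

# ---- introspection ---------------------------------------------------------

.layerTable <- function(layers, inShape) {
  shp <- inShape
  rows <- lapply(layers, function(l) {
    out <- switch(l$kind,
      conv = c(l$outH, l$outW, l$Cout),
      deconv = c(l$outH, l$outW, l$Cout),
      dense = l$Fout,
      shp)
    shp <<- out
    data.frame(layer = l$kind,
               output = paste(out, collapse = "x"),
               params = sum(vapply(l[intersect(.PARAM_NAMES, names(l))],
                                   length, integer(1))))
  })
  do.call(rbind, rows)
}

#' Number of trainable parameters of a model
#' @param model a CAEModel, PatchClassifier, or MRClassifier.
#' @return integer parameter count (weights, biases, batch-norm
#'   scale/shift).
#' @export
numParameters <- function(model) {
  if (is(model, "CAEModel"))
    return(nnNumParams(model@encoder) + nnNumParams(model@decoder))
  if (is(model, "PatchClassifier"))
    return(nnNumParams(model@encoder) + nnNumParams(model@head))
  if (is(model, "MRClassifier"))
    return(sum(vapply(model@encoders, nnNumParams, numeric(1))) +
           sum(vapply(model@decoders, nnNumParams, numeric(1))) +
           sum(vapply(model@branches, nnNumParams, numeric(1))) +
           nnNumParams(model@head))
  stop("unsupported model class: ", class(model))
}

#' Print the layer table of a model (shapes and parameter counts)
#' @param model a CAEModel or PatchClassifier.
#' @return invisibly, the table as a data.frame.
#' @export
describeModel <- function(model) {
  if (is(model, "CAEModel")) {
    tab <- rbind(
      cbind(module = "encoder",
            .layerTable(model@encoder, attr(model@encoder, "inShape"))),
      cbind(module = "decoder",
            .layerTable(model@decoder, attr(model@decoder, "inShape"))))
  } else if (is(model, "PatchClassifier")) {
    tab <- rbind(
      cbind(module = "encoder",
            .layerTable(model@encoder, attr(model@encoder, "inShape"))),
      cbind(module = "head",
            .layerTable(model@head, attr(model@head, "inShape"))))
  } else {
    stop("unsupported model class: ", class(model))
  }
  print(tab, row.names = FALSE)
  cat(sprintf("total trainable parameters: %d\n", numParameters(model)))
  invisible(tab)
}

setMethod("show", "CAEModel", function(object) {
  s <- object@spec
  cat(sprintf(
    "CAEModel: %d x %d x 3 -> %d x %d x %d bottleneck (%d parameters)\n",
    s$inputSize, s$inputSize, s$inputSize %/% 16L, s$inputSize %/% 16L,
    s$depths[4], numParameters(object)))
})

setMethod("show", "PatchClassifier", function(object) {
  s <- object@spec
  cat(sprintf(
    "PatchClassifier: %d x %d x 3 -> 2-class softmax (%d parameters)\n",
    s$inputSize, s$inputSize, numParameters(object)))
})

setMethod("show", "MRClassifier", function(object) {
  cat(sprintf(
    "MRClassifier: 3 branches, flatten %d, concat %d (%d parameters)\n",
    object@spec$branchFlattenLength, object@spec$concatLength,
    numParameters(object)))
})
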