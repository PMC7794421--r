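# Two-phase training: (1) autoencoder on the joint reconstruction loss;
# (2) encoder-classifier initialised from phase 1, trained on
# cross-entropy; plus the multi-resolution multi-task variant.

.CLASSES <- c("non_tumor", "tumor")

.onehot <- function(labels) {
  Y <- matrix(0, 2L, length(labels))
  Y[cbind(match(labels, .CLASSES), seq_along(labels))] <- 1
  Y
}

.batchIdx <- function(n, batchSize) {
  ord <- sample.int(n)
  split(ord, ceiling(seq_along(ord) / batchSize))
}

.resolveBatch <- function(n, batchSize) {
  if (n < 2L * batchSize) {
    bs <- max(1L, n %/% 2L)
    warning("fewer than 2 x batchSize patches; reducing batch size to ", bs)
    bs
  } else {
    batchSize
  }
}

#' Assign cross-validation folds
#'
#' Units (typically slide ids, so no slide contributes patches to both the
#' training and validation side of a fold) are assigned to k disjoint folds
#' whose union is the full set.
#'
#' @param units vector of unit identifiers, one per sample.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold indices (1..k), one per sample.
#' @export
cvFolds <- function(units, k = 5L, seed = 1L) {
  set.seed(seed)
  u <- unique(units)
  fu <- sample(rep_len(seq_len(k), length(u)))
  fu[match(units, u)]
}

#' Train the autoencoder h_CAE on the joint reconstruction loss
#'
#' Patches are optionally augmented on the fly with random 90-degree
#' rotations and horizontal/vertical flips; optimisation is ADAM. The run
#' is fully deterministic given the config seed.
#'
#' @param patches a \linkS4class{PatchSet}, list of (H, W, 3) arrays, or
#'   batch matrix.
#' @param lossCfg a \linkS4class{LossConfig}.
#' @param trainCfg a \linkS4class{TrainConfig}.
#' @param model optional \linkS4class{CAEModel} to continue training;
#'   built fresh from the patch size and seed when NULL.
#' @return list with elements \code{model} (trained
#'   \linkS4class{CAEModel}) and \code{log} (data.frame with per-epoch
#'   joint loss and its mse/ssimLoss/mae components; attributes
#'   \code{seed} and \code{config} snapshot the run).
#' @export
trainAutoencoder <- function(patches, lossCfg = lossConfig(),
                             trainCfg = trainConfig(), model = NULL) {
  X <- .patchMatrix(patches)
  n <- ncol(X)
  if (n == 0L) stop("empty patch set")
  H <- as.integer(sqrt(nrow(X) / 3L))
  if (H * H * 3L != nrow(X)) stop("patches must be square H x H x 3")
  set.seed(trainCfg@seed)
  if (is.null(model)) model <- buildCAE(H, seed = trainCfg@seed)
  bs <- .resolveBatch(n, trainCfg@batchSize)
  enc <- model@encoder
  dec <- model@decoder
  stEnc <- nnAdamInit(enc)
  stDec <- nnAdamInit(dec)
  perms <- if (trainCfg@augment) nnDihedralPerms(H, H, 3L) else NULL
  log <- vector("list", trainCfg@epochs)
  for (ep in seq_len(trainCfg@epochs)) {
    tot <- 0
    comp <- c(mse = 0, ssimLoss = 0, mae = 0)
    nb <- 0
    for (ix in .batchIdx(n, bs)) {
      Xb <- X[, ix, drop = FALSE]
      if (!is.null(perms)) Xb <- nnAugmentBatch(Xb, perms)
      fe <- nnForward(enc, Xb, training = TRUE)
      enc <- fe$layers
      fd <- nnForward(dec, fe$out, training = TRUE)
      dec <- fd$layers
      lg <- reconLossGrad(Xb, fd$out, lossCfg, H, H, 3L)
      bd <- nnBackward(dec, fd$caches, lg$grad)
      be <- nnBackward(enc, fe$caches, bd$dX)
      up <- nnAdamStep(dec, bd$grads, stDec, trainCfg@learningRate,
                       trainCfg@beta1, trainCfg@beta2)
      dec <- up$layers; stDec <- up$state
      up <- nnAdamStep(enc, be$grads, stEnc, trainCfg@learningRate,
                       trainCfg@beta1, trainCfg@beta2)
      enc <- up$layers; stEnc <- up$state
      w <- length(ix)
      tot <- tot + as.numeric(lg$loss) * w
      comp <- comp + lg$components * w
      nb <- nb + w
    }
    log[[ep]] <- data.frame(epoch = ep, jointLoss = tot / nb,
                            mse = comp[["mse"]] / nb,
                            ssimLoss = comp[["ssimLoss"]] / nb,
                            mae = comp[["mae"]] / nb)
  }
  # recalibrate batch-norm running statistics under the final weights
  enc <- nnCalibrateBN(enc, X)
  Zc <- nnPredictChunked(enc, X)
  dec <- nnCalibrateBN(dec, Zc)
  model@encoder <- enc
  model@decoder <- dec
  log <- do.call(rbind, log)
  attr(log, "seed") <- trainCfg@seed
  attr(log, "config") <- trainCfg
  list(model = model, log = log)
}

# Forward a classifier (encoder + head); returns probs and caches.
.clfForward <- function(enc, head, X, training) {
  fe <- nnForward(enc, X, training = training)
  fh <- nnForward(head, fe$out, training = training)
  list(fe = fe, fh = fh, probs = fh$out)
}

#' Train the encoder-classifier h_CL from a pretrained autoencoder
#'
#' The encoder is initialised bit-identically from the trained autoencoder
#' via \code{\link{transferEncoderWeights}} and the whole module is then
#' updated without freezing the encoder, minimising the classification
#' cross-entropy.
#'
#' @param patches a labelled \linkS4class{PatchSet} (labels "tumor" /
#'   "non_tumor"; both classes must be present).
#' @param cae a trained \linkS4class{CAEModel}, or NULL to train from a
#'   random initialisation.
#' @param trainCfg a \linkS4class{TrainConfig}.
#' @param valPatches optional labelled \linkS4class{PatchSet} used for
#'   per-epoch validation accuracy.
#' @return list with elements \code{model} (trained
#'   \linkS4class{PatchClassifier}) and \code{log} (per-epoch
#'   cross-entropy, training accuracy and, when supplied, validation
#'   accuracy).
#' @export
trainClassifier <- function(patches, cae = NULL,
                            trainCfg = trainConfig(), valPatches = NULL) {
  stopifnot(is(patches, "PatchSet"))
  labels <- patches@info$label
  if (length(unique(labels[labels != "unlabeled"])) < 2L)
    stop("both classes must be present in the training data")
  X <- .patchMatrix(patches)
  H <- patches@patchSize
  set.seed(trainCfg@seed)
  clf <- buildPatchClassifier(H, dropoutRate = trainCfg@dropoutRate,
                              seed = trainCfg@seed)
  if (!is.null(cae)) clf <- transferEncoderWeights(cae, clf)
  n <- ncol(X)
  bs <- .resolveBatch(n, trainCfg@batchSize)
  enc <- clf@encoder
  head <- clf@head
  nh <- length(head)  # last layer is softmax
  stEnc <- nnAdamInit(enc)
  stHead <- nnAdamInit(head)
  perms <- if (trainCfg@augment) nnDihedralPerms(H, H, 3L) else NULL
  Y <- .onehot(labels)
  log <- vector("list", trainCfg@epochs)
  for (ep in seq_len(trainCfg@epochs)) {
    tot <- 0
    hits <- 0
    for (ix in .batchIdx(n, bs)) {
      Xb <- X[, ix, drop = FALSE]
      if (!is.null(perms)) Xb <- nnAugmentBatch(Xb, perms)
      Yb <- Y[, ix, drop = FALSE]
      f <- .clfForward(enc, head, Xb, training = TRUE)
      enc <- f$fe$layers
      head <- f$fh$layers
      P <- f$probs
      tot <- tot + crossEntropyLoss(NULL, pmax(colSums(P * Yb), 1e-12)) *
        length(ix)
      hits <- hits + sum(max.col(t(P)) == max.col(t(Yb)))
      dLogits <- (P - Yb) / ncol(P)
      bh <- nnBackward(head[seq_len(nh - 1L)],
                       f$fh$caches[seq_len(nh - 1L)], dLogits)
      be <- nnBackward(enc, f$fe$caches, bh$dX)
      up <- nnAdamStep(head, c(bh$grads, list(NULL)), stHead,
                       trainCfg@learningRate, trainCfg@beta1,
                       trainCfg@beta2)
      head <- up$layers; stHead <- up$state
      up <- nnAdamStep(enc, be$grads, stEnc, trainCfg@learningRate,
                       trainCfg@beta1, trainCfg@beta2)
      enc <- up$layers; stEnc <- up$state
    }
    valAcc <- NA_real_
    if (!is.null(valPatches)) {
      clf@encoder <- enc
      clf@head <- head
      pr <- predictPatches(clf, valPatches)
      valAcc <- mean(pr$label == valPatches@info$label)
    }
    log[[ep]] <- data.frame(epoch = ep, ceLoss = tot / n,
                            trainAcc = hits / n, valAcc = valAcc)
  }
  enc <- nnCalibrateBN(enc, X)
  head <- nnCalibrateBN(head, nnPredictChunked(enc, X))
  clf@encoder <- enc
  clf@head <- head
  log <- do.call(rbind, log)
  attr(log, "seed") <- trainCfg@seed
  attr(log, "config") <- trainCfg
  list(model = clf, log = log)
}

#' Predict tumor probabilities and labels for patches
#'
#' Inference mode: dropout off, batch normalisation using running
#' statistics, so repeated calls are identical.
#'
#' @param model a trained \linkS4class{PatchClassifier} or
#'   \linkS4class{MRClassifier}.
#' @param patches a \linkS4class{PatchSet} (or list of
#'   \linkS4class{MultiResSample}s for the multi-resolution model).
#' @return data.frame with columns \code{nonTumorProb}, \code{tumorProb}
#'   and \code{label}, one row per patch.
#' @export
predictPatches <- function(model, patches) {
  if (is(model, "MRClassifier")) return(.predictMR(model, patches))
  X <- .patchMatrix(patches)
  if (nrow(X) != prod(attr(model@encoder, "inShape")))
    stop("patch shape does not match the model input")
  Z <- nnPredictChunked(model@encoder, X)
  P <- nnPredictChunked(model@head, Z)
  data.frame(nonTumorProb = P[1, ], tumorProb = P[2, ],
             label = .CLASSES[max.col(t(P))], stringsAsFactors = FALSE)
}

# ---- multi-resolution ------------------------------------------------------

.MR_MAGS <- c("5x", "10x", "20x")

.mrBatch <- function(samples, mag, ix) {
  nnStack(lapply(samples[ix], function(s) s@pixels[[mag]]))
}

#' Assemble a multi-resolution classifier from three trained autoencoders
#'
#' @param caes named list of \linkS4class{CAEModel}s ("5x", "10x", "20x"),
#'   typically each pretrained on its own magnification.
#' @param dropoutRate dropout probability of the dense layers.
#' @param seed integer seed for the fusion-head initialisation.
#' @return an \linkS4class{MRClassifier}
#' @export
buildMRModel <- function(caes, dropoutRate = 0.7, seed = 1L) {
  if (!all(.MR_MAGS %in% names(caes)))
    stop("caes must be a named list with elements 5x, 10x, 20x")
  set.seed(seed)
  bot <- attr(caes[["20x"]]@encoder, "outShape")
  mr <- buildMRClassifier(bot, dropoutRate = dropoutRate)
  new("MRClassifier",
      encoders = lapply(caes[.MR_MAGS], function(m) m@encoder),
      decoders = lapply(caes[.MR_MAGS], function(m) m@decoder),
      branches = stats::setNames(mr$branches, .MR_MAGS),
      head = mr$head,
      spec = list(bottleneck = bot,
                  branchFlattenLength = mr$branchFlattenLength,
                  concatLength = mr$concatLength,
                  inputSize = caes[["20x"]]@spec$inputSize))
}

.mrForwardInfer <- function(model, samples) {
  n <- length(samples)
  flats <- lapply(.MR_MAGS, function(mg) {
    Xm <- .mrBatch(samples, mg, seq_len(n))
    Z <- nnPredictChunked(model@encoders[[mg]], Xm)
    nnPredictChunked(model@branches[[mg]], Z)
  })
  concat <- do.call(rbind, flats)
  nnPredictChunked(model@head, concat)
}

.predictMR <- function(model, samples) {
  for (s in samples) validObject(s)
  P <- .mrForwardInfer(model, samples)
  data.frame(nonTumorProb = P[1, ], tumorProb = P[2, ],
             label = .CLASSES[max.col(t(P))], stringsAsFactors = FALSE)
}

#' Multi-task training of the multi-resolution model
#'
#' Minimises \code{w_r * (sum of the three branch reconstruction losses) +
#' w_c * classification cross-entropy} jointly over the three
#' encoder/decoder pairs, the three branch stacks and the fusion head,
#' with weights from \code{trainCfg@mrLossWeights}.
#'
#' @param samples list of complete \linkS4class{MultiResSample}s with 20x
#'   labels.
#' @param caes named list of pretrained \linkS4class{CAEModel}s
#'   ("5x", "10x", "20x").
#' @param lossCfg a \linkS4class{LossConfig} for the reconstruction terms.
#' @param trainCfg a \linkS4class{TrainConfig}.
#' @return list with \code{model} (trained \linkS4class{MRClassifier}) and
#'   \code{log} (per-epoch reconstruction losses per magnification,
#'   classification loss, and total).
#' @export
trainMR <- function(samples, caes, lossCfg = lossConfig(),
                    trainCfg = trainConfig()) {
  if (length(samples) == 0L) stop("empty sample set")
  for (s in samples) {
    if (!all(.MR_MAGS %in% names(s@pixels)))
      stop("sample missing a magnification: need 5x, 10x, 20x")
  }
  set.seed(trainCfg@seed)
  model <- buildMRModel(caes, dropoutRate = trainCfg@dropoutRate,
                        seed = trainCfg@seed)
  n <- length(samples)
  bs <- .resolveBatch(n, trainCfg@batchSize)
  H <- dim(samples[[1]]@pixels[["20x"]])[1]
  wr <- trainCfg@mrLossWeights[["reconstruction"]]
  wc <- trainCfg@mrLossWeights[["classification"]]
  labels <- vapply(samples, function(s) s@label, character(1))
  Y <- .onehot(labels)
  encs <- model@encoders
  decs <- model@decoders
  brs <- model@branches
  head <- model@head
  nh <- length(head)
  stE <- lapply(encs, nnAdamInit)
  stD <- lapply(decs, nnAdamInit)
  stB <- lapply(brs, nnAdamInit)
  stH <- nnAdamInit(head)
  flatLen <- model@spec$branchFlattenLength
  log <- vector("list", trainCfg@epochs)
  for (ep in seq_len(trainCfg@epochs)) {
    acc <- c(recon5x = 0, recon10x = 0, recon20x = 0, classLoss = 0,
             totalLoss = 0)
    for (ix in .batchIdx(n, bs)) {
      B <- length(ix)
      Yb <- Y[, ix, drop = FALSE]
      feL <- list(); fdL <- list(); fbL <- list(); rgL <- list()
      flats <- vector("list", 3L)
      names(flats) <- .MR_MAGS
      rl <- numeric(3L)
      names(rl) <- .MR_MAGS
      for (mg in .MR_MAGS) {
        Xm <- .mrBatch(samples, mg, ix)
        fe <- nnForward(encs[[mg]], Xm, training = TRUE)
        encs[[mg]] <- fe$layers
        fd <- nnForward(decs[[mg]], fe$out, training = TRUE)
        decs[[mg]] <- fd$layers
        rg <- reconLossGrad(Xm, fd$out, lossCfg, H, H, 3L)
        fb <- nnForward(brs[[mg]], fe$out, training = TRUE)
        brs[[mg]] <- fb$layers
        feL[[mg]] <- fe; fdL[[mg]] <- fd; fbL[[mg]] <- fb; rgL[[mg]] <- rg
        flats[[mg]] <- fb$out
        rl[mg] <- as.numeric(rg$loss)
      }
      concat <- do.call(rbind, flats)
      fh <- nnForward(head, concat, training = TRUE)
      head <- fh$layers
      P <- fh$out
      ce <- crossEntropyLoss(NULL, pmax(colSums(P * Yb), 1e-12))
      total <- wr * sum(rl) + wc * ce
      dLogits <- wc * (P - Yb) / B
      bh <- nnBackward(head[seq_len(nh - 1L)],
                       fh$caches[seq_len(nh - 1L)], dLogits)
      up <- nnAdamStep(head, c(bh$grads, list(NULL)), stH,
                       trainCfg@learningRate, trainCfg@beta1,
                       trainCfg@beta2)
      head <- up$layers; stH <- up$state
      for (k in seq_along(.MR_MAGS)) {
        mg <- .MR_MAGS[k]
        dFlat <- bh$dX[((k - 1L) * flatLen + 1L):(k * flatLen), ,
                       drop = FALSE]
        bb <- nnBackward(brs[[mg]], fbL[[mg]]$caches, dFlat)
        bd <- nnBackward(decs[[mg]], fdL[[mg]]$caches, wr * rgL[[mg]]$grad)
        be <- nnBackward(encs[[mg]], feL[[mg]]$caches, bb$dX + bd$dX)
        up <- nnAdamStep(brs[[mg]], bb$grads, stB[[mg]],
                         trainCfg@learningRate, trainCfg@beta1,
                         trainCfg@beta2)
        brs[[mg]] <- up$layers; stB[[mg]] <- up$state
        up <- nnAdamStep(decs[[mg]], bd$grads, stD[[mg]],
                         trainCfg@learningRate, trainCfg@beta1,
                         trainCfg@beta2)
        decs[[mg]] <- up$layers; stD[[mg]] <- up$state
        up <- nnAdamStep(encs[[mg]], be$grads, stE[[mg]],
                         trainCfg@learningRate, trainCfg@beta1,
                         trainCfg@beta2)
        encs[[mg]] <- up$layers; stE[[mg]] <- up$state
      }
      w <- B / n
      acc <- acc + w * c(rl[["5x"]], rl[["10x"]], rl[["20x"]], ce, total)
    }
    log[[ep]] <- data.frame(epoch = ep, recon5x = acc[[1]],
                            recon10x = acc[[2]], recon20x = acc[[3]],
                            classLoss = acc[[4]], totalLoss = acc[[5]])
  }
  flats <- list()
  for (mg in .MR_MAGS) {
    Xm <- .mrBatch(samples, mg, seq_len(n))
    encs[[mg]] <- nnCalibrateBN(encs[[mg]], Xm)
    Zm <- nnPredictChunked(encs[[mg]], Xm)
    decs[[mg]] <- nnCalibrateBN(decs[[mg]], Zm)
    brs[[mg]] <- nnCalibrateBN(brs[[mg]], Zm)
    flats[[mg]] <- nnPredictChunked(brs[[mg]], Zm)
  }
  head <- nnCalibrateBN(head, do.call(rbind, flats[.MR_MAGS]))
  model@encoders <- encs
  model@decoders <- decs
  model@branches <- brs
  model@head <- head
  log <- do.call(rbind, log)
  attr(log, "seed") <- trainCfg@seed
  attr(log, "config") <- trainCfg
  list(model = model, log = log)
}
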