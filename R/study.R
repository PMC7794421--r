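# Desk-scale end-to-end study on the synthetic fixture: the full
# two-phase pipeline (autoencoder pretraining, classifier fine-tuning,
# whole-slide prediction, mask assembly and scoring) at sizes that run on
# one CPU in minutes.

#' Run the desk-scale end-to-end study on synthetic slides
#'
#' Protocol: a balanced set of 250 tumor + 250 non-tumor patches is drawn
#' from synthetic 2048 x 2048 slides (seed-determined); 400 patches train
#' and 100 are held out. The autoencoder is trained on 200 of the training
#' patches for \code{caeEpochs} under the joint MSE + SSIM + MAE loss, the
#' classifier is initialised from it and trained for \code{clfEpochs}.
#' Held-out patch accuracy is measured, then a fresh test slide (disjoint
#' seed) is tiled, predicted, assembled into a mask and scored by dice
#' against the block-quantized ground truth.
#'
#' @param seed integer seed governing generation, splits and training.
#' @param caeEpochs,clfEpochs training epochs of the two phases.
#' @param lossCfg a \linkS4class{LossConfig} for phase 1.
#' @param verbose print progress lines.
#' @return list with elements \code{accuracy} (held-out patch accuracy),
#'   \code{dice} (assembled mask vs block-quantized truth),
#'   \code{slideAccuracy} (patch accuracy over the test slide),
#'   \code{caeLog}, \code{clfLog}, \code{model}, \code{report}
#'   (\linkS4class{MetricsReport} for the test slide).
#' @export
deskScaleStudy <- function(seed = 7L, caeEpochs = 20L, clfEpochs = 30L,
                           lossCfg = lossConfig(), verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  spec <- synthSpec(seed = seed)
  say("generating patch dataset (2 x 250 patches, ", spec@dims,
      "px slides) ...")
  ds <- generatePatchDataset(spec, nPerClass = 250L)

  set.seed(seed)
  idxT <- which(ds@info$label == "tumor")
  idxN <- which(ds@info$label == "non_tumor")
  testIdx <- c(sample(idxT, 50L), sample(idxN, 50L))
  trainIdx <- setdiff(seq_along(ds@pixels), testIdx)
  sub <- function(ix) new("PatchSet", pixels = ds@pixels[ix],
                          info = ds@info[ix, , drop = FALSE],
                          patchSize = ds@patchSize)
  trainSet <- sub(trainIdx)
  testSet <- sub(testIdx)

  say("phase 1: autoencoder, ", caeEpochs, " epochs ...")
  caeCfg <- trainConfig(epochs = caeEpochs, batchSize = 64L,
                        learningRate = 1e-3, seed = seed)
  cae <- trainAutoencoder(sub(trainIdx[seq_len(200L)]), lossCfg, caeCfg)

  say("phase 2: classifier, ", clfEpochs, " epochs ...")
  clfCfg <- trainConfig(epochs = clfEpochs, batchSize = 64L,
                        learningRate = 1e-3, seed = seed)
  clf <- trainClassifier(trainSet, cae$model, clfCfg)

  pr <- predictPatches(clf$model, testSet)
  acc <- mean(pr$label == testSet@info$label)
  say("held-out patch accuracy: ", round(acc, 4))

  say("scoring a fresh test slide ...")
  testSpec <- synthSpec(seed = seed + 1000L)
  tsl <- generateSlide(testSpec)
  tiled <- tileSlide(tsl$images[["20x"]], patchSize = spec@patchSize,
                     mask = tsl$masks[["20x"]])
  prS <- predictPatches(clf$model, tiled$patches)
  predMask <- assembleMask(tiled$grid, prS$label)
  report <- evaluateMask(predMask, tsl$masks[["20x"]], grid = tiled$grid,
                         blockQuantized = TRUE)
  say("dice vs block-quantized truth: ", round(report@dice, 4))

  list(accuracy = acc, dice = report@dice,
       slideAccuracy = mean(prS$label == tiled$patches@info$label),
       caeLog = cae$log, clfLog = clf$log, model = clf$model,
       report = report)
}
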