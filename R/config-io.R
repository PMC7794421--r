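# YAML (de)serialization of the configuration value classes, so runs are
# reproducible from their emitted config snapshots.

#' Convert a configuration object to a plain list
#' @param x a LossConfig, SSIMConfig, TrainConfig or SynthSpec.
#' @return a named list suitable for YAML serialization.
#' @export
configAsList <- function(x) {
  if (is(x, "LossConfig")) {
    return(list(alpha = x@alpha, beta = x@beta, gamma = x@gamma,
                mseMode = x@mseMode, ssim = configAsList(x@ssim)))
  }
  if (is(x, "SSIMConfig")) {
    return(list(windowSize = x@windowSize, windowKind = x@windowKind,
                gaussianSigma = x@gaussianSigma,
                dynamicRange = x@dynamicRange, k1 = x@k1, k2 = x@k2,
                expL = x@expL, expC = x@expC, expS = x@expS,
                channelMode = x@channelMode))
  }
  if (is(x, "TrainConfig")) {
    return(list(epochs = x@epochs, batchSize = x@batchSize,
                learningRate = x@learningRate, beta1 = x@beta1,
                beta2 = x@beta2, dropoutRate = x@dropoutRate,
                augment = x@augment, cvFolds = x@cvFolds, seed = x@seed,
                mrLossWeights = as.list(x@mrLossWeights)))
  }
  if (is(x, "SynthSpec")) {
    return(list(seed = x@seed, dims = x@dims, nBlobs = x@nBlobs,
                radiusRange = x@radiusRange,
                tumorFraction = x@tumorFraction,
                tissueColor = x@tissueColor, tumorColor = x@tumorColor,
                noiseAmp = x@noiseAmp, patchSize = x@patchSize))
  }
  stop("unsupported configuration class: ", class(x))
}

#' Write configuration objects to a YAML file
#' @param ... named configuration objects (e.g. \code{loss = lossConfig()}).
#' @param path output YAML path.
#' @export
writeConfig <- function(..., path) {
  objs <- list(...)
  yaml::write_yaml(lapply(objs, configAsList), path)
  invisible(path)
}

.listToConfig <- function(kind, lst) {
  switch(kind,
    loss = lossConfig(alpha = lst$alpha, beta = lst$beta,
                      gamma = lst$gamma, mseMode = lst$mseMode,
                      ssim = if (is.null(lst$ssim)) ssimConfig()
                             else .listToConfig("ssim", lst$ssim)),
    ssim = do.call(ssimConfig, lst),
    train = trainConfig(epochs = lst$epochs, batchSize = lst$batchSize,
                        learningRate = lst$learningRate,
                        beta1 = lst$beta1, beta2 = lst$beta2,
                        dropoutRate = lst$dropoutRate,
                        augment = lst$augment, cvFolds = lst$cvFolds,
                        seed = lst$seed,
                        mrLossWeights = unlist(lst$mrLossWeights)),
    synth = do.call(synthSpec, lst),
    stop("unknown config kind: ", kind))
}

#' Read configuration objects from a YAML file
#'
#' Recognised top-level blocks: \code{loss}, \code{ssim}, \code{train},
#' \code{synth}.
#'
#' @param path YAML path written by \code{\link{writeConfig}} (or by hand).
#' @return named list of configuration objects.
#' @export
readConfig <- function(path) {
  lst <- yaml::read_yaml(path)
  out <- list()
  for (nm in names(lst)) out[[nm]] <- .listToConfig(nm, lst[[nm]])
  out
}
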