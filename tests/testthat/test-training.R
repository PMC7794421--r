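# Training runs in these tests are deliberately tiny (32-px patches, few
# epochs); the full desk-scale end-to-end run lives in test-acceptance.R.

test_that("autoencoder training reduces the joint loss deterministically", {
  ps <- makePatchSet(48L, H = 32L, seed = 31L)
  cfg <- tinyTrainConfig(epochs = 4L, seed = 7L)
  fit <- trainAutoencoder(ps, lossConfig(), cfg)
  expect_s4_class(fit$model, "CAEModel")
  expect_equal(nrow(fit$log), 4L)
  expect_lt(fit$log$jointLoss[4], fit$log$jointLoss[1])
  # joint loss recomposes from logged components with default weights
  expect_equal(fit$log$jointLoss,
               0.5 * (fit$log$mse + fit$log$ssimLoss + fit$log$mae),
               tolerance = 1e-10)

  # identical seed => identical loss history
  fit2 <- trainAutoencoder(ps, lossConfig(), cfg)
  expect_identical(fit$log, fit2$log)

  expect_error(trainAutoencoder(list(), lossConfig(), cfg), "empty")
  expect_error(trainConfig(epochs = 0L))
})

test_that("small patch sets reduce the batch size with a warning", {
  ps <- makePatchSet(10L, H = 32L, seed = 32L)
  cfg <- trainConfig(epochs = 1L, batchSize = 64L, learningRate = 1e-3,
                     seed = 1L)
  expect_warning(fit <- trainAutoencoder(ps, lossConfig(), cfg),
                 "reducing batch size")
  expect_equal(nrow(fit$log), 1L)
})

test_that("classifier training starts from CAE weights and unfreezes them", {
  ps <- makePatchSet(48L, H = 32L, seed = 33L)
  cae <- trainAutoencoder(ps, lossConfig(),
                          tinyTrainConfig(epochs = 2L, seed = 3L))$model

  fit <- trainClassifier(ps, cae, tinyTrainConfig(epochs = 3L, seed = 3L))
  expect_s4_class(fit$model, "PatchClassifier")
  # the trained encoder moved away from the CAE initialisation
  expect_gt(histocae:::nnMaxParamDiff(cae@encoder, fit$model@encoder), 0)
  # training improved the fit on this separable set
  expect_gt(fit$log$trainAcc[3], 0.6)

  # the transfer itself is bit-identical (checked before any update)
  clf0 <- transferEncoderWeights(cae, buildPatchClassifier(32L, seed = 3L))
  expect_equal(histocae:::nnMaxParamDiff(cae@encoder, clf0@encoder), 0)

  single <- makePatchSet(8L, H = 32L, labels = rep("tumor", 8L))
  expect_error(trainClassifier(single, cae, tinyTrainConfig(1L)),
               "both classes")
})

test_that("prediction is deterministic with valid probabilities", {
  ps <- makePatchSet(12L, H = 32L, seed = 34L)
  clf <- buildPatchClassifier(32L, seed = 8L)
  p1 <- predictPatches(clf, ps)
  p2 <- predictPatches(clf, ps)
  expect_identical(p1, p2)
  expect_equal(p1$nonTumorProb + p1$tumorProb, rep(1, 12L),
               tolerance = 1e-6)
  expect_true(all(p1$label %in% c("tumor", "non_tumor")))
})

test_that("cross-validation folds partition units without leakage", {
  slides <- rep(paste0("s", 1:10), each = 7)
  folds <- cvFolds(slides, k = 5L, seed = 2L)
  expect_length(folds, length(slides))
  expect_setequal(unique(folds), 1:5)
  # all patches of one slide share a fold
  expect_true(all(tapply(folds, slides, function(f) length(unique(f))) == 1))
  # folds partition the set
  for (k in 1:5) {
    val <- slides[folds == k]
    train <- slides[folds != k]
    expect_length(intersect(unique(val), unique(train)), 0)
  }
})

test_that("augmentation permutations preserve patch content", {
  perms <- histocae:::nnDihedralPerms(8L, 8L, 3L)
  expect_length(perms, 8L)
  x <- runif(8 * 8 * 3)
  for (p in perms) {
    expect_setequal(p, seq_len(8 * 8 * 3))       # a true permutation
    expect_equal(sort(x[p]), sort(x))            # content preserved
  }
})

test_that("multi-task MR training logs recompose into the total loss", {
  spec <- synthSpec(seed = 19L, dims = 512L)
  slide <- generateSlide(spec)
  samples <- sampleMultiResDataset(slide, nPerClass = 8L, patchSize = 32L,
                                   seed = 19L)
  caes <- list("5x" = buildCAE(32L, seed = 1L),
               "10x" = buildCAE(32L, seed = 2L),
               "20x" = buildCAE(32L, seed = 3L))
  cfg <- tinyTrainConfig(epochs = 5L, seed = 5L, batchSize = 8L)
  fit <- trainMR(samples, caes, lossConfig(), cfg)
  expect_s4_class(fit$model, "MRClassifier")
  wr <- cfg@mrLossWeights[["reconstruction"]]
  wc <- cfg@mrLossWeights[["classification"]]
  expect_equal(fit$log$totalLoss,
               wr * (fit$log$recon5x + fit$log$recon10x +
                     fit$log$recon20x) + wc * fit$log$classLoss,
               tolerance = 1e-10)
  expect_lt(fit$log$totalLoss[5], fit$log$totalLoss[1])

  # prediction over MR samples
  pr <- predictPatches(fit$model, samples)
  expect_equal(nrow(pr), length(samples))
  expect_equal(pr$nonTumorProb + pr$tumorProb, rep(1, length(samples)),
               tolerance = 1e-6)

  # a sample missing one magnification is rejected
  broken <- samples
  broken[[1]]@pixels <- broken[[1]]@pixels[c("5x", "10x")]
  expect_error(trainMR(broken, caes, lossConfig(), cfg), "magnification")
})

test_that("zero classification weight leaves the fusion head untouched", {
  spec <- synthSpec(seed = 23L, dims = 512L)
  slide <- generateSlide(spec)
  samples <- sampleMultiResDataset(slide, nPerClass = 4L, patchSize = 32L,
                                   seed = 23L)
  caes <- list("5x" = buildCAE(32L, seed = 1L),
               "10x" = buildCAE(32L, seed = 2L),
               "20x" = buildCAE(32L, seed = 3L))
  cfg <- trainConfig(epochs = 1L, batchSize = 4L, learningRate = 1e-3,
                     seed = 5L,
                     mrLossWeights = c(reconstruction = 1,
                                       classification = 0))
  ref <- buildMRModel(caes, dropoutRate = cfg@dropoutRate, seed = cfg@seed)
  fit <- trainMR(samples, caes, lossConfig(), cfg)
  # dense/batch-norm parameters of the head received zero update
  expect_equal(histocae:::nnMaxParamDiff(ref@head, fit$model@head), 0)
  # while the decoders did move (reconstruction weight is nonzero)
  expect_gt(histocae:::nnMaxParamDiff(ref@decoders[["20x"]],
                                      fit$model@decoders[["20x"]]), 0)
})
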