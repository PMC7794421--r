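test_that("encoder halves spatial dims four times to a 64-channel map", {
  set.seed(1)
  enc <- buildEncoder(64L)
  expect_equal(attr(enc, "outShape"), c(4L, 4L, 64L))
  x <- array(runif(64 * 64 * 3), c(64, 64, 3))
  z <- histocae:::nnForward(enc, matrix(histocae:::nnArray2Col(x)))$out
  expect_equal(nrow(z), 4 * 4 * 64)

  # per-layer output channels in order 16, 32, 64, 64
  convs <- Filter(function(l) l$kind == "conv", enc)
  expect_equal(vapply(convs, function(l) l$Cout, integer(1)),
               c(16L, 16L, 32L, 32L, 64L, 64L, 64L, 64L))

  expect_error(buildEncoder(100L), "divisible by 16")
})

test_that("decoder inverts encoder shapes with outputs in [0, 1]", {
  set.seed(2)
  cae <- buildCAE(64L, seed = 3L)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3))
  rec <- reconstructPatches(cae, list(x))[[1]]
  expect_equal(dim(rec), dim(x))
  expect_true(all(rec >= 0 & rec <= 1))
  # untrained reconstruction is not the input
  expect_lt(ssim(x, rec), 1)
})

test_that("classifier head emits a 2-class softmax and a known size", {
  set.seed(4)
  clf <- buildPatchClassifier(64L, seed = 5L)
  ps <- makePatchSet(6L, H = 64L, seed = 6L)
  pr <- predictPatches(clf, ps)
  expect_equal(nrow(pr), 6L)
  expect_equal(pr$nonTumorProb + pr$tumorProb, rep(1, 6), tolerance = 1e-6)
  # inference is deterministic (dropout off)
  pr2 <- predictPatches(clf, ps)
  expect_identical(pr, pr2)
})

test_that("parameter counts match closed-form arithmetic", {
  countConv <- function(cin, cout, k) cout * k * k * cin + cout
  countBN <- function(c) 2 * c
  # encoder: stages (3->16), (16->16 s2), (16->32), (32->32 s2), ...
  depths <- c(16, 32, 64, 64)
  cin <- 3
  encN <- 0
  for (d in depths) {
    encN <- encN + countConv(cin, d, 3) + countBN(d) +
      countConv(d, d, 3) + countBN(d)
    cin <- d
  }
  enc <- buildEncoder(64L)
  expect_equal(histocae:::nnNumParams(enc), encN)

  # single-resolution head on a 4 x 4 x 64 bottleneck:
  # conv 3x3 s2 64->64 + BN + dense (2*2*64 -> 2)
  headN <- countConv(64, 64, 3) + countBN(64) + (2 * 2 * 64) * 2 + 2
  head <- buildClassifierHead(c(4L, 4L, 64L))
  expect_equal(histocae:::nnNumParams(head), headN)

  # deterministic and seed-independent
  m1 <- buildPatchClassifier(64L, seed = 1L)
  m2 <- buildPatchClassifier(64L, seed = 99L)
  expect_equal(numParameters(m1), numParameters(m2))
})

test_that("MR classifier hits the 512/1536 flatten contracts", {
  set.seed(6)
  mr <- buildMRClassifier(c(16L, 16L, 64L))
  expect_equal(mr$branchFlattenLength, 512L)
  expect_equal(mr$concatLength, 1536L)

  # spatial trace by stride-2 same-padding arithmetic: 16 -> 8 -> 4 -> 2 -> 1
  trace <- 16L
  for (i in 1:4) trace <- c(trace, as.integer(ceiling(tail(trace, 1) / 2)))
  expect_equal(trace, c(16L, 8L, 4L, 2L, 1L))
  convs <- Filter(function(l) l$kind == "conv", mr$branches[[1]])
  expect_equal(vapply(convs, function(l) l$outH, integer(1)), trace[-1])
  expect_equal(vapply(convs, function(l) l$Cout, integer(1)),
               c(128L, 256L, 512L, 512L))

  # a forward pass through one branch really flattens to 512
  z <- matrix(runif(16 * 16 * 64), ncol = 1)
  flat <- histocae:::nnForward(mr$branches[[1]], z)$out
  expect_equal(nrow(flat), 512L)

  # head softmax over the concatenated vector
  probs <- histocae:::nnForward(mr$head,
                                matrix(runif(1536 * 2), 1536, 2))$out
  expect_equal(colSums(probs), c(1, 1), tolerance = 1e-6)
})

test_that("encoder weight transfer is bit-exact and guarded", {
  set.seed(7)
  cae <- buildCAE(32L, seed = 11L)
  clf <- buildPatchClassifier(32L, seed = 22L)
  expect_gt(histocae:::nnMaxParamDiff(cae@encoder, clf@encoder), 0)
  clf2 <- transferEncoderWeights(cae, clf)
  expect_equal(histocae:::nnMaxParamDiff(cae@encoder, clf2@encoder), 0)

  # mismatched depths error names the first differing stage
  bad <- buildPatchClassifier(32L, depths = c(16L, 32L, 64L, 128L))
  expect_error(transferEncoderWeights(cae, bad), "stage 4")
  bad2 <- buildPatchClassifier(64L)
  expect_error(transferEncoderWeights(cae, bad2), "input size")
})

test_that("describeModel reports layer shapes and parameter totals", {
  cae <- buildCAE(32L, seed = 1L)
  tab <- describeModel(cae)
  expect_true(any(tab$output == "2x2x64"))  # bottleneck of a 32-px model
  expect_equal(sum(tab$params), numParameters(cae))
})
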