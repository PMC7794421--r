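test_that("mseLoss matches the double-loop oracle in both modes", {
  x <- matrix(c(1, 0.5, 0, 0), 1)
  y <- matrix(0, 1, 4)
  expect_equal(mseLoss(x, y, "literal_sum"), 1.25)
  expect_equal(mseLoss(x, y, "per_pixel_mean"), 0.3125)
  expect_equal(mseLoss(x, x), 0)
  # homogeneity: doubling differences quadruples the loss
  expect_equal(mseLoss(2 * x, 2 * y, "literal_sum"),
               4 * mseLoss(x, y, "literal_sum"))
  set.seed(42)
  for (i in 1:5) {
    a <- matrix(runif(16), 4)
    b <- matrix(runif(16), 4)
    expect_equal(mseLoss(a, b, "literal_sum"), oracleMse(a, b),
                 tolerance = 1e-10)
    expect_equal(mseLoss(a, b, "per_pixel_mean"), oracleMse(a, b) / 16,
                 tolerance = 1e-10)
  }
  expect_error(mseLoss(matrix(0, 2, 2), matrix(0, 2, 3)), "mismatch")
})

test_that("maeLoss is the batch mean absolute difference", {
  x <- matrix(c(0.5, 0.5, 0, 0), 1)
  y <- matrix(0, 1, 4)
  expect_equal(maeLoss(x, y), 0.25)
  expect_equal(maeLoss(x, x), 0)
  expect_equal(maeLoss(y, x), maeLoss(x, y))  # sign invariance
  set.seed(43)
  for (i in 1:5) {
    a <- matrix(runif(16), 4)
    b <- matrix(runif(16), 4)
    expect_equal(maeLoss(a, b), oracleMae(a, b), tolerance = 1e-10)
  }
  expect_error(maeLoss(matrix(0, 2, 2), matrix(0, 3, 2)), "mismatch")
})

test_that("ssim matches its closed forms and the windowed oracle", {
  cfg <- ssimConfig()
  set.seed(7)
  x <- matrix(runif(32 * 32), 32)
  expect_equal(ssim(x, x, cfg), 1)

  # two distinct constant images: closed-form luminance term
  c1 <- 0.3; c2 <- 0.7
  a <- matrix(c1, 16, 16)
  b <- matrix(c2, 16, 16)
  C1 <- (cfg@k1 * cfg@dynamicRange)^2
  expect_equal(ssim(a, b, cfg), (2 * c1 * c2 + C1) / (c1^2 + c2^2 + C1),
               tolerance = 1e-12)

  # symmetry and agreement with the naive reference on noisy pairs
  y <- pmin(pmax(x + rnorm(length(x), sd = 0.1), 0), 1)
  expect_equal(ssim(x, y, cfg), ssim(y, x, cfg), tolerance = 1e-12)
  small <- ssimConfig(windowSize = 7L)
  xs <- x[1:12, 1:12]; ys <- y[1:12, 1:12]
  expect_equal(ssim(xs, ys, small), oracleSsim(xs, ys, small),
               tolerance = 1e-12)
  uni <- ssimConfig(windowSize = 7L, windowKind = "uniform")
  expect_equal(ssim(xs, ys, uni), oracleSsim(xs, ys, uni),
               tolerance = 1e-12)

  expect_gt(ssim(x, y, cfg), -1)
  expect_lt(ssim(x, y, cfg), 1)
  expect_error(ssim(matrix(0.1, 5, 5), matrix(0.2, 5, 5), cfg), "window")
})

test_that("ssimLoss is 1 - ssim and vanishes at identity", {
  set.seed(8)
  x <- matrix(runif(32 * 32), 32)
  y <- pmin(pmax(x + rnorm(length(x), sd = 0.05), 0), 1)
  cfg <- ssimConfig()
  expect_equal(ssimLoss(x, x, cfg), 0)
  expect_equal(ssimLoss(x, y, cfg), 1 - ssim(x, y, cfg))
  expect_equal(ssimLoss(x, y, cfg), 1 - oracleSsim(x, y, cfg),
               tolerance = 1e-12)
})

test_that("ssim gradient agrees with finite differences", {
  set.seed(12)
  cfg <- ssimConfig(windowSize = 7L)
  x <- matrix(runif(144), 12)
  y <- pmin(pmax(x + rnorm(144, sd = 0.1), 0.01), 0.99)
  g <- histocae:::ssimGrad(x, y, cfg)
  h <- 1e-6
  for (i in sample(144, 6)) {
    yp <- y; yp[i] <- yp[i] + h
    ym <- y; ym[i] <- ym[i] - h
    num <- (ssim(x, yp, cfg) - ssim(x, ym, cfg)) / (2 * h)
    expect_equal(g[i], num, tolerance = 1e-5)
  }
})

test_that("joint loss recomposes from its components and weights", {
  cfg <- lossConfig()
  set.seed(9)
  xs <- lapply(1:8, function(i) array(runif(16 * 16 * 3), c(16, 16, 3)))
  ys <- lapply(xs, function(a) pmin(pmax(a + rnorm(length(a), sd = 0.05),
                                         0), 1))
  scfg <- ssimConfig(windowSize = 7L)
  cfg <- lossConfig(ssim = scfg)
  jl <- jointReconstructionLoss(xs, ys, cfg)
  # independently computed components
  xm <- simplify2array(xs); ym <- simplify2array(ys)
  m <- mseLoss(xm, ym, "per_pixel_mean")
  s <- mean(mapply(function(a, b) ssimLoss(a, b, scfg), xs, ys))
  a <- maeLoss(xm, ym)
  expect_equal(as.numeric(jl), 0.5 * (m + s + a), tolerance = 1e-12)
  expect_equal(unname(attr(jl, "components")), c(m, s, a),
               tolerance = 1e-12)

  expect_equal(as.numeric(jointReconstructionLoss(xs, xs, cfg)), 0)

  # linearity in each weight
  for (w in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
    cw <- lossConfig(alpha = w[1], beta = w[2], gamma = w[3], ssim = scfg)
    expect_equal(as.numeric(jointReconstructionLoss(xs, ys, cw)),
                 sum(w * c(m, s, a)), tolerance = 1e-12)
  }
  # the seven variants are expressible by zeroing weights
  variants <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 0),
                   c(1, 0, 1), c(0, 1, 1), c(1, 1, 1))
  for (w in variants) {
    cw <- lossConfig(alpha = w[1], beta = w[2], gamma = w[3], ssim = scfg)
    expect_equal(as.numeric(jointReconstructionLoss(xs, ys, cw)),
                 sum(w * c(m, s, a)), tolerance = 1e-12)
  }
})

test_that("cross-entropy matches direct evaluation and clamps zeros", {
  expect_equal(crossEntropyLoss(NULL, c(1, 1, 1)), 0)
  expect_equal(crossEntropyLoss(NULL, c(0.5, 0.5)), log(2))
  expect_equal(crossEntropyLoss(NULL, c(0.9, 0.8, 0.5)),
               -(log(0.9) + log(0.8) + log(0.5)) / 3)
  # matrix + labels interface
  P <- rbind(c(0.9, 0.1), c(0.2, 0.8))
  colnames(P) <- c("non_tumor", "tumor")
  expect_equal(crossEntropyLoss(c("non_tumor", "tumor"), P),
               -(log(0.9) + log(0.8)) / 2)
  # clamped, finite on saturated predictions
  expect_true(is.finite(crossEntropyLoss(NULL, c(0, 1))))
  expect_equal(crossEntropyLoss(NULL, 0), -log(1e-12))
})

test_that("losses are nonnegative on random batches", {
  set.seed(10)
  for (i in 1:5) {
    a <- array(runif(12 * 12 * 3), c(12, 12, 3))
    b <- array(runif(12 * 12 * 3), c(12, 12, 3))
    cfg <- lossConfig(ssim = ssimConfig(windowSize = 7L))
    expect_gte(as.numeric(jointReconstructionLoss(a, b, cfg)), 0)
    expect_gte(mseLoss(a, b), 0)
    expect_gte(maeLoss(a, b), 0)
    expect_gte(ssimLoss(a, b, cfg@ssim), 0)
  }
})
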