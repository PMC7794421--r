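test_that("assembleMask paints exactly the tumor cells", {
  grid <- tileSlide(slideImage(array(0.5, c(512, 512, 3)), "a"),
                    patchSize = 256L)$grid
  m0 <- assembleMask(grid, rep("non_tumor", 4L))
  expect_true(all(m0@pixels == 0L))

  # cells are row-major: (0,0), (0,1), (1,0), (1,1)
  labels <- c("non_tumor", "tumor", "non_tumor", "non_tumor")
  m1 <- assembleMask(grid, labels)
  expect_equal(sum(m1@pixels), 256L * 256L)  # 65536 tumor pixels
  expect_true(all(m1@pixels[1:256, 257:512] == 1L))
  expect_true(all(m1@pixels[257:512, ] == 0L))
  expect_true(all(m1@pixels[, 1:256] == 0L))

  # re-tiling the block mask recovers the labels at any threshold <= 1
  relab <- tileSlide(slideImage(array(0, c(512, 512, 3)), "a"),
                     patchSize = 256L,
                     mask = m1)$patches@info$label
  expect_equal(relab, labels)

  expect_error(assembleMask(grid, labels[1:3]), "\\(1, 1\\)")
})

test_that("dice matches set arithmetic with sensible limits", {
  A <- matrix(0L, 8, 8); A[1:4] <- 1L
  expect_equal(dice(A, A), 1)
  B <- matrix(0L, 8, 8); B[60:63] <- 1L
  expect_equal(dice(A, B), 0)
  # |A| = 4, |B| = 4, |A intersect B| = 2
  C <- matrix(0L, 8, 8); C[3:6] <- 1L
  expect_equal(dice(A, C), 0.5)
  # both empty: perfect-agreement limit
  expect_equal(dice(matrix(0L, 4, 4), matrix(0L, 4, 4)), 1)
  expect_error(dice(matrix(0L, 4, 4), matrix(0L, 4, 5)), "mismatch")
})

test_that("dice is symmetric and equals 2J/(1+J)", {
  set.seed(51)
  for (i in 1:8) {
    a <- matrix(rbinom(100, 1, 0.4), 10)
    b <- matrix(rbinom(100, 1, 0.4), 10)
    if (sum(a) + sum(b) == 0) next
    expect_equal(dice(a, b), dice(b, a))
    inter <- sum(a * b)
    uni <- sum(pmax(a, b))
    J <- inter / uni
    expect_equal(dice(a, b), 2 * J / (1 + J), tolerance = 1e-12)
  }
})

test_that("classificationReport matches the contingency-table oracle", {
  perfect <- classificationReport(c("tumor", "non_tumor"),
                                  c("tumor", "non_tumor"))
  expect_equal(accuracy(perfect), 1)
  expect_true(all(perClassMetrics(perfect)$precision == 1))
  expect_true(all(perClassMetrics(perfect)$f1 == 1))

  # TP=40, FP=10, FN=20, TN=30 with tumor as positive
  truth <- c(rep("tumor", 60), rep("non_tumor", 40))
  pred <- c(rep("tumor", 40), rep("non_tumor", 20),
            rep("tumor", 10), rep("non_tumor", 30))
  rep1 <- classificationReport(truth, pred)
  pc <- perClassMetrics(rep1)
  expect_equal(pc["tumor", "precision"], 40 / 50)
  expect_equal(pc["tumor", "recall"], 40 / 60)
  expect_equal(pc["tumor", "f1"],
               2 * (0.8 * (2 / 3)) / (0.8 + 2 / 3))
  expect_equal(accuracy(rep1), 0.7)
  expect_equal(sum(rep1@confusion), 100)

  # swapping the positive-class convention swaps the per-class rows
  flip <- function(x) ifelse(x == "tumor", "non_tumor", "tumor")
  rep2 <- classificationReport(flip(truth), flip(pred))
  expect_equal(perClassMetrics(rep2)["non_tumor", "precision"],
               pc["tumor", "precision"])
  expect_equal(perClassMetrics(rep2)["tumor", "recall"],
               pc["non_tumor", "recall"])

  expect_error(classificationReport(character(0), character(0)), "empty")
})

test_that("accuracy equals the label-weighted mean of per-class recalls", {
  set.seed(52)
  for (i in 1:5) {
    truth <- sample(c("tumor", "non_tumor"), 60, replace = TRUE)
    pred <- sample(c("tumor", "non_tumor"), 60, replace = TRUE)
    r <- classificationReport(truth, pred)
    pc <- perClassMetrics(r)
    w <- table(factor(truth, c("non_tumor", "tumor"))) / length(truth)
    expect_equal(accuracy(r),
                 sum(pc[c("non_tumor", "tumor"), "recall"] * as.numeric(w)),
                 tolerance = 1e-12)
  }
})

test_that("zero-denominator ratios are reported as 0 and flagged", {
  r <- classificationReport(rep("non_tumor", 5),
                            rep("non_tumor", 5))
  pc <- perClassMetrics(r)
  expect_equal(pc["tumor", "precision"], 0)
  expect_true(pc["tumor", "flagged"])
  expect_equal(accuracy(r), 1)
})

test_that("oracle labels give dice exactly 1 against block truth", {
  spec <- synthSpec(seed = 53L, dims = 512L)
  sl <- generateSlide(spec)
  tiled <- tileSlide(sl$images[["20x"]], patchSize = 32L,
                     mask = sl$masks[["20x"]])
  oracleMask <- assembleMask(tiled$grid, tiled$patches@info$label)
  bq <- blockQuantizeMask(sl$masks[["20x"]], tiled$grid)
  expect_equal(dice(oracleMask, bq), 1)

  r <- evaluateMask(oracleMask, sl$masks[["20x"]], grid = tiled$grid,
                    blockQuantized = TRUE)
  expect_equal(r@dice, 1)
  expect_equal(accuracy(r), 1)
  # against the raw mask the dice is high but below 1 (block effects)
  r2 <- evaluateMask(oracleMask, sl$masks[["20x"]])
  expect_lt(r2@dice, 1)
  expect_gt(r2@dice, 0.6)
})
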