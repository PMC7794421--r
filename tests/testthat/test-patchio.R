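test_that("tileSlide produces the exact full-patch grid", {
  set.seed(11)
  mk <- function(D) slideImage(array(runif(D * D * 3), c(D, D, 3L)), "s")

  t1 <- tileSlide(mk(512L), patchSize = 256L)
  expect_equal(gridDims(t1$grid), c(2L, 2L))
  expect_length(t1$patches@pixels, 4L)

  s <- mk(256L)
  t2 <- tileSlide(s, patchSize = 256L)
  expect_length(t2$patches@pixels, 1L)
  expect_identical(t2$patches@pixels[[1]], s@pixels)

  # border strips dropped: verify against brute-force enumeration
  s600 <- mk(600L)
  t3 <- tileSlide(s600, patchSize = 256L)
  oc <- oracleTileCells(600L, 600L, 256L)
  expect_equal(nrow(t3$grid@cells), nrow(oc))
  expect_equal(unname(t3$grid@cells[, "row"]), oc$row)
  expect_equal(unname(t3$grid@cells[, "col"]), oc$col)
  # patches are pixel-exact crops
  i <- 4L
  r0 <- t3$grid@cells[i, "row"] * 256L
  c0 <- t3$grid@cells[i, "col"] * 256L
  expect_identical(t3$patches@pixels[[i]],
                   s600@pixels[(r0 + 1):(r0 + 256), (c0 + 1):(c0 + 256), ,
                               drop = FALSE])
})

test_that("patch count equals floor(H/stride) * floor(W/stride)", {
  set.seed(3)
  for (i in 1:6) {
    H <- sample(40:200, 1)
    W <- sample(40:200, 1)
    ps <- sample(c(16L, 32L, 48L), 1)
    s <- slideImage(array(runif(H * W * 3), c(H, W, 3L)), "p")
    tl <- suppressWarnings(tileSlide(s, patchSize = ps))
    expect_length(tl$patches@pixels, (H %/% ps) * (W %/% ps))
  }
})

test_that("tile then stitch reproduces multiple-of-patch slides bit-exactly", {
  set.seed(5)
  s <- slideImage(array(runif(128 * 192 * 3), c(128L, 192L, 3L)), "rt")
  tl <- tileSlide(s, patchSize = 64L)
  back <- stitchPatches(tl$patches, tl$grid)
  expect_identical(back@pixels, s@pixels)
})

test_that("tiling guards: stride, undersized slides", {
  s <- slideImage(array(0.5, c(64L, 64L, 3L)), "g")
  expect_error(tileSlide(s, patchSize = 32L, stride = 16L), "stride")
  small <- slideImage(array(0.5, c(20L, 20L, 3L)), "tiny")
  expect_warning(res <- tileSlide(small, patchSize = 32L), "smaller")
  expect_length(res$patches@pixels, 0L)
  expect_equal(gridDims(res$grid), c(0L, 0L))
})

test_that("labelPatch applies the inclusive 30% rule", {
  expect_equal(labelPatch(matrix(0L, 256, 256)),
               list(label = "non_tumor", tumorFraction = 0))
  # exactly 30%: inclusive
  m <- matrix(0L, 10, 10)
  m[1:30] <- 1L
  lp <- labelPatch(m)
  expect_equal(lp$label, "tumor")
  expect_equal(lp$tumorFraction, 0.30)
  # hand pixel-count oracle on 4x4
  m5 <- matrix(0L, 4, 4); m5[1:5] <- 1L
  expect_equal(labelPatch(m5), list(label = "tumor", tumorFraction = 0.3125))
  m4 <- matrix(0L, 4, 4); m4[1:4] <- 1L
  expect_equal(labelPatch(m4),
               list(label = "non_tumor", tumorFraction = 0.25))
  expect_error(labelPatch(matrix(0L, 0, 0)), "empty")
})

test_that("labelPatch is monotone in tumor pixels", {
  set.seed(9)
  for (i in 1:10) {
    m <- matrix(rbinom(64, 1, 0.3), 8, 8)
    lab1 <- labelPatch(m)$label
    zero <- which(m == 0)
    if (length(zero) == 0) next
    m[sample(zero, 1)] <- 1L
    lab2 <- labelPatch(m)$label
    expect_false(lab1 == "tumor" && lab2 == "non_tumor")
  }
})

test_that("closeSmallRegions fills small enclosed holes only", {
  # all-foreground unchanged
  full <- matrix(1L, 20, 20)
  expect_identical(closeSmallRegions(full), full)

  # enclosed 3x3 hole (area 9) filled; area-51 hole untouched
  m <- matrix(1L, 30, 30)
  m[5:7, 5:7] <- 0L                       # area 9
  m[15:17, 10:26] <- 0L                   # area 51
  out <- closeSmallRegions(m, maxArea = 50L)
  expect_true(all(out[5:7, 5:7] == 1L))
  expect_true(all(out[15:17, 10:26] == 0L))

  # area exactly 50 is filled (inclusive bound)
  m2 <- matrix(1L, 30, 30)
  m2[10:14, 10:19] <- 0L                  # area 50
  expect_true(all(closeSmallRegions(m2, 50L)[10:14, 10:19] == 1L))

  # border-touching background never filled
  m3 <- matrix(1L, 10, 10)
  m3[1, 1:3] <- 0L
  expect_identical(closeSmallRegions(m3, 50L), m3)
})

test_that("closeSmallRegions is idempotent and leaves no small holes", {
  set.seed(21)
  for (i in 1:5) {
    m <- matrix(as.integer(runif(40 * 40) < 0.65), 40, 40)
    out <- closeSmallRegions(m, maxArea = 12L)
    expect_true(all(out >= m))  # foreground never removed
    expect_identical(closeSmallRegions(out, maxArea = 12L), out)
    # component-area oracle: no enclosed background component <= 12 remains
    comps <- oracleComponents(out, 0L)
    for (cp in comps) {
      if (!cp$border) expect_gt(cp$size, 12L)
    }
  }
})

test_that("closeSmallRegions works on MaskImage objects", {
  m <- matrix(1L, 12, 12)
  m[6:7, 6:7] <- 0L
  mask <- maskImage(m, "s", "10x")
  out <- closeSmallRegions(mask)
  expect_s4_class(out, "MaskImage")
  expect_equal(out@magnification, "10x")
  expect_true(all(out@pixels == 1L))
})

test_that("extractMultiRes maps centers by truncated halving", {
  pyr <- makePyramid(1024L)
  s <- extractMultiRes(pyr, c(512L, 512L), patchSize = 64L)
  expect_s4_class(s, "MultiResSample")
  expect_equal(s@center, c(512L, 512L))
  expect_equal(dim(s@pixels[["10x"]]), c(64L, 64L, 3L))
  expect_equal(dim(s@pixels[["5x"]]), c(64L, 64L, 3L))

  # integer-division oracle for odd centers
  s2 <- extractMultiRes(pyr, c(511L, 511L), patchSize = 64L)
  expect_equal(as.integer(trunc(c(511, 511) / 2)), c(255L, 255L))
  expect_equal(as.integer(trunc(c(511, 511) / 4)), c(127L, 127L))
  # patch content at 5x is centered at (127,127): extract manually
  half <- 32L
  ref <- pyr[["5x"]]@pixels[(127 - half + 1):(127 + half),
                            (127 - half + 1):(127 + half), , drop = FALSE]
  expect_identical(s2@pixels[["5x"]], ref)

  expect_error(extractMultiRes(pyr, c(100L, 100L), patchSize = 256L),
               "5x")
})

test_that("slide and mask round-trip through TIFF/PNG", {
  set.seed(4)
  px <- array(runif(32 * 48 * 3), c(32L, 48L, 3L))
  s <- slideImage(px, "io", "10x")
  f <- withr::local_tempfile(fileext = ".tiff")
  writeSlide(s, f)
  back <- readSlide(f, magnification = "10x")
  expect_equal(back@pixels, px, tolerance = 1e-4)

  m <- maskImage(matrix(as.integer(runif(32 * 48) < 0.4), 32, 48), "io")
  fm <- withr::local_tempfile(fileext = ".png")
  writeMask(m, fm)
  expect_identical(readMask(fm)@pixels, m@pixels)
})

test_that("writePatches emits a complete manifest", {
  ps <- makePatchSet(4L, H = 16L)
  dir <- withr::local_tempdir()
  man <- writePatches(ps, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_equal(nrow(man), 4L)
  expect_true(all(file.exists(man$path)))
})
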