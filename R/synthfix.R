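# Deterministic synthetic multi-resolution slides with tumor-blob masks,
# so every pipeline stage is exercisable without any external data. The
# fixture emulates the geometry of a scanned H&E slide — a light tissue
# texture with darker, smoothly shaped tumor blobs occupying a target area
# fraction — not its histology.

.blockHalve <- function(m) {
  # 2x2 block sums of a matrix with even dimensions
  a <- m[seq(1L, nrow(m), 2L), , drop = FALSE] +
    m[seq(2L, nrow(m), 2L), , drop = FALSE]
  a[, seq(1L, ncol(m), 2L), drop = FALSE] +
    a[, seq(2L, ncol(m), 2L), drop = FALSE]
}

.downsampleImage <- function(px) {
  # area averaging, one pyramid step (2x)
  d <- dim(px)
  out <- array(0, c(d[1] %/% 2L, d[2] %/% 2L, d[3]))
  for (ch in seq_len(d[3])) out[, , ch] <- .blockHalve(px[, , ch]) / 4
  out
}

.downsampleMask <- function(m) {
  # majority vote per 2x2 block; ties (2 of 4) go to tumor so thin
  # structures survive the pyramid
  (.blockHalve(m) >= 2L) * 1L
}

.drawBlob <- function(D, center, radius, axisRatio, angle) {
  # filled rotated ellipse as a logical matrix
  r <- ceiling(radius * max(1, axisRatio)) + 1L
  r1 <- max(1L, center[1] - r); r2 <- min(D, center[1] + r)
  c1 <- max(1L, center[2] - r); c2 <- min(D, center[2] + r)
  rows <- r1:r2
  cols <- c1:c2
  dr <- outer(rows - center[1], rep(1, length(cols)))
  dc <- outer(rep(1, length(rows)), cols - center[2])
  u <- cos(angle) * dr + sin(angle) * dc
  v <- -sin(angle) * dr + cos(angle) * dc
  inside <- (u / radius)^2 + (v / (radius * axisRatio))^2 <= 1
  list(rows = rows, cols = cols, inside = inside)
}

#' Generate a synthetic 5x/10x/20x slide pyramid with tumor masks
#'
#' Tumor regions are smooth elliptical blobs whose texture (base color)
#' differs from the tissue background by a fixed gap, plus i.i.d. pixel
#' noise, so tumor and tissue patches are separable by construction. Blobs
#' are added until the target tumor fraction is reached (achieved fraction
#' within 0.05 of the target, else an error). Lower pyramid levels are
#' produced by exact 2x area averaging (images) and 2x2 majority vote
#' (masks). Output is fully determined by the seed.
#'
#' @param spec a \linkS4class{SynthSpec}.
#' @return list with elements \code{images} and \code{masks}: named lists
#'   ("20x", "10x", "5x") of \linkS4class{SlideImage}s /
#'   \linkS4class{MaskImage}s.
#' @export
generateSlide <- function(spec) {
  set.seed(spec@seed)
  D <- spec@dims
  id <- sprintf("synth%04d", spec@seed)
  m <- matrix(0L, D, D)
  target <- spec@tumorFraction
  for (i in seq_len(spec@nBlobs)) {
    if (mean(m) >= target - 0.01) break
    ctr <- sample.int(D, 2L)
    rad <- runif(1, spec@radiusRange[1], spec@radiusRange[2])
    b <- .drawBlob(D, ctr, rad, axisRatio = runif(1, 0.6, 1.4),
                   angle = runif(1, 0, pi))
    m[b$rows, b$cols][b$inside] <- 1L
  }
  achieved <- mean(m)
  if (abs(achieved - target) > 0.05)
    stop(sprintf(
      "infeasible tumor fraction: target %.2f, achieved %.3f; adjust blob radius/count",
      target, achieved))
  px <- array(0, c(D, D, 3L))
  for (ch in 1:3) {
    base <- spec@tissueColor[ch] * (1 - m) + spec@tumorColor[ch] * m
    px[, , ch] <- pmin(pmax(base + rnorm(D * D, sd = spec@noiseAmp), 0), 1)
  }
  images <- list("20x" = slideImage(px, id, "20x"))
  masks <- list("20x" = maskImage(m, id, "20x"))
  p10 <- .downsampleImage(px)
  m10 <- .downsampleMask(m)
  images[["10x"]] <- slideImage(p10, id, "10x")
  masks[["10x"]] <- maskImage(m10, id, "10x")
  images[["5x"]] <- slideImage(.downsampleImage(p10), id, "5x")
  masks[["5x"]] <- maskImage(.downsampleMask(m10), id, "5x")
  list(images = images, masks = masks)
}

#' Generate a balanced labelled patch dataset from synthetic slides
#'
#' Slides are generated (seeds \code{spec@seed}, \code{spec@seed + 1}, ...)
#' and tiled at 20x with \code{\link{tileSlide}}; patches are labelled with
#' the 30\% rule. To keep the two classes separable by construction, the
#' dataset draws only patches whose tumor fraction is bounded away from the
#' label threshold (tumor: fraction >= \code{tumorMargin}; non-tumor:
#' fraction <= \code{tissueMargin}); patch-grid boundary ambiguity is
#' exercised through whole-slide mask evaluation instead.
#'
#' @param spec a \linkS4class{SynthSpec}.
#' @param nPerClass patches per class (>= 1).
#' @param labelThreshold tumor coverage threshold of the labelling rule.
#' @param tumorMargin,tissueMargin tumor-fraction bounds defining clearly
#'   tumor / clearly tissue patches.
#' @param maxSlides slides to generate before giving up.
#' @return a balanced \linkS4class{PatchSet} with 2 * nPerClass patches.
#' @export
generatePatchDataset <- function(spec, nPerClass,
                                 labelThreshold = 0.30,
                                 tumorMargin = 0.5, tissueMargin = 0.1,
                                 maxSlides = 8L) {
  stopifnot(nPerClass >= 1L)
  pxT <- list(); pxN <- list()
  infoT <- list(); infoN <- list()
  for (k in seq_len(maxSlides)) {
    sl <- generateSlide(new("SynthSpec", seed = spec@seed + k - 1L,
                            dims = spec@dims, nBlobs = spec@nBlobs,
                            radiusRange = spec@radiusRange,
                            tumorFraction = spec@tumorFraction,
                            tissueColor = spec@tissueColor,
                            tumorColor = spec@tumorColor,
                            noiseAmp = spec@noiseAmp,
                            patchSize = spec@patchSize))
    tiled <- tileSlide(sl$images[["20x"]], patchSize = spec@patchSize,
                       mask = sl$masks[["20x"]],
                       labelThreshold = labelThreshold)
    info <- tiled$patches@info
    isT <- info$label == "tumor" & info$tumorFraction >= tumorMargin
    isN <- info$label == "non_tumor" & info$tumorFraction <= tissueMargin
    pxT <- c(pxT, tiled$patches@pixels[isT])
    pxN <- c(pxN, tiled$patches@pixels[isN])
    infoT <- c(infoT, list(info[isT, , drop = FALSE]))
    infoN <- c(infoN, list(info[isN, , drop = FALSE]))
    if (length(pxT) >= nPerClass && length(pxN) >= nPerClass) break
  }
  if (length(pxT) < nPerClass || length(pxN) < nPerClass)
    stop("not enough qualifying patches (", length(pxT), " tumor, ",
         length(pxN), " non-tumor); increase dims or lower nPerClass")
  infoT <- do.call(rbind, infoT)
  infoN <- do.call(rbind, infoN)
  set.seed(spec@seed)
  selT <- sample(length(pxT), nPerClass)
  selN <- sample(length(pxN), nPerClass)
  info <- rbind(infoT[selT, , drop = FALSE], infoN[selN, , drop = FALSE])
  rownames(info) <- NULL
  new("PatchSet", pixels = c(pxT[selT], pxN[selN]), info = info,
      patchSize = spec@patchSize)
}

#' Sample balanced multi-resolution training samples from one slide
#'
#' Random 20x centers are drawn, co-registered patch triplets extracted
#' with \code{\link{extractMultiRes}}, and accepted into per-class quotas
#' using the same clear-margin rule as \code{\link{generatePatchDataset}}.
#'
#' @param slide output of \code{\link{generateSlide}}.
#' @param nPerClass samples per class.
#' @param patchSize patch edge length at every level.
#' @param seed integer seed for center sampling.
#' @param labelThreshold tumor coverage threshold.
#' @param tumorMargin,tissueMargin clear-margin bounds on tumor fraction.
#' @return list of 2 * nPerClass \linkS4class{MultiResSample}s.
#' @export
sampleMultiResDataset <- function(slide, nPerClass, patchSize = 32L,
                                  seed = 1L, labelThreshold = 0.30,
                                  tumorMargin = 0.5, tissueMargin = 0.1) {
  set.seed(seed)
  D <- dim(slide$images[["20x"]]@pixels)[1]
  half <- patchSize %/% 2L
  lo <- 4L * (half + 2L)
  hi <- 4L * ((D %/% 4L) - half - 1L)
  gotT <- list(); gotN <- list()
  tries <- 0L
  while ((length(gotT) < nPerClass || length(gotN) < nPerClass) &&
         tries < 200L * nPerClass) {
    tries <- tries + 1L
    ctr <- as.integer(round(runif(2, lo, hi)))
    s <- extractMultiRes(slide$images, ctr, patchSize,
                         masks = slide$masks,
                         labelThreshold = labelThreshold)
    tf <- s@info$tumorFraction[s@info$magnification == "20x"]
    if (s@label == "tumor" && tf >= tumorMargin &&
        length(gotT) < nPerClass) {
      gotT <- c(gotT, list(s))
    } else if (s@label == "non_tumor" && tf <= tissueMargin &&
               length(gotN) < nPerClass) {
      gotN <- c(gotN, list(s))
    }
  }
  if (length(gotT) < nPerClass || length(gotN) < nPerClass)
    stop("could not sample enough clear multi-resolution patches")
  c(gotT, gotN)
}
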