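# Slide tiling, patch labelling, mask preprocessing and co-registered
# multi-resolution patch extraction.

#' Read an RGB slide image from TIFF or PNG
#'
#' Intensities are normalised to [0, 1] regardless of source bit depth;
#' grayscale sources are replicated over three channels.
#'
#' @param path path to a TIFF or PNG file.
#' @param slideId slide identifier; defaults to the file name.
#' @param magnification one of "5x", "10x", "20x".
#' @return a \linkS4class{SlideImage}
#' @export
readSlide <- function(path, slideId = NULL,
                      magnification = "20x") {
  if (is.null(slideId))
    slideId <- sub("\\.[^.]*$", "", basename(path))
  img <- EBImage::readImage(path)
  d <- EBImage::imageData(img)
  # EBImage stores (x, y[, channel]); transpose to (row, col, channel)
  if (length(dim(d)) == 2L) {
    d <- t(d)
    d <- array(rep(d, 3L), c(dim(d), 3L))
  } else {
    d <- aperm(d[, , 1:3, drop = FALSE], c(2L, 1L, 3L))
  }
  d <- pmin(pmax(d, 0), 1)
  slideImage(d, slideId = slideId, magnification = magnification)
}

#' Read a binary tumor mask from a single-channel PNG/TIFF
#'
#' Pixel values {0, 255} (or {0, 1}) are mapped to {0, 1}.
#'
#' @inheritParams readSlide
#' @return a \linkS4class{MaskImage}
#' @export
readMask <- function(path, slideId = NULL, magnification = "20x") {
  if (is.null(slideId))
    slideId <- sub("\\.[^.]*$", "", basename(path))
  d <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(d)) == 3L) d <- d[, , 1]
  m <- t(d)
  maskImage((m > 0.5) * 1L, slideId = slideId, magnification = magnification)
}

#' Write a SlideImage to TIFF or PNG
#' @param slide a \linkS4class{SlideImage}
#' @param path output path; format chosen by extension.
#' @export
writeSlide <- function(slide, path) {
  d <- aperm(slide@pixels, c(2L, 1L, 3L))
  EBImage::writeImage(EBImage::Image(d, colormode = "Color"), path)
  invisible(path)
}

#' Write a MaskImage as a single-channel PNG ({0,1} mapped to {0,255})
#' @param mask a \linkS4class{MaskImage}
#' @param path output path.
#' @export
writeMask <- function(mask, path) {
  EBImage::writeImage(EBImage::Image(t(mask@pixels)), path)
  invisible(path)
}

#' Label one patch from its mask patch by tumor-pixel coverage
#'
#' A patch is labelled tumor when 30\% or more of its area is covered by
#' tumor pixels (the threshold is inclusive).
#'
#' @param maskPatch 2-D binary array (1 = tumor pixel).
#' @param threshold coverage fraction at or above which the patch is tumor.
#' @return list with elements \code{label} ("tumor"/"non_tumor") and
#'   \code{tumorFraction} in [0, 1].
#' @export
labelPatch <- function(maskPatch, threshold = 0.30) {
  if (length(maskPatch) == 0L) stop("labelPatch: empty mask patch")
  if (!all(maskPatch %in% c(0, 1))) stop("labelPatch: mask must be binary")
  tf <- sum(maskPatch) / length(maskPatch)
  list(label = if (tf >= threshold) "tumor" else "non_tumor",
       tumorFraction = tf)
}

#' Tile a slide into a uniform grid of non-overlapping patches
#'
#' Patches are pixel-exact crops on a row-major, 0-based grid with top-left
#' origin. Border strips narrower than \code{patchSize} are dropped, so the
#' patch count is floor(H / patchSize) * floor(W / patchSize). When a mask
#' is supplied each patch is labelled with \code{\link{labelPatch}};
#' otherwise labels are "unlabeled".
#'
#' @param slide a \linkS4class{SlideImage}.
#' @param patchSize patch edge length, pixels.
#' @param stride grid stride; must equal \code{patchSize}.
#' @param mask optional aligned \linkS4class{MaskImage}.
#' @param labelThreshold coverage threshold passed to
#'   \code{\link{labelPatch}}.
#' @return list with elements \code{grid} (a \linkS4class{TileGrid}) and
#'   \code{patches} (a \linkS4class{PatchSet}). A slide smaller than one
#'   patch yields an empty grid with a warning.
#' @export
tileSlide <- function(slide, patchSize = 256L, stride = patchSize,
                      mask = NULL, labelThreshold = 0.30) {
  patchSize <- as.integer(patchSize)
  stride <- as.integer(stride)
  if (patchSize < 1L) stop("patchSize must be >= 1")
  if (stride != patchSize)
    stop("stride must equal patchSize (non-overlapping tiling)")
  d <- dim(slide@pixels)
  H <- d[1]; W <- d[2]
  if (!is.null(mask) && !identical(dim(mask@pixels), c(H, W)))
    stop("mask shape does not match the slide")
  nR <- H %/% patchSize
  nC <- W %/% patchSize
  if (nR == 0L || nC == 0L) {
    warning("slide (", H, " x ", W, ") smaller than one ", patchSize,
            "-pixel patch; empty grid")
    nR <- 0L; nC <- 0L
  }
  cells <- if (nR > 0L) {
    cbind(row = rep(0:(nR - 1L), times = nC),
          col = rep(0:(nC - 1L), each = nR))
  } else {
    cbind(row = integer(0), col = integer(0))
  }
  # order cells row-major
  if (nrow(cells) > 0L)
    cells <- cells[order(cells[, "row"], cells[, "col"]), , drop = FALSE]
  grid <- new("TileGrid", slideId = slide@slideId, patchSize = patchSize,
              stride = stride, nRows = as.integer(nR),
              nCols = as.integer(nC), cells = cells)
  n <- nrow(cells)
  px <- vector("list", n)
  tf <- rep(NA_real_, n)
  lab <- rep("unlabeled", n)
  for (i in seq_len(n)) {
    r0 <- cells[i, "row"] * patchSize
    c0 <- cells[i, "col"] * patchSize
    px[[i]] <- slide@pixels[(r0 + 1L):(r0 + patchSize),
                            (c0 + 1L):(c0 + patchSize), , drop = FALSE]
    if (!is.null(mask)) {
      lp <- labelPatch(mask@pixels[(r0 + 1L):(r0 + patchSize),
                                   (c0 + 1L):(c0 + patchSize)],
                       labelThreshold)
      tf[i] <- lp$tumorFraction
      lab[i] <- lp$label
    }
  }
  info <- data.frame(slideId = rep(slide@slideId, n),
                     row = cells[, "row"], col = cells[, "col"],
                     magnification = rep(slide@magnification, n),
                     tumorFraction = tf, label = lab,
                     stringsAsFactors = FALSE)
  patches <- new("PatchSet", pixels = px, info = info,
                 patchSize = patchSize)
  list(grid = grid, patches = patches)
}

#' Stitch a PatchSet back into a slide by grid position
#'
#' The inverse of \code{\link{tileSlide}} on its tiled region: for slides
#' whose dimensions are exact multiples of the patch size the round trip is
#' bit-exact.
#'
#' @param patches a \linkS4class{PatchSet} with grid positions.
#' @param grid the \linkS4class{TileGrid} the patches came from.
#' @return a \linkS4class{SlideImage} of the tiled dimensions.
#' @export
stitchPatches <- function(patches, grid) {
  ps <- grid@patchSize
  out <- array(0, c(grid@nRows * ps, grid@nCols * ps, 3L))
  info <- patches@info
  for (i in seq_along(patches@pixels)) {
    r0 <- info$row[i] * ps
    c0 <- info$col[i] * ps
    out[(r0 + 1L):(r0 + ps), (c0 + 1L):(c0 + ps), ] <- patches@pixels[[i]]
  }
  slideImage(out, slideId = grid@slideId, magnification = "20x")
}

#' Fill small enclosed holes in a binary tumor mask
#'
#' Every background connected component (4-connectivity) that does not
#' touch the image border and has area at most \code{maxArea} pixels is
#' filled to foreground. Foreground pixels are never removed and
#' border-touching background is never filled. The operation is idempotent.
#'
#' @param mask a \linkS4class{MaskImage} or binary matrix.
#' @param maxArea inclusive area bound in pixels (default 50).
#' @return object of the same type as \code{mask}.
#' @export
closeSmallRegions <- function(mask, maxArea = 50L) {
  m <- if (is(mask, "MaskImage")) mask@pixels else mask
  if (!all(m %in% c(0, 1))) stop("mask must be binary")
  lab <- EBImage::bwlabel(1L - m)
  n <- max(lab)
  if (n > 0L) {
    areas <- tabulate(lab[lab > 0L], nbins = n)
    border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1],
                       lab[, ncol(lab)]))
    fill <- setdiff(which(areas <= maxArea), border)
    if (length(fill) > 0L) m[lab %in% fill] <- 1L
  }
  storage.mode(m) <- "integer"
  if (is(mask, "MaskImage")) {
    new("MaskImage", pixels = m, slideId = mask@slideId,
        magnification = mask@magnification)
  } else {
    m
  }
}

#' Extract co-registered patches from a 5x/10x/20x pyramid
#'
#' Patches of one common pixel size centered at the same physical location
#' are taken from the three magnifications: the 10x (5x) patch is centered
#' at \code{center/2} (\code{center/4}), rounded toward zero.
#'
#' @param pyramid named list of \linkS4class{SlideImage}s ("5x", "10x",
#'   "20x") related by exact 2x downsampling per step.
#' @param center integer (x, y) = (col, row) center at 20x, 1-based.
#' @param patchSize patch edge length at every level, pixels.
#' @param masks optional named list of aligned \linkS4class{MaskImage}s;
#'   when given, each magnification is labelled independently with the 30\%
#'   rule and the sample label is the one taken at 20x.
#' @param labelThreshold coverage threshold for labelling.
#' @return a \linkS4class{MultiResSample}
#' @export
extractMultiRes <- function(pyramid, center, patchSize = 256L,
                            masks = NULL, labelThreshold = 0.30) {
  mags <- c("5x", "10x", "20x")
  if (!all(mags %in% names(pyramid)))
    stop("pyramid must have levels 5x, 10x and 20x")
  patchSize <- as.integer(patchSize)
  d20 <- dim(pyramid[["20x"]]@pixels)[1:2]
  d10 <- dim(pyramid[["10x"]]@pixels)[1:2]
  d5 <- dim(pyramid[["5x"]]@pixels)[1:2]
  if (!identical(d10, d20 %/% 2L) || !identical(d5, d20 %/% 4L))
    stop("pyramid levels must be related by exact 2x downsampling")
  centers <- list("20x" = as.integer(center),
                  "10x" = as.integer(trunc(center / 2)),
                  "5x" = as.integer(trunc(center / 4)))
  half <- patchSize %/% 2L
  px <- list()
  lab <- character(0)
  tf <- numeric(0)
  for (mg in mags) {
    ctr <- centers[[mg]]
    dd <- dim(pyramid[[mg]]@pixels)
    r1 <- ctr[2] - half + 1L
    c1 <- ctr[1] - half + 1L
    r2 <- r1 + patchSize - 1L
    c2 <- c1 + patchSize - 1L
    if (r1 < 1L || c1 < 1L || r2 > dd[1] || c2 > dd[2])
      stop("patch at center (", ctr[1], ", ", ctr[2],
           ") extends past the border at level ", mg)
    px[[mg]] <- pyramid[[mg]]@pixels[r1:r2, c1:c2, , drop = FALSE]
    if (!is.null(masks)) {
      lp <- labelPatch(masks[[mg]]@pixels[r1:r2, c1:c2], labelThreshold)
      lab[mg] <- lp$label
      tf[mg] <- lp$tumorFraction
    } else {
      lab[mg] <- "unlabeled"
      tf[mg] <- NA_real_
    }
  }
  info <- data.frame(magnification = mags, label = lab[mags],
                     tumorFraction = tf[mags], stringsAsFactors = FALSE)
  new("MultiResSample", pixels = px, center = as.integer(center),
      label = lab[["20x"]], info = info)
}

#' Write a PatchSet to disk as PNG files plus a manifest CSV
#'
#' The manifest has columns slideId, row, col, magnification,
#' tumorFraction, label, path.
#'
#' @param patches a \linkS4class{PatchSet}.
#' @param dir output directory (created if absent).
#' @return invisibly, the manifest data.frame.
#' @export
writePatches <- function(patches, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  info <- patches@info
  paths <- character(nrow(info))
  for (i in seq_along(patches@pixels)) {
    fn <- sprintf("%s_r%03d_c%03d_%s.png", info$slideId[i], info$row[i],
                  info$col[i], info$magnification[i])
    paths[i] <- file.path(dir, fn)
    d <- aperm(patches@pixels[[i]], c(2L, 1L, 3L))
    EBImage::writeImage(EBImage::Image(d, colormode = "Color"), paths[i])
  }
  manifest <- cbind(info, path = paths)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
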