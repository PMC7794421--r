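# Reconstruction loss family (MSE, MAE, SSIM, weighted joint form) and the
# classification cross-entropy, with the analytic SSIM gradient needed for
# autoencoder training.

.band_cache <- new.env(parent = emptyenv())

.ssimWindow1d <- function(cfg) {
  w <- cfg@windowSize
  if (cfg@windowKind == "uniform") return(rep(1 / w, w))
  r <- seq_len(w) - (w + 1) / 2
  g <- exp(-r^2 / (2 * cfg@gaussianSigma^2))
  g / sum(g)
}

# (n - w + 1) x n banded operator: row i holds the window at offset i.
# Windowed weighted local sums over a 2-D image X are Kh %*% X %*% t(Kw)
# (the separable form of correlation with the 2-D window), computed on the
# valid region only so no padding convention enters the SSIM value.
.ssimBand <- function(n, cfg) {
  key <- paste(n, cfg@windowSize, cfg@windowKind, cfg@gaussianSigma,
               sep = "_")
  hit <- .band_cache[[key]]
  if (!is.null(hit)) return(hit)
  w <- cfg@windowSize
  g <- .ssimWindow1d(cfg)
  m <- n - w + 1L
  K <- matrix(0, m, n)
  for (i in seq_len(m)) K[i, i:(i + w - 1L)] <- g
  .band_cache[[key]] <- K
  K
}

.ssimMaps <- function(x, y, cfg) {
  H <- nrow(x); W <- ncol(x)
  if (H < cfg@windowSize || W < cfg@windowSize)
    stop("image (", H, " x ", W, ") smaller than the SSIM window (",
         cfg@windowSize, ")")
  Kh <- .ssimBand(H, cfg)
  Kw <- .ssimBand(W, cfg)
  mux <- Kh %*% x %*% t(Kw)
  muy <- Kh %*% y %*% t(Kw)
  sx2 <- pmax(Kh %*% (x * x) %*% t(Kw) - mux^2, 0)
  sy2 <- pmax(Kh %*% (y * y) %*% t(Kw) - muy^2, 0)
  sxy <- Kh %*% (x * y) %*% t(Kw) - mux * muy
  L <- cfg@dynamicRange
  list(mux = mux, muy = muy, sx2 = sx2, sy2 = sy2, sxy = sxy,
       C1 = (cfg@k1 * L)^2, C2 = (cfg@k2 * L)^2, Kh = Kh, Kw = Kw)
}

.ssimChannel <- function(x, y, cfg) {
  m <- .ssimMaps(x, y, cfg)
  C3 <- m$C2 / 2
  lum <- (2 * m$mux * m$muy + m$C1) / (m$mux^2 + m$muy^2 + m$C1)
  sx <- sqrt(m$sx2); sy <- sqrt(m$sy2)
  con <- (2 * sx * sy + m$C2) / (m$sx2 + m$sy2 + m$C2)
  str <- (m$sxy + C3) / (sx * sy + C3)
  mean(lum^cfg@expL * con^cfg@expC * str^cfg@expS)
}

.luma <- function(a) {
  0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
}

#' Structural similarity index between two images
#'
#' Mean over sliding windows of the product of luminance, contrast and
#' structure comparison terms (exponents configurable), with stabilisers
#' C1 = (k1 L)^2, C2 = (k2 L)^2, C3 = C2/2. Multichannel images are handled
#' per \code{channelMode}: SSIM per channel averaged over channels, or SSIM
#' of the luma image. Windows are taken over the valid region only.
#'
#' @param x,y images of identical shape: H x W matrices or H x W x C arrays,
#'   values within [0, dynamicRange].
#' @param cfg an \linkS4class{SSIMConfig}.
#' @return scalar in (-1, 1]; 1 iff \code{x == y}.
#' @export
ssim <- function(x, y, cfg = ssimConfig()) {
  if (!identical(dim(x), dim(y))) stop("ssim: shape mismatch")
  if (length(dim(x)) == 2L) return(.ssimChannel(x, y, cfg))
  if (cfg@channelMode == "luma") return(.ssimChannel(.luma(x), .luma(y), cfg))
  mean(vapply(seq_len(dim(x)[3]),
              function(ch) .ssimChannel(x[, , ch], y[, , ch], cfg),
              numeric(1)))
}

#' SSIM-based reconstruction loss, 1 - SSIM
#'
#' @inheritParams ssim
#' @return scalar in [0, 2); 0 iff the images are identical.
#' @export
ssimLoss <- function(x, y, cfg = ssimConfig()) 1 - ssim(x, y, cfg)

# d mean(SSIM map) / d y for one channel, exponents (1,1,1). Writing
# A1 = 2 mux muy + C1, A2 = 2 sxy + C2, B1 = mux^2 + muy^2 + C1,
# B2 = sx2 + sy2 + C2 (so the map is A1 A2 / (B1 B2)), the chain rule
# through muy, sy2 and sxy gives
#   dS/dy = corr(G, T0) + 2 y corr(G, T1) + x corr(G, T2)
# with T1 = dS/dsy2, T2 = dS/dsxy, T0 = dS/dmuy - 2 muy T1 - mux T2, and
# corr(G, .) the adjoint of the windowing operator.
.ssimGradChannel <- function(x, y, cfg) {
  if (cfg@expL != 1 || cfg@expC != 1 || cfg@expS != 1)
    stop("SSIM gradient implemented for unit exponents only")
  m <- .ssimMaps(x, y, cfg)
  A1 <- 2 * m$mux * m$muy + m$C1
  A2 <- 2 * m$sxy + m$C2
  B1 <- m$mux^2 + m$muy^2 + m$C1
  B2 <- m$sx2 + m$sy2 + m$C2
  dmu <- (2 * m$mux * A2) / (B1 * B2) - (2 * m$muy * A1 * A2) / (B1^2 * B2)
  T1 <- -A1 * A2 / (B1 * B2^2)
  T2 <- 2 * A1 / (B1 * B2)
  T0 <- dmu - 2 * m$muy * T1 - m$mux * T2
  back <- function(Tm) t(m$Kh) %*% Tm %*% m$Kw
  (back(T0) + 2 * y * back(T1) + x * back(T2)) / length(A1)
}

# Gradient of ssim(x, y) w.r.t. y; same shape as y.
ssimGrad <- function(x, y, cfg = ssimConfig()) {
  if (length(dim(x)) == 2L) return(.ssimGradChannel(x, y, cfg))
  if (cfg@channelMode == "luma") {
    g <- .ssimGradChannel(.luma(x), .luma(y), cfg)
    out <- array(0, dim(y))
    wts <- c(0.299, 0.587, 0.114)
    for (ch in 1:3) out[, , ch] <- g * wts[ch]
    return(out)
  }
  C <- dim(x)[3]
  out <- array(0, dim(y))
  for (ch in seq_len(C))
    out[, , ch] <- .ssimGradChannel(x[, , ch], y[, , ch], cfg) / C
  out
}

#' Mean squared error reconstruction loss
#'
#' In \code{"literal_sum"} mode this is the raw double sum
#' \eqn{\sum_i \sum_j (x_{ij} - \hat x_{ij})^2} over the M images and N
#' pixels of the batch; \code{"per_pixel_mean"} divides by MN. Training uses
#' the per-pixel mean so the MSE term stays commensurate with the SSIM term.
#'
#' @param x,y originals and reconstructions, any equal shape (a batch is
#'   simply the collection of all its pixels).
#' @param mode "per_pixel_mean" or "literal_sum".
#' @return nonnegative scalar.
#' @export
mseLoss <- function(x, y, mode = c("per_pixel_mean", "literal_sum")) {
  mode <- match.arg(mode)
  if (!identical(dim(x), dim(y)) || length(x) != length(y))
    stop("mseLoss: shape mismatch")
  d2 <- (x - y)^2
  if (mode == "literal_sum") sum(d2) else mean(d2)
}

#' Mean absolute error reconstruction loss
#'
#' \eqn{\frac{1}{M}\frac{1}{N}\sum_i\sum_j |x_{ij} - \hat x_{ij}|}, i.e. the
#' mean absolute difference over the batch.
#'
#' @inheritParams mseLoss
#' @return nonnegative scalar.
#' @export
maeLoss <- function(x, y) {
  if (!identical(dim(x), dim(y)) || length(x) != length(y))
    stop("maeLoss: shape mismatch")
  mean(abs(x - y))
}

# SSIM-loss term of a batch: mean over images of (1 - ssim). Accepts a
# single image (2-D/3-D), a 4-D (H, W, C, B) array, or a list of images.
.batchSsimLoss <- function(x, y, cfg) {
  if (is.list(x)) {
    vals <- mapply(function(a, b) ssimLoss(a, b, cfg), x, y)
    return(mean(vals))
  }
  nd <- length(dim(x))
  if (nd <= 3L) return(ssimLoss(x, y, cfg))
  B <- dim(x)[4]
  mean(vapply(seq_len(B),
              function(b) ssimLoss(x[, , , b], y[, , , b], cfg),
              numeric(1)))
}

#' Joint reconstruction loss: weighted sum of MSE, SSIM loss and MAE
#'
#' \deqn{l_R = \alpha\, l_{MSE} + \beta\, (1 - SSIM) + \gamma\, l_{MAE}}
#' with defaults \eqn{\alpha = \beta = \gamma = 0.5}. For batches the SSIM
#' term is the mean over images of their (1 - SSIM).
#'
#' @param x,y originals and reconstructions: single images, 4-D
#'   (H, W, C, B) arrays, or lists of images.
#' @param cfg a \linkS4class{LossConfig}.
#' @return nonnegative scalar; attribute \code{"components"} carries the
#'   three unweighted terms.
#' @export
jointReconstructionLoss <- function(x, y, cfg = lossConfig()) {
  if (is.list(x)) {
    xm <- simplify2array(x)
    ym <- simplify2array(y)
  } else {
    xm <- x; ym <- y
  }
  m <- mseLoss(xm, ym, cfg@mseMode)
  s <- .batchSsimLoss(x, y, cfg@ssim)
  a <- maeLoss(xm, ym)
  total <- cfg@alpha * m + cfg@beta * s + cfg@gamma * a
  attr(total, "components") <- c(mse = m, ssimLoss = s, mae = a)
  total
}

#' Classification cross-entropy
#'
#' Mean negative log-probability of the true class over the batch,
#' \eqn{l_C = -\frac{1}{M}\sum_c y_c \log \hat y_c}. Probabilities are
#' clamped at 1e-12 so saturated predictions stay finite.
#'
#' @param trueLabels vector of true class labels (character/factor), or
#'   NULL when \code{predProbs} is already the vector of true-class
#'   probabilities.
#' @param predProbs n x K matrix of class probabilities with class names as
#'   column names, or a numeric vector of true-class probabilities.
#' @return nonnegative scalar.
#' @export
crossEntropyLoss <- function(trueLabels, predProbs) {
  if (is.matrix(predProbs)) {
    if (is.null(colnames(predProbs)))
      stop("predProbs matrix needs class column names")
    idx <- match(as.character(trueLabels), colnames(predProbs))
    if (anyNA(idx)) stop("labels not found among predProbs columns")
    p <- predProbs[cbind(seq_len(nrow(predProbs)), idx)]
  } else {
    p <- predProbs
  }
  p <- pmax(p, 1e-12)
  -mean(log(p))
}

# Joint reconstruction loss and its gradient for a batch in the internal
# (H*W*C) x B layout; used by the training loops.
reconLossGrad <- function(X, Xhat, cfg, H, W, C) {
  B <- ncol(X)
  n <- length(X)
  diff <- Xhat - X
  mse <- if (cfg@mseMode == "literal_sum") sum(diff^2) else mean(diff^2)
  gmse <- if (cfg@mseMode == "literal_sum") 2 * diff else 2 * diff / n
  mae <- mean(abs(diff))
  gmae <- sign(diff) / n
  sl <- 0
  gssim <- 0 * X
  if (cfg@beta > 0) {
    scfg <- cfg@ssim
    if (scfg@expL != 1 || scfg@expC != 1 || scfg@expS != 1 ||
        scfg@channelMode != "per_channel_mean") {
      # general (slower) path through the public SSIM value/gradient
      for (b in seq_len(B)) {
        xb <- nnCol2Array(X[, b], H, W, C)
        yb <- nnCol2Array(Xhat[, b], H, W, C)
        sl <- sl + ssimLoss(xb, yb, scfg)
        gssim[, b] <- -nnArray2Col(ssimGrad(xb, yb, scfg))
      }
      sl <- sl / B
      gssim <- gssim / B
      total <- cfg@alpha * mse + cfg@beta * sl + cfg@gamma * mae
      grad <- cfg@alpha * gmse + cfg@beta * gssim + cfg@gamma * gmae
      return(list(loss = total, grad = grad,
                  components = c(mse = mse, ssimLoss = sl, mae = mae)))
    }
    for (b in seq_len(B)) {
      xb <- nnCol2Array(X[, b], H, W, C)
      yb <- nnCol2Array(Xhat[, b], H, W, C)
      gb <- array(0, c(H, W, C))
      sb <- 0
      for (ch in seq_len(C)) {
        mm <- .ssimMaps(xb[, , ch], yb[, , ch], scfg)
        A1 <- 2 * mm$mux * mm$muy + mm$C1
        A2 <- 2 * mm$sxy + mm$C2
        B1 <- mm$mux^2 + mm$muy^2 + mm$C1
        B2 <- mm$sx2 + mm$sy2 + mm$C2
        sb <- sb + mean(A1 * A2 / (B1 * B2))
        dmu <- (2 * mm$mux * A2) / (B1 * B2) -
          (2 * mm$muy * A1 * A2) / (B1^2 * B2)
        T1 <- -A1 * A2 / (B1 * B2^2)
        T2 <- 2 * A1 / (B1 * B2)
        T0 <- dmu - 2 * mm$muy * T1 - mm$mux * T2
        gb[, , ch] <- (t(mm$Kh) %*% T0 %*% mm$Kw +
                       2 * yb[, , ch] * (t(mm$Kh) %*% T1 %*% mm$Kw) +
                       xb[, , ch] * (t(mm$Kh) %*% T2 %*% mm$Kw)) /
          length(A1)
      }
      sl <- sl + (1 - sb / C)
      gssim[, b] <- -nnArray2Col(gb) / C
    }
    sl <- sl / B
    gssim <- gssim / B
  }
  total <- cfg@alpha * mse + cfg@beta * sl + cfg@gamma * mae
  grad <- cfg@alpha * gmse + cfg@beta * gssim + cfg@gamma * gmae
  list(loss = total, grad = grad,
       components = c(mse = mse, ssimLoss = sl, mae = mae))
}
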