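# Independent oracles and small fixture builders used across the suite.

# Brute-force tiling enumeration: all (r, c) with ps*(r+1) <= H etc.
oracleTileCells <- function(H, W, ps) {
  cells <- expand.grid(row = 0:max(0, H %/% ps - 1),
                       col = 0:max(0, W %/% ps - 1))
  cells <- cells[ps * (cells$row + 1) <= H & ps * (cells$col + 1) <= W, ]
  cells[order(cells$row, cells$col), ]
}

# Double-loop MSE/MAE oracles over an M x N batch matrix (rows = images).
oracleMse <- function(x, y) {
  s <- 0
  for (i in seq_len(nrow(x))) for (j in seq_len(ncol(x)))
    s <- s + (x[i, j] - y[i, j])^2
  s
}

oracleMae <- function(x, y) {
  s <- 0
  for (i in seq_len(nrow(x))) for (j in seq_len(ncol(x)))
    s <- s + abs(x[i, j] - y[i, j])
  s / (nrow(x) * ncol(x))
}

# Naive windowed SSIM: explicit loop over valid windows.
oracleSsim <- function(x, y, cfg) {
  w <- cfg@windowSize
  r <- seq_len(w) - (w + 1) / 2
  g <- if (cfg@windowKind == "gaussian") {
    exp(-r^2 / (2 * cfg@gaussianSigma^2))
  } else {
    rep(1, w)
  }
  g <- g / sum(g)
  G2 <- outer(g, g)
  C1 <- (cfg@k1 * cfg@dynamicRange)^2
  C2 <- (cfg@k2 * cfg@dynamicRange)^2
  H <- nrow(x); W <- ncol(x)
  vals <- numeric(0)
  for (i in 1:(H - w + 1)) for (j in 1:(W - w + 1)) {
    xa <- x[i:(i + w - 1), j:(j + w - 1)]
    ya <- y[i:(i + w - 1), j:(j + w - 1)]
    mx <- sum(G2 * xa); my <- sum(G2 * ya)
    vx <- sum(G2 * xa^2) - mx^2
    vy <- sum(G2 * ya^2) - my^2
    cxy <- sum(G2 * xa * ya) - mx * my
    lum <- (2 * mx * my + C1) / (mx^2 + my^2 + C1)
    con <- (2 * sqrt(max(vx, 0)) * sqrt(max(vy, 0)) + C2) / (vx + vy + C2)
    str <- (cxy + C2 / 2) / (sqrt(max(vx, 0)) * sqrt(max(vy, 0)) + C2 / 2)
    vals <- c(vals, lum * con * str)
  }
  mean(vals)
}

# Enumerate 4-connected components of a binary matrix (value, size,
# touches-border) by breadth-first search; independent of EBImage.
oracleComponents <- function(m, value) {
  H <- nrow(m); W <- ncol(m)
  seen <- matrix(FALSE, H, W)
  comps <- list()
  for (s0 in which(m == value & !seen)) {
    if (seen[s0]) next
    queue <- s0
    seen[s0] <- TRUE
    px <- integer(0)
    while (length(queue) > 0) {
      p <- queue[1]; queue <- queue[-1]
      px <- c(px, p)
      r <- (p - 1) %% H + 1
      cc <- (p - 1) %/% H + 1
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        rr <- r + d[1]; cw <- cc + d[2]
        if (rr >= 1 && rr <= H && cw >= 1 && cw <= W) {
          q <- rr + (cw - 1) * H
          if (m[q] == value && !seen[q]) { seen[q] <- TRUE; queue <- c(queue, q) }
        }
      }
    }
    r <- (px - 1) %% H + 1
    cc <- (px - 1) %/% H + 1
    comps[[length(comps) + 1]] <- list(
      pixels = px, size = length(px),
      border = any(r == 1 | r == H | cc == 1 | cc == W))
  }
  comps
}

# Small deterministic random patch set (H x H x 3 arrays in [0, 1]).
makePatchSet <- function(n, H = 32L, seed = 1L,
                         labels = rep(c("tumor", "non_tumor"),
                                      length.out = n)) {
  set.seed(seed)
  px <- lapply(seq_len(n), function(i) {
    base <- if (labels[i] == "tumor") 0.3 else 0.7
    array(pmin(pmax(base + rnorm(H * H * 3, sd = 0.08), 0), 1),
          c(H, H, 3L))
  })
  info <- data.frame(slideId = "fix", row = seq_len(n) - 1L, col = 0L,
                     magnification = "20x",
                     tumorFraction = ifelse(labels == "tumor", 1, 0),
                     label = labels, stringsAsFactors = FALSE)
  new("PatchSet", pixels = px, info = info, patchSize = as.integer(H))
}

# Constant-valued 3-level pyramid for multi-resolution geometry tests.
makePyramid <- function(D20 = 256L, value = 0.5) {
  mk <- function(D, mag) slideImage(array(value, c(D, D, 3L)),
                                    "pyr", mag)
  list("20x" = mk(D20, "20x"), "10x" = mk(D20 %/% 2L, "10x"),
       "5x" = mk(D20 %/% 4L, "5x"))
}

# Short training configuration for desk tests.
tinyTrainConfig <- function(epochs, seed = 7L, batchSize = 16L) {
  trainConfig(epochs = epochs, batchSize = batchSize,
              learningRate = 1e-3, seed = seed)
}
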