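# Internal minimal neural-network engine.
#
# A mini-batch is a dense matrix of dim (C*H*W) x B: each column is one
# image flattened channel-fastest (channel, then row, then column). This
# layout makes the im2col GEMM output land directly in the next layer's
# layout (no transposes) and lets per-channel bias and batch-norm terms
# broadcast by plain column recycling. Convolutions are im2col GEMMs; the
# im2col gather is a precomputed sparse 0/1 matrix G so the backward
# scatter-add is simply crossprod(G, .). Transposed convolutions reuse the
# machinery of the mirror-image convolution with the roles of forward and
# backward-data swapped. Stride-2 "same" padding follows the ceil(H/s)
# convention (extra padding on the bottom/right) so a stride-2 layer halves
# even dimensions exactly and 4 layers map 256 -> 16.
#
# Everything is deterministic given R's RNG state; dropout and weight
# initialisation are the only consumers of randomness.

.plan_cache <- new.env(parent = emptyenv())

# Reinterpret a Matrix dense result as a base matrix without a copy.
.dmat <- function(S, nr, nc) {
  v <- S@x
  dim(v) <- c(nr, nc)
  v
}

# Sparse im2col plan for input (H, W, C), k x k kernel, given stride.
# Column q of the kernel window is ordered channel-fastest:
# q = ch + (dh-1)*C + (dw-1)*C*k.
nnConvPlan <- function(H, W, C, k, stride) {
  key <- paste(H, W, C, k, stride, sep = "_")
  hit <- .plan_cache[[key]]
  if (!is.null(hit)) return(hit)
  outH <- as.integer(ceiling(H / stride))
  outW <- as.integer(ceiling(W / stride))
  padH <- max((outH - 1L) * stride + k - H, 0L)
  padW <- max((outW - 1L) * stride + k - W, 0L)
  padTop <- padH %/% 2L
  padLeft <- padW %/% 2L
  kkC <- k * k * C
  P <- outH * outW
  g <- expand.grid(ch = seq_len(C), dh = seq_len(k), dw = seq_len(k),
                   ho = seq_len(outH), wo = seq_len(outW))
  hi <- (g$ho - 1L) * stride + g$dh - padTop
  wi <- (g$wo - 1L) * stride + g$dw - padLeft
  ok <- hi >= 1L & hi <= H & wi >= 1L & wi <= W
  j <- g$ch + (hi - 1L) * C + (wi - 1L) * C * H
  G <- Matrix::sparseMatrix(i = which(ok), j = j[ok], x = 1,
                            dims = c(kkC * P, H * W * C))
  plan <- list(G = G, H = H, W = W, C = C, k = k, stride = stride,
               outH = outH, outW = outW, kkC = kkC, P = P)
  .plan_cache[[key]] <- plan
  plan
}

.nnAct <- function(Z, act) {
  switch(act,
         relu = { Z[Z < 0] <- 0; Z },
         sigmoid = 1 / (1 + exp(-Z)),
         linear = Z,
         stop("unknown activation: ", act))
}

.nnActGrad <- function(dY, A, act) {
  switch(act,
         relu = dY * (A > 0),
         sigmoid = dY * A * (1 - A),
         linear = dY)
}

# ---- layer constructors ----------------------------------------------------

nnConv <- function(H, W, Cin, Cout, k = 3L, stride = 1L, act = "relu") {
  plan <- nnConvPlan(H, W, Cin, k, stride)
  sdw <- sqrt(2 / (k * k * Cin))
  list(kind = "conv", act = act, plan = plan, Cin = Cin, Cout = Cout,
       W = matrix(rnorm(Cout * plan$kkC, sd = sdw), Cout),
       b = numeric(Cout),
       outH = plan$outH, outW = plan$outW)
}

# Transposed convolution: input (H, W, Cin) -> output (H*stride, W*stride,
# Cout); the plan is built for the mirror convolution (big -> small).
nnDeconv <- function(H, W, Cin, Cout, k = 3L, stride = 2L, act = "relu") {
  outH <- H * stride
  outW <- W * stride
  plan <- nnConvPlan(outH, outW, Cout, k, stride)
  stopifnot(plan$outH == H, plan$outW == W)
  sdw <- sqrt(2 / (k * k * Cin))
  list(kind = "deconv", act = act, plan = plan, Cin = Cin, Cout = Cout,
       W = matrix(rnorm(Cin * plan$kkC, sd = sdw), Cin),
       b = numeric(Cout),
       H = H, W = W, outH = outH, outW = outW)
}

nnBatchNorm <- function(spatial, C, momentum = 0.1, eps = 1e-5) {
  list(kind = "bn", spatial = as.integer(spatial), C = as.integer(C),
       gamma = rep(1, C), beta = numeric(C),
       runMean = numeric(C), runVar = rep(1, C),
       momentum = momentum, eps = eps)
}

nnDense <- function(Fin, Fout, act = "linear") {
  list(kind = "dense", act = act, Fin = Fin, Fout = Fout,
       W = matrix(rnorm(Fout * Fin, sd = sqrt(2 / Fin)), Fout),
       b = numeric(Fout))
}

nnDropout <- function(rate) list(kind = "dropout", rate = rate)

nnSoftmax <- function() list(kind = "softmax")

nnFlatten <- function() list(kind = "flatten")  # identity in this layout

# ---- forward / backward ----------------------------------------------------

.fwdConv <- function(layer, X) {
  plan <- layer$plan
  B <- ncol(X)
  cols <- .dmat(plan$G %*% X, plan$kkC, plan$P * B)
  Z <- layer$W %*% cols
  Z <- Z + layer$b                       # recycles per output channel
  A <- .nnAct(Z, layer$act)
  dim(A) <- c(layer$Cout * plan$P, B)
  list(out = A, cache = list(cols = cols, A = A))
}

.bwdConv <- function(layer, cache, dY) {
  plan <- layer$plan
  B <- ncol(dY)
  dZ <- .nnActGrad(dY, cache$A, layer$act)
  dim(dZ) <- c(layer$Cout, plan$P * B)
  dW <- tcrossprod(dZ, cache$cols)
  db <- rowSums(dZ)
  dcols <- crossprod(layer$W, dZ)
  dim(dcols) <- c(plan$kkC * plan$P, B)
  dX <- .dmat(Matrix::crossprod(plan$G, dcols), plan$H * plan$W * plan$C, B)
  list(dX = dX, grads = list(W = dW, b = db))
}

.fwdDeconv <- function(layer, X) {
  plan <- layer$plan
  B <- ncol(X)
  Xm <- X
  dim(Xm) <- c(layer$Cin, plan$P * B)
  U <- crossprod(layer$W, Xm)            # (kkCout, P*B)
  dim(U) <- c(plan$kkC * plan$P, B)
  Z <- .dmat(Matrix::crossprod(plan$G, U),
             layer$Cout * layer$outH * layer$outW, B)
  Z <- Z + layer$b                       # recycles per output channel
  A <- .nnAct(Z, layer$act)
  list(out = A, cache = list(Xm = Xm, A = A))
}

.bwdDeconv <- function(layer, cache, dY) {
  plan <- layer$plan
  B <- ncol(dY)
  dZ <- .nnActGrad(dY, cache$A, layer$act)
  dbm <- dZ
  dim(dbm) <- c(layer$Cout, layer$outH * layer$outW * B)
  db <- rowSums(dbm)
  colsD <- .dmat(plan$G %*% dZ, plan$kkC, plan$P * B)
  dW <- tcrossprod(cache$Xm, colsD)      # (Cin, kkCout)
  dXm <- layer$W %*% colsD               # (Cin, P*B)
  dim(dXm) <- c(layer$Cin * plan$P, B)
  list(dX = dXm, grads = list(W = dW, b = db))
}

.fwdBN <- function(layer, X, training) {
  S <- layer$spatial
  C <- layer$C
  B <- ncol(X)
  dim(X) <- c(C, S * B)
  if (training) {
    mu <- .rowMeans(X, C, S * B)
    ex2 <- .rowMeans(X * X, C, S * B)
    v <- pmax(ex2 - mu^2, 0)
  } else {
    mu <- layer$runMean
    v <- layer$runVar
  }
  inv <- 1 / sqrt(v + layer$eps)
  xhat <- (X - mu) * inv                 # length-C terms recycle per column
  out <- xhat * layer$gamma + layer$beta
  dim(out) <- c(C * S, B)
  list(out = out,
       cache = list(xhat = xhat, inv = inv, mu = mu, v = v,
                    training = training))
}

.bwdBN <- function(layer, cache, dY) {
  S <- layer$spatial
  C <- layer$C
  B <- ncol(dY)
  dim(dY) <- c(C, S * B)
  xhat <- cache$xhat
  dyx <- dY * xhat
  dgamma <- rowSums(dyx)
  dbeta <- rowSums(dY)
  mdy <- dbeta / (S * B)
  mdyx <- dgamma / (S * B)
  gi <- layer$gamma * cache$inv
  dX <- gi * (dY - mdy - xhat * mdyx)
  dim(dX) <- c(C * S, B)
  list(dX = dX, grads = list(gamma = dgamma, beta = dbeta))
}

.fwdDense <- function(layer, X) {
  Z <- layer$W %*% X + layer$b
  A <- .nnAct(Z, layer$act)
  list(out = A, cache = list(X = X, A = A))
}

.bwdDense <- function(layer, cache, dY) {
  dZ <- .nnActGrad(dY, cache$A, layer$act)
  list(dX = crossprod(layer$W, dZ),
       grads = list(W = tcrossprod(dZ, cache$X), b = rowSums(dZ)))
}

.fwdDropout <- function(layer, X, training) {
  if (!training || layer$rate <= 0)
    return(list(out = X, cache = NULL))
  mask <- (runif(length(X)) >= layer$rate) / (1 - layer$rate)
  dim(mask) <- dim(X)
  list(out = X * mask, cache = list(mask = mask))
}

.fwdSoftmax <- function(X) {
  Z <- sweep(X, 2L, apply(X, 2L, max), "-")
  E <- exp(Z)
  P <- sweep(E, 2L, colSums(E), "/")
  list(out = P, cache = NULL)
}

# Forward pass through a layer list. Returns the output and per-layer
# caches; batch-norm running statistics are updated on the returned layer
# list when training. keepCaches = FALSE (inference) drops the caches to
# bound memory.
nnForward <- function(layers, X, training = FALSE, keepCaches = TRUE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    r <- switch(l$kind,
                conv = .fwdConv(l, X),
                deconv = .fwdDeconv(l, X),
                bn = .fwdBN(l, X, training),
                dense = .fwdDense(l, X),
                dropout = .fwdDropout(l, X, training),
                flatten = list(out = X, cache = NULL),
                softmax = .fwdSoftmax(X),
                stop("unknown layer kind: ", l$kind))
    if (l$kind == "bn" && training) {
      m <- l$momentum
      layers[[i]]$runMean <- (1 - m) * l$runMean + m * r$cache$mu
      layers[[i]]$runVar <- (1 - m) * l$runVar + m * r$cache$v
    }
    if (keepCaches) caches[[i]] <- r$cache
    X <- r$out
  }
  list(out = X, caches = caches, layers = layers)
}

# Backward pass; dOut is the gradient w.r.t. the network output. The
# softmax layer must not be included (classification gradients are taken
# w.r.t. the pre-softmax logits).
nnBackward <- function(layers, caches, dOut) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    r <- switch(l$kind,
                conv = .bwdConv(l, caches[[i]], dOut),
                deconv = .bwdDeconv(l, caches[[i]], dOut),
                bn = .bwdBN(l, caches[[i]], dOut),
                dense = .bwdDense(l, caches[[i]], dOut),
                dropout = if (is.null(caches[[i]])) {
                  list(dX = dOut, grads = NULL)
                } else {
                  list(dX = dOut * caches[[i]]$mask, grads = NULL)
                },
                flatten = list(dX = dOut, grads = NULL),
                softmax = stop("softmax has no backward; use logits"),
                stop("unknown layer kind: ", l$kind))
    grads[i] <- list(r$grads)  # [[<- would drop NULL entries
    dOut <- r$dX
  }
  list(dX = dOut, grads = grads)
}

# ---- parameters and ADAM ---------------------------------------------------

.PARAM_NAMES <- c("W", "b", "gamma", "beta")

nnParams <- function(layers) {
  lapply(layers, function(l) l[intersect(.PARAM_NAMES, names(l))])
}

# Trainable parameter count (weights + biases + batch-norm gamma/beta).
nnNumParams <- function(layers) {
  sum(vapply(nnParams(layers),
             function(p) sum(vapply(p, length, integer(1))), numeric(1)))
}

nnAdamInit <- function(layers) {
  list(t = 0L,
       m = lapply(nnParams(layers), function(p) lapply(p, function(x) x * 0)),
       v = lapply(nnParams(layers), function(p) lapply(p, function(x) x * 0)))
}

nnAdamStep <- function(layers, grads, state, lr, beta1, beta2, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (nm in names(g)) {
      state$m[[i]][[nm]] <- beta1 * state$m[[i]][[nm]] + (1 - beta1) * g[[nm]]
      state$v[[i]][[nm]] <- beta2 * state$v[[i]][[nm]] +
        (1 - beta2) * g[[nm]]^2
      mhat <- state$m[[i]][[nm]] / bc1
      vhat <- state$v[[i]][[nm]] / bc2
      layers[[i]][[nm]] <- layers[[i]][[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(layers = layers, state = state)
}

# Copy all parameters (and batch-norm running statistics) from one layer
# list into another with identical structure.
nnCopyParams <- function(from, to) {
  stopifnot(length(from) == length(to))
  for (i in seq_along(from)) {
    for (nm in c(.PARAM_NAMES, "runMean", "runVar")) {
      if (!is.null(from[[i]][[nm]])) to[[i]][[nm]] <- from[[i]][[nm]]
    }
  }
  to
}

# Maximum absolute difference between the parameters of two layer lists.
nnMaxParamDiff <- function(a, b) {
  d <- 0
  for (i in seq_along(a)) {
    for (nm in .PARAM_NAMES) {
      if (!is.null(a[[i]][[nm]]))
        d <- max(d, max(abs(a[[i]][[nm]] - b[[i]][[nm]])))
    }
  }
  d
}

# ---- batch helpers ---------------------------------------------------------

# Stack a list of (H, W, C) arrays into the (C*H*W) x B batch layout.
nnStack <- function(patches) {
  if (length(patches) == 0L) return(matrix(numeric(0), 0L, 0L))
  vapply(patches,
         function(p) as.vector(aperm(p, c(3L, 1L, 2L))),
         numeric(length(patches[[1]])))
}

# Inverse of nnStack: batch matrix -> list of (H, W, C) arrays.
nnUnstack <- function(X, H, W, C) {
  lapply(seq_len(ncol(X)),
         function(b) aperm(array(X[, b], c(C, H, W)), c(2L, 3L, 1L)))
}

# One column of the batch as an (H, W, C) array, and back.
nnCol2Array <- function(x, H, W, C) {
  aperm(array(x, c(C, H, W)), c(2L, 3L, 1L))
}

nnArray2Col <- function(a) as.vector(aperm(a, c(3L, 1L, 2L)))

# Index permutations implementing the 8 dihedral symmetries of a square
# patch, applied identically to every channel: used for label-preserving
# rotation/flip augmentation.
nnDihedralPerms <- function(H, W, C) {
  stopifnot(H == W)
  base <- matrix(seq_len(H * W), H, W)
  ops <- list(
    function(m) m,
    function(m) t(m[nrow(m):1, , drop = FALSE]),            # rot90
    function(m) m[nrow(m):1, ncol(m):1, drop = FALSE],      # rot180
    function(m) t(m)[nrow(m):1, , drop = FALSE],            # rot270
    function(m) m[nrow(m):1, , drop = FALSE],               # vflip
    function(m) m[, ncol(m):1, drop = FALSE],               # hflip
    function(m) t(m),                                       # transpose
    function(m) t(m[nrow(m):1, ncol(m):1, drop = FALSE]))   # anti-transpose
  lapply(ops, function(f) {
    p <- as.vector(f(base))   # spatial permutation, column-major
    as.vector(outer(seq_len(C), (p - 1L) * C, "+"))
  })
}

nnAugmentBatch <- function(X, perms) {
  ops <- sample.int(length(perms), ncol(X), replace = TRUE)
  for (b in seq_len(ncol(X))) {
    if (ops[b] > 1L) X[, b] <- X[perms[[ops[b]]], b]
  }
  X
}


# Recalibrate batch-norm running statistics with one pass over X under
# the final weights: each bn layer's running mean/var is set to the exact
# statistics of its input at this pass (dropout off, everything else in
# inference mode). Removes the training-time lag of momentum-averaged
# statistics. At most `cap` samples are used.
nnCalibrateBN <- function(layers, X, cap = 256L) {
  if (ncol(X) > cap)
    X <- X[, round(seq(1L, ncol(X), length.out = cap)), drop = FALSE]
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (l$kind == "bn") {
      r <- .fwdBN(l, X, training = TRUE)
      layers[[i]]$runMean <- r$cache$mu
      layers[[i]]$runVar <- r$cache$v
      X <- r$out
    } else {
      X <- switch(l$kind,
                  conv = .fwdConv(l, X)$out,
                  deconv = .fwdDeconv(l, X)$out,
                  dense = .fwdDense(l, X)$out,
                  softmax = .fwdSoftmax(X)$out,
                  X)  # dropout/flatten: identity at inference
    }
  }
  layers
}

# Chunked inference forward: bound memory by processing at most chunk
# columns at a time; caches are discarded.
nnPredictChunked <- function(layers, X, chunk = 256L) {
  n <- ncol(X)
  if (n <= chunk)
    return(nnForward(layers, X, training = FALSE, keepCaches = FALSE)$out)
  parts <- split(seq_len(n), ceiling(seq_len(n) / chunk))
  do.call(cbind, lapply(parts, function(ix) {
    nnForward(layers, X[, ix, drop = FALSE], training = FALSE,
              keepCaches = FALSE)$out
  }))
}
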