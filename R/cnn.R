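# CNN comparator (ConvNet for sEMG images). A real-valued sample
# (channels x T) is reshaped into a C x H x W image with C = 100 time steps
# as channels and the electrode channels laid out row-major on an H x W
# grid (16 x 8 for 128 channels, 4 x 2 for 8). Two blocks of
# [conv 2x2 stride 2 same -> batch norm -> max pool 2x2 stride 2], then a
# fully-connected softmax layer. Trained with Adam (lr 0.01). Pooling along
# an axis of size 1 is skipped. Implemented directly with im2col
# convolutions and hand-written backprop (verified by finite differences in
# the tests).

#' CNN architecture description
#'
#' @param channels number of EMG channels (128 or 8).
#' @param gestures number of output classes, default 9.
#' @param timeSteps window length T (image channel count C), default 100.
#' @param c1,c2 filters of the two convolutional blocks, defaults 32 and 16.
#' @param k kernel side length, default 2 (stride fixed at 2).
#' @return a `CnnArch` list with the input image shape and layer sizes.
#' @export
cnnArch <- function(channels, gestures = 9, timeSteps = 100, c1 = 32,
                    c2 = 16, k = 2) {
  hw <- if (channels == 128) c(16, 8) else if (channels == 8) c(4, 2) else
    stop("no image reshape defined for ", channels, " channels")
  stopifnot(prod(hw) == channels)
  structure(list(channels = channels, H = hw[1], W = hw[2], C = timeSteps,
    C1 = c1, C2 = c2, k = k, gestures = gestures), class = "CnnArch")
}

# Strided 2x2 'same' convolution: X (Cin, H, W, n) -> (Cout, oH, oW, n)
# with oH = ceiling(H/2); zero padding bottom/right when H or W is odd.
convPatches <- function(X, k) {
  d <- dim(X)
  oH <- ceiling(d[2] / k); oW <- ceiling(d[3] / k)
  Xp <- array(0, c(d[1], oH * k, oW * k, d[4]))
  Xp[, seq_len(d[2]), seq_len(d[3]), ] <- X
  P <- array(0, c(d[1] * k * k, oH, oW, d[4]))
  r <- 0
  for (dy in seq_len(k)) for (dx in seq_len(k)) {
    P[r + seq_len(d[1]), , , ] <-
      Xp[, seq(dy, by = k, length.out = oH),
         seq(dx, by = k, length.out = oW), , drop = FALSE]
    r <- r + d[1]
  }
  P
}

convForward <- function(X, K, b, k) {
  P <- convPatches(X, k)
  dp <- dim(P)
  Y <- K %*% matrix(P, dp[1]) + b
  list(out = array(Y, c(nrow(K), dp[2], dp[3], dp[4])), P = P)
}

convBackward <- function(dOut, P, K, k, dimX) {
  m <- dim(dOut)
  dY <- matrix(dOut, m[1])
  dp <- dim(P)
  dK <- dY %*% t(matrix(P, dp[1]))
  db <- rowSums(dY)
  dP <- array(crossprod(K, dY), dp)
  oH <- dp[2]; oW <- dp[3]
  dXp <- array(0, c(dimX[1], oH * k, oW * k, dimX[4]))
  r <- 0
  for (dy in seq_len(k)) for (dx in seq_len(k)) {
    dXp[, seq(dy, by = k, length.out = oH),
        seq(dx, by = k, length.out = oW), ] <- dP[r + seq_len(dimX[1]), , , ]
    r <- r + dimX[1]
  }
  list(dX = dXp[, seq_len(dimX[2]), seq_len(dimX[3]), , drop = FALSE],
       dK = dK, db = db)
}

# Batch norm over (spatial, batch) per channel. Population statistics.
bnForward <- function(X, gamma, beta, eps = 1e-5) {
  d <- dim(X)
  Xm <- matrix(X, d[1])
  m <- rowMeans(Xm)
  v <- rowMeans((Xm - m)^2)
  xhat <- (Xm - m) / sqrt(v + eps)
  list(out = array(gamma * xhat + beta, d), xhat = xhat, v = v, m = m,
       eps = eps)
}

bnBackward <- function(dOut, cache, gamma) {
  d <- dim(dOut)
  dY <- matrix(dOut, d[1])
  dgamma <- rowSums(dY * cache$xhat)
  dbeta <- rowSums(dY)
  dxhat <- dY * gamma
  dX <- (dxhat - rowMeans(dxhat) - cache$xhat * rowMeans(dxhat *
    cache$xhat)) / sqrt(cache$v + cache$eps)
  list(dX = array(dX, d), dgamma = dgamma, dbeta = dbeta)
}

bnEval <- function(X, gamma, beta, m, v, eps = 1e-5) {
  d <- dim(X)
  array(gamma * ((matrix(X, d[1]) - m) / sqrt(v + eps)) + beta, d)
}

# Max pool with window 2 and stride 2 along each spatial axis of size > 1
# (requires even extent); ties broken toward the first element.
poolForward <- function(X) {
  d <- dim(X)
  kh <- if (d[2] > 1) 2 else 1
  kw <- if (d[3] > 1) 2 else 1
  if (d[2] %% kh || d[3] %% kw) stop("pooling needs even spatial extent")
  oH <- d[2] / kh; oW <- d[3] / kw
  best <- NULL; idx <- NULL
  j <- 0
  for (dy in seq_len(kh)) for (dx in seq_len(kw)) {
    j <- j + 1
    s <- X[, seq(dy, by = kh, length.out = oH),
           seq(dx, by = kw, length.out = oW), , drop = FALSE]
    if (is.null(best)) {
      best <- s; idx <- array(1L, dim(s))
    } else {
      m <- s > best
      best[m] <- s[m]; idx[m] <- j
    }
  }
  list(out = best, idx = idx, kh = kh, kw = kw, dimX = d)
}

poolBackward <- function(dOut, cache) {
  d <- cache$dimX
  dX <- array(0, d)
  oH <- dim(dOut)[2]; oW <- dim(dOut)[3]
  j <- 0
  for (dy in seq_len(cache$kh)) for (dx in seq_len(cache$kw)) {
    j <- j + 1
    dX[, seq(dy, by = cache$kh, length.out = oH),
       seq(dx, by = cache$kw, length.out = oW), ] <-
      dOut * (cache$idx == j)
  }
  dX
}

# Reshape real samples (ch x T x n) to image batches (T, H, W, n); electrode
# channel c sits at row (c - 1) %/% W + 1, column (c - 1) %% W + 1.
reshapeToImage <- function(data, H, W) {
  d <- dim(data)
  aperm(array(aperm(data, c(2, 1, 3)), c(d[2], W, H, d[3])), c(1, 3, 2, 4))
}

#' Construct a CNN classifier
#'
#' @param arch a [cnnArch()].
#' @param seed initialisation seed.
#' @return a `CnnModel` list (parameters, batch-norm running statistics,
#'   architecture).
#' @export
cnnNetwork <- function(arch, seed = 1) {
  set.seed(seed)
  u <- function(r, c, fan) matrix(stats::runif(r * c, -1, 1) / sqrt(fan),
                                  r, c)
  kk <- arch$k^2
  # trace the spatial shape through the two blocks to size the FC layer
  shp <- c(arch$H, arch$W)
  conv <- function(s) ceiling(s / 2)
  pool <- function(s) ifelse(s > 1, s / 2, s)
  shp <- pool(conv(shp))
  shp <- pool(conv(shp))
  flat <- arch$C2 * prod(shp)
  params <- list(
    K1 = u(arch$C1, arch$C * kk, arch$C * kk), b1 = rep(0, arch$C1),
    g1 = rep(1, arch$C1), be1 = rep(0, arch$C1),
    K2 = u(arch$C2, arch$C1 * kk, arch$C1 * kk), b2 = rep(0, arch$C2),
    g2 = rep(1, arch$C2), be2 = rep(0, arch$C2),
    Wf = u(arch$gestures, flat, flat), bf = rep(0, arch$gestures))
  structure(list(params = params, arch = arch, flat = flat,
    bnStats = list(m1 = rep(0, arch$C1), v1 = rep(1, arch$C1),
      m2 = rep(0, arch$C2), v2 = rep(1, arch$C2))), class = "CnnModel")
}

#' @export
print.CnnModel <- function(x, ...) {
  cat(sprintf("CnnModel: %d ch as %dx%dx%d image -> %d classes\n",
    x$arch$channels, x$arch$C, x$arch$H, x$arch$W, x$arch$gestures))
  invisible(x)
}

# Training-mode forward with caches. X: (C, H, W, n) image batch.
cnnForwardTrain <- function(params, arch, X) {
  c1 <- convForward(X, params$K1, params$b1, arch$k)
  n1 <- bnForward(c1$out, params$g1, params$be1)
  p1 <- poolForward(n1$out)
  c2 <- convForward(p1$out, params$K2, params$b2, arch$k)
  n2 <- bnForward(c2$out, params$g2, params$be2)
  p2 <- poolForward(n2$out)
  d <- dim(p2$out)
  flat <- matrix(p2$out, prod(d[1:3]), d[4])
  logits <- params$Wf %*% flat + params$bf
  list(logits = logits, c1 = c1, n1 = n1, p1 = p1, c2 = c2, n2 = n2,
       p2 = p2, flat = flat, dimX = dim(X))
}

cnnBackward <- function(params, arch, X, Y) {
  fw <- cnnForwardTrain(params, arch, X)
  sx <- softmaxXent(fw$logits, Y)
  grads <- lapply(params, function(p) p * 0)
  grads$Wf <- sx$grad %*% t(fw$flat)
  grads$bf <- rowSums(sx$grad)
  dflat <- crossprod(params$Wf, sx$grad)
  dp2 <- array(dflat, dim(fw$p2$out))
  dn2 <- poolBackward(dp2, fw$p2)
  bb2 <- bnBackward(dn2, fw$n2, params$g2)
  grads$g2 <- bb2$dgamma; grads$be2 <- bb2$dbeta
  cb2 <- convBackward(bb2$dX, fw$c2$P, params$K2, arch$k, dim(fw$p1$out))
  grads$K2 <- cb2$dK; grads$b2 <- cb2$db
  dp1 <- poolBackward(cb2$dX, fw$p1)
  bb1 <- bnBackward(dp1, fw$n1, params$g1)
  grads$g1 <- bb1$dgamma; grads$be1 <- bb1$dbeta
  cb1 <- convBackward(bb1$dX, fw$c1$P, params$K1, arch$k, fw$dimX)
  grads$K1 <- cb1$dK; grads$b1 <- cb1$db
  list(grads = grads, loss = sx$loss,
       bn = list(m1 = fw$n1$m, v1 = fw$n1$v, m2 = fw$n2$m, v2 = fw$n2$v))
}

#' Train a CNN classifier on real-valued samples
#'
#' Mini-batch Adam on softmax cross-entropy; batch-norm uses batch
#' statistics during training and exponentially averaged running statistics
#' at prediction time.
#'
#' @param model a [cnnNetwork()].
#' @param samples a [SampleSet-class] of kind "real".
#' @param config a [denseTrainConfig()].
#' @return the trained model.
#' @export
cnnTrain <- function(model, samples, config = denseTrainConfig()) {
  stopifnot(is(samples, "SampleSet"), samples@kind == "real")
  arch <- model$arch
  if (nChannels(samples) != arch$channels)
    stop("sample channels do not match the architecture image size")
  classes <- sort(unique(samples@labels$gesture))
  stopifnot(length(classes) == arch$gestures)
  model$classes <- classes
  X <- reshapeToImage(samples@data, arch$H, arch$W)
  y <- match(samples@labels$gesture, classes)
  n <- dim(X)[4]
  nb <- max(2, round(config$batchFraction * n))
  set.seed(config$seed)
  state <- adamInit(model$params)
  bestLoss <- Inf; wait <- 0; history <- numeric(0)
  mom <- 0.1
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    losses <- numeric(0)
    for (start in seq(1, n, by = nb)) {
      idx <- ord[start:min(start + nb - 1, n)]
      if (length(idx) < 2) next  # batch stats need > 1 sample
      Yb <- oneHot(y[idx], length(classes))
      bg <- cnnBackward(model$params, arch, X[, , , idx, drop = FALSE], Yb)
      up <- adamStep(model$params, bg$grads, state, config$learningRate)
      model$params <- up$params; state <- up$state
      for (nm in names(bg$bn))
        model$bnStats[[nm]] <- (1 - mom) * model$bnStats[[nm]] +
          mom * bg$bn[[nm]]
      losses <- c(losses, bg$loss)
    }
    history <- c(history, mean(losses))
    if (mean(losses) < bestLoss - 1e-4) {
      bestLoss <- mean(losses); wait <- 0
    } else {
      wait <- wait + 1
      if (wait >= config$patience) break
    }
  }
  model$lossHistory <- history
  model
}

# Evaluation-mode forward using running batch-norm statistics.
cnnForwardEval <- function(model, X) {
  params <- model$params; arch <- model$arch; bs <- model$bnStats
  c1 <- convForward(X, params$K1, params$b1, arch$k)
  p1 <- poolForward(bnEval(c1$out, params$g1, params$be1, bs$m1, bs$v1))
  c2 <- convForward(p1$out, params$K2, params$b2, arch$k)
  p2 <- poolForward(bnEval(c2$out, params$g2, params$be2, bs$m2, bs$v2))
  d <- dim(p2$out)
  params$Wf %*% matrix(p2$out, prod(d[1:3]), d[4]) + params$bf
}

#' Predict / evaluate a CNN classifier
#'
#' @param model a trained `CnnModel`.
#' @param samples a [SampleSet-class] of kind "real".
#' @param batchSize forward chunk size.
#' @return `cnnPredict`: predicted labels; `cnnEvaluate`: accuracy.
#' @export
cnnPredict <- function(model, samples, batchSize = 512) {
  arch <- model$arch
  X <- reshapeToImage(samples@data, arch$H, arch$W)
  n <- dim(X)[4]
  classes <- if (is.null(model$classes)) seq_len(arch$gestures) else
    model$classes
  out <- integer(n)
  for (start in seq(1, n, by = batchSize)) {
    idx <- start:min(start + batchSize - 1, n)
    lg <- cnnForwardEval(model, X[, , , idx, drop = FALSE])
    out[idx] <- classes[max.col(t(lg))]
  }
  out
}

#' @rdname cnnPredict
#' @export
cnnEvaluate <- function(model, samples, batchSize = 512) {
  mean(cnnPredict(model, samples, batchSize) == samples@labels$gesture)
}
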