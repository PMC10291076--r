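# LSTM comparator: an input layer, one LSTM layer and a fully-connected
# softmax layer. A real-valued sample (channels x T) is consumed as T steps
# of channel vectors; the readout uses the final hidden state. Trained with
# Adam (lr 0.01), batch size 1/8 of the training set. Implemented directly
# (forward + BPTT) with the standard 4-gate cell.

#' Construct an LSTM classifier
#'
#' @param inputSize channels per time step (128 HD / 8 LD).
#' @param hiddenSize LSTM units, chosen to match the SNN hidden layer
#'   (100 HD / 20 LD).
#' @param outputSize number of gesture classes, default 9.
#' @param seed initialisation seed.
#' @return an `LstmModel` list with parameter matrices `Wx` (4h x i), `Wh`
#'   (4h x h), `b` (4h), `Wo` (o x h), `bo` (o). Gate row blocks are ordered
#'   input, forget, cell, output.
#' @export
lstmNetwork <- function(inputSize, hiddenSize, outputSize = 9, seed = 1) {
  set.seed(seed)
  h <- hiddenSize
  u <- function(r, c, fan) matrix(stats::runif(r * c, -1, 1) / sqrt(fan),
                                  r, c)
  params <- list(Wx = u(4 * h, inputSize, inputSize),
    Wh = u(4 * h, h, h), b = rep(0, 4 * h),
    Wo = u(outputSize, h, h), bo = rep(0, outputSize))
  structure(list(params = params, inputSize = inputSize, hiddenSize = h,
    outputSize = outputSize), class = "LstmModel")
}

#' @export
print.LstmModel <- function(x, ...) {
  cat(sprintf("LstmModel: %d -> %d -> %d (%d parameters)\n", x$inputSize,
    x$hiddenSize, x$outputSize, lstmParameterCount(x)))
  invisible(x)
}

#' Trainable parameter count of an LSTM classifier
#'
#' Gates contribute 4(i*h + h*h + h); the FC layer h*o + o.
#'
#' @param model an `LstmModel`.
#' @export
lstmParameterCount <- function(model) {
  with(model, 4 * (inputSize * hiddenSize + hiddenSize^2 + hiddenSize) +
    hiddenSize * outputSize + outputSize)
}

# Forward pass. X: ch x T x n. Returns logits and (optionally) the cached
# per-step quantities needed for BPTT.
lstmForward <- function(params, X, cache = FALSE) {
  ch <- dim(X)[1]; T <- dim(X)[2]; n <- dim(X)[3]
  h <- ncol(params$Wh)
  H <- C <- matrix(0, h, n)
  ck <- if (cache) vector("list", T)
  for (t in seq_len(T)) {
    xt <- matrix(X[, t, ], ch, n)
    z <- params$Wx %*% xt + params$Wh %*% H + params$b
    i <- sigmoid(z[1:h, , drop = FALSE])
    f <- sigmoid(z[(h + 1):(2 * h), , drop = FALSE])
    g <- tanh(z[(2 * h + 1):(3 * h), , drop = FALSE])
    o <- sigmoid(z[(3 * h + 1):(4 * h), , drop = FALSE])
    Cprev <- C
    C <- f * Cprev + i * g
    tc <- tanh(C)
    if (cache) ck[[t]] <- list(i = i, f = f, g = g, o = o, Cprev = Cprev,
      tc = tc, Hprev = H, xt = xt)
    H <- o * tc
  }
  list(logits = params$Wo %*% H + params$bo, H = H, cache = ck)
}

# BPTT for one mini-batch; returns grads + loss.
lstmBackward <- function(params, X, Y) {
  fw <- lstmForward(params, X, cache = TRUE)
  sx <- softmaxXent(fw$logits, Y)
  h <- ncol(params$Wh); T <- dim(X)[2]
  grads <- lapply(params, function(p) p * 0)
  grads$Wo <- sx$grad %*% t(fw$H)
  grads$bo <- rowSums(sx$grad)
  dH <- crossprod(params$Wo, sx$grad)
  dC <- dH * 0
  for (t in rev(seq_len(T))) {
    k <- fw$cache[[t]]
    dC <- dC + dH * k$o * (1 - k$tc^2)
    di <- dC * k$g * k$i * (1 - k$i)
    df <- dC * k$Cprev * k$f * (1 - k$f)
    dg <- dC * k$i * (1 - k$g^2)
    do <- dH * k$tc * k$o * (1 - k$o)
    dz <- rbind(di, df, dg, do)
    grads$Wx <- grads$Wx + dz %*% t(k$xt)
    grads$Wh <- grads$Wh + dz %*% t(k$Hprev)
    grads$b <- grads$b + rowSums(dz)
    dH <- crossprod(params$Wh, dz)
    dC <- dC * k$f
  }
  list(grads = grads, loss = sx$loss)
}

#' Training configuration for the dense baselines
#'
#' @param learningRate Adam learning rate, default 0.01.
#' @inheritParams trainConfig
#' @return a `TrainConfig` list.
#' @export
denseTrainConfig <- function(learningRate = 0.01, batchFraction = 1 / 8,
                             epochs = 100, patience = 10, seed = 1) {
  structure(list(learningRate = learningRate,
    batchFraction = batchFraction, epochs = as.integer(epochs),
    patience = as.integer(patience), seed = as.integer(seed)),
    class = "TrainConfig")
}

#' Train an LSTM classifier on real-valued samples
#'
#' @param model an [lstmNetwork()].
#' @param samples a [SampleSet-class] of kind "real".
#' @param config a [denseTrainConfig()].
#' @return the trained model (with `classes` and `lossHistory`).
#' @export
lstmTrain <- function(model, samples, config = denseTrainConfig()) {
  stopifnot(is(samples, "SampleSet"), samples@kind == "real")
  classes <- sort(unique(samples@labels$gesture))
  stopifnot(length(classes) == model$outputSize)
  model$classes <- classes
  denseTrainLoop(model, samples@data, samples@labels$gesture, classes,
    config, function(params, X, idx, Yb)
      lstmBackward(params, X[, , idx, drop = FALSE], Yb))
}

#' Predict / evaluate an LSTM classifier
#'
#' @param model a trained `LstmModel`.
#' @param samples a [SampleSet-class] of kind "real".
#' @param batchSize forward chunk size.
#' @return `lstmPredict`: predicted labels; `lstmEvaluate`: accuracy.
#' @export
lstmPredict <- function(model, samples, batchSize = 512) {
  X <- samples@data; n <- dim(X)[3]
  classes <- if (is.null(model$classes)) seq_len(model$outputSize) else
    model$classes
  out <- integer(n)
  for (start in seq(1, n, by = batchSize)) {
    idx <- start:min(start + batchSize - 1, n)
    lg <- lstmForward(model$params, X[, , idx, drop = FALSE])$logits
    out[idx] <- classes[max.col(t(lg))]
  }
  out
}

#' @rdname lstmPredict
#' @export
lstmEvaluate <- function(model, samples, batchSize = 512) {
  mean(lstmPredict(model, samples, batchSize) == samples@labels$gesture)
}
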