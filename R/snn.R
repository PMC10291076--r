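# Spiking neural network with voltage-current LIF neurons.
#
# Per time step, each layer updates its synaptic current and membrane
# voltage,
#   I(t) = mu * I(t-1) + W %*% S_in(t) + b,      mu = exp(-1/tauSyn)
#   U(t) = tau * U(t-1) + R * I(t),              tau = exp(-1/tauMem)
# fires where U >= V_thr2, and resets firing neurons to U * (1 - p). With
# p = 1.5 the post-spike voltage is negative, suppressing continuous firing.
# The plain LIF-V variant sets mu = 0 (current is the instantaneous weighted
# input). The readout is softmax of the second layer's membrane voltage
# averaged over the integration window; training is mini-batch SGD with
# backpropagation through time, substituting a surrogate pseudo-derivative
# for the spike nonlinearity.

#' LIF neuron parameters
#'
#' @param tauMem membrane time constant, default 10 steps.
#' @param tauSyn synaptic-current time constant, default 5 steps.
#' @param vThr2 firing threshold, default 10.
#' @param penalty reset penalty p, default 1.5.
#' @param r membrane resistance, default 1.
#' @param variant "lif-vi" (coupled voltage-current decay) or "lif-v".
#' @return a [LifParams-class].
#' @export
lifParams <- function(tauMem = 10, tauSyn = 5, vThr2 = 10, penalty = 1.5,
                      r = 1, variant = c("lif-vi", "lif-v")) {
  new("LifParams", tauMem = tauMem, tauSyn = tauSyn, vThr2 = vThr2,
    penalty = penalty, r = r, variant = match.arg(variant))
}

#' Decay factors of a LIF parameterisation
#'
#' @param params a [LifParams-class].
#' @return list with `tau` = exp(-1/tauMem) and `mu` = exp(-1/tauSyn)
#'   (0 for the "lif-v" variant).
#' @export
decayFactors <- function(params) {
  list(tau = exp(-1 / params@tauMem),
       mu = if (params@variant == "lif-v") 0 else exp(-1 / params@tauSyn))
}

#' One LIF layer update step
#'
#' Update order: current, voltage, threshold test (fires at U == V_thr2
#' exactly), penalty reset.
#'
#' @param state list with `U` and `I` (neurons x batch matrices or vectors).
#' @param inputSpikes inputs x batch binary matrix (or vector).
#' @param W neurons x inputs weight matrix. @param b neuron biases.
#' @param params a [LifParams-class].
#' @return list(state = list(U, I), spikes = neurons x batch binary matrix,
#'   uPre = pre-reset voltage).
#' @export
lifStep <- function(state, inputSpikes, W, b, params) {
  if (is.vector(inputSpikes)) inputSpikes <- matrix(inputSpikes)
  if (!(length(b) %in% c(1L, nrow(W))) || ncol(W) != nrow(inputSpikes))
    stop("dimension mismatch between weights, biases and input")
  dk <- decayFactors(params)
  I <- dk$mu * state$I + W %*% inputSpikes + b
  U <- dk$tau * state$U + params@r * I
  S <- (U >= params@vThr2) * 1
  list(state = list(U = U * (1 - params@penalty * S), I = I), spikes = S,
       uPre = U)
}

#' Construct a two-hidden-layer SNN
#'
#' Weights are initialised uniformly in (-1, 1) scaled by 1/sqrt(fan-in),
#' biases at zero, under the given seed.
#'
#' @param inputCount input channels (128 for HD, 8 for LD).
#' @param hiddenCount first hidden layer size (100 for HD, 20 for LD).
#' @param outputCount second hidden layer size; one neuron per gesture
#'   class, default 9.
#' @param params a [LifParams-class] shared by both layers.
#' @param timeSteps integration window T, default 100.
#' @param seed initialisation seed.
#' @return an [SnnNetwork-class].
#' @export
snnNetwork <- function(inputCount, hiddenCount, outputCount = 9,
                       params = lifParams(), timeSteps = 100, seed = 1) {
  set.seed(seed)
  W1 <- matrix(stats::runif(hiddenCount * inputCount, -1, 1) /
               sqrt(inputCount), hiddenCount, inputCount)
  W2 <- matrix(stats::runif(outputCount * hiddenCount, -1, 1) /
               sqrt(hiddenCount), outputCount, hiddenCount)
  new("SnnNetwork", W1 = W1, b1 = rep(0, hiddenCount), W2 = W2,
    b2 = rep(0, outputCount), params = params,
    timeSteps = as.integer(timeSteps))
}

#' @describeIn snnNetwork number of trainable parameters:
#'   input x hidden + hidden x output + hidden + output.
#' @param x an [SnnNetwork-class].
#' @export
setMethod("countParameters", "SnnNetwork", function(x)
  length(x@W1) + length(x@W2) + length(x@b1) + length(x@b2))

softmaxCols <- function(z) {
  z <- z - matrix(apply(z, 2, max), nrow(z), ncol(z), byrow = TRUE)
  e <- exp(z)
  e / matrix(colSums(e), nrow(z), ncol(z), byrow = TRUE)
}

#' Forward pass of the SNN
#'
#' Both layers are stepped from zero state for t = 1..T; the class
#' probabilities are softmax((1/T) * sum_t U2(t)) with the post-reset
#' voltages. Layer-2 spiking and reset dynamics are applied even though only
#' the voltage is read out.
#'
#' @param net an [SnnNetwork-class].
#' @param spikes channels x T x n binary array (a single channels x T matrix
#'   is also accepted).
#' @param traces record the per-step states needed for backpropagation.
#' @param resetReadout apply layer-2 spiking/reset during readout (default);
#'   `FALSE` gives a pure integrator readout for comparison.
#' @return list: `probs` (n x classes), `spikes1`/`spikes2` (total spike
#'   counts per sample), and when `traces` is set the per-step state arrays.
#' @export
snnForward <- function(net, spikes, traces = FALSE, resetReadout = TRUE) {
  if (is.matrix(spikes)) spikes <- array(spikes, c(dim(spikes), 1))
  ch <- dim(spikes)[1]; T <- dim(spikes)[2]; n <- dim(spikes)[3]
  if (ch != ncol(net@W1)) stop("channel count does not match network input")
  if (T != net@timeSteps) stop("sample length does not match timeSteps")
  p <- net@params
  dk <- decayFactors(p)
  h <- nrow(net@W1); o <- nrow(net@W2)
  U1 <- I1 <- matrix(0, h, n); U2 <- I2 <- matrix(0, o, n)
  accum <- matrix(0, o, n)
  c1 <- c2 <- rep(0, n)
  tr <- if (traces)
    list(uPre1 = array(0, c(h, n, T)), s1 = array(0, c(h, n, T)),
         uPre2 = array(0, c(o, n, T)), s2 = array(0, c(o, n, T)))
  for (t in seq_len(T)) {
    sIn <- matrix(spikes[, t, ], ch, n)
    I1 <- dk$mu * I1 + net@W1 %*% sIn + net@b1
    U1 <- dk$tau * U1 + p@r * I1
    S1 <- (U1 >= p@vThr2) * 1
    if (traces) { tr$uPre1[, , t] <- U1; tr$s1[, , t] <- S1 }
    U1 <- U1 * (1 - p@penalty * S1)
    I2 <- dk$mu * I2 + net@W2 %*% S1 + net@b2
    U2 <- dk$tau * U2 + p@r * I2
    S2 <- (U2 >= p@vThr2) * 1
    if (traces) { tr$uPre2[, , t] <- U2; tr$s2[, , t] <- S2 }
    if (resetReadout) U2 <- U2 * (1 - p@penalty * S2)
    accum <- accum + U2
    c1 <- c1 + colSums(S1); c2 <- c2 + colSums(S2)
  }
  out <- list(probs = t(softmaxCols(accum / T)), spikes1 = c1, spikes2 = c2)
  if (traces) out$traces <- tr
  out
}

#' Surrogate pseudo-derivative of the spike nonlinearity
#'
#' Normalised fast sigmoid g(v) = (beta/4) / (1 + beta*|v|/2)^2 at membrane
#' distance v = U - V_thr2: non-negative, even, maximal (beta/4) at v = 0,
#' unit integral over the real line. Used backward-only; the forward pass
#' keeps the hard threshold.
#'
#' @param v membrane distance from threshold.
#' @param beta slope, default 10.
#' @export
surrogateGradient <- function(v, beta = 10) {
  (beta / 4) / (1 + beta * abs(v) / 2)^2
}

#' Training configuration for the SNN
#'
#' @param learningRate SGD learning rate, default 0.1.
#' @param batchFraction mini-batch size as a fraction of the training set,
#'   default 1/8.
#' @param epochs maximum epochs, default 100.
#' @param beta surrogate-gradient slope, default 10.
#' @param clipNorm per-tensor gradient L2-norm clip, default 0.3. The
#'   average-membrane-voltage readout amplifies a unit weight change by
#'   roughly 1/((1-mu)(1-tau)) (about 58 at the default time constants), so
#'   raw SGD steps at lr 0.1 overshoot; clipping keeps the default learning
#'   rate usable. Set to `Inf` to disable.
#' @param patience early stop when the epoch training loss has not improved
#'   for this many epochs, default 10.
#' @param seed shuffling seed.
#' @return a `TrainConfig` list.
#' @export
trainConfig <- function(learningRate = 0.1, batchFraction = 1 / 8,
                        epochs = 100, beta = 10, clipNorm = 0.3,
                        patience = 10, seed = 1) {
  stopifnot(learningRate >= 0, batchFraction > 0, batchFraction <= 1)
  structure(list(learningRate = learningRate,
    batchFraction = batchFraction, epochs = as.integer(epochs), beta = beta,
    clipNorm = clipNorm, patience = as.integer(patience),
    seed = as.integer(seed)), class = "TrainConfig")
}

clipGrad <- function(g, maxNorm) {
  nrm <- sqrt(sum(g^2))
  if (is.finite(maxNorm) && nrm > maxNorm) g * (maxNorm / nrm) else g
}

# Surrogate-gradient BPTT for one mini-batch. X: ch x T x nb binary array,
# Y: classes x nb one-hot. Returns gradients and the batch CE loss.
#
# The penalty reset is detached from the gradient graph (its -p*U
# discontinuity, smeared by the surrogate, otherwise amplifies the backward
# recurrence by up to p*V_thr2*g(0) per step and the gradient norm explodes
# exponentially over the 100-step window); only the multiplicative factor
# (1 - p*S) is kept, which makes the recurrence contractive. The surrogate
# replaces dS/dU solely where spikes feed forward (layer 1 -> layer 2).
snnBackward <- function(net, X, Y, beta) {
  p <- net@params; dk <- decayFactors(p)
  T <- net@timeSteps; nb <- dim(X)[3]
  fw <- snnForward(net, X, traces = TRUE)
  tr <- fw$traces
  P <- t(fw$probs)                                   # classes x nb
  loss <- -mean(colSums(Y * log(pmax(P, 1e-12))))
  gRead <- (P - Y) / (T * nb)
  o <- nrow(net@W2); h <- nrow(net@W1)
  gW2 <- matrix(0, o, h); gb2 <- rep(0, o)
  gW1 <- matrix(0, h, ncol(net@W1)); gb1 <- rep(0, h)
  gS1 <- array(0, c(h, nb, T))
  gUnext <- gInext <- matrix(0, o, nb)
  for (t in rev(seq_len(T))) {                       # layer 2
    S <- matrix(tr$s2[, , t], o, nb)
    gUpre <- (gRead + dk$tau * gUnext) * (1 - p@penalty * S)
    gI <- p@r * gUpre + dk$mu * gInext
    S1t <- matrix(tr$s1[, , t], h, nb)
    gW2 <- gW2 + gI %*% t(S1t)
    gb2 <- gb2 + rowSums(gI)
    gS1[, , t] <- crossprod(net@W2, gI)
    gUnext <- gUpre; gInext <- gI
  }
  gUnext <- gInext <- matrix(0, h, nb)
  for (t in rev(seq_len(T))) {                       # layer 1
    uPre <- matrix(tr$uPre1[, , t], h, nb)
    S <- matrix(tr$s1[, , t], h, nb)
    sg <- surrogateGradient(uPre - p@vThr2, beta)
    gUpre <- (dk$tau * gUnext) * (1 - p@penalty * S) +
      matrix(gS1[, , t], h, nb) * sg
    gI <- p@r * gUpre + dk$mu * gInext
    sIn <- matrix(X[, t, ], ncol(net@W1), nb)
    gW1 <- gW1 + gI %*% t(sIn)
    gb1 <- gb1 + rowSums(gI)
    gUnext <- gUpre; gInext <- gI
  }
  list(gW1 = gW1, gb1 = gb1, gW2 = gW2, gb2 = gb2, loss = loss)
}

#' Train an SNN by surrogate-gradient SGD
#'
#' Mini-batch stochastic gradient descent on the cross-entropy of the
#' average-membrane-voltage softmax readout, with gradients propagated
#' through time using [surrogateGradient()] in place of the spike
#' derivative. Deterministic under the config seed.
#'
#' @param net an [SnnNetwork-class].
#' @param samples a [SampleSet-class] of kind "spike"; gestures are the
#'   class labels.
#' @param config a [trainConfig()].
#' @param verbose print per-epoch loss.
#' @return the trained network, with the per-epoch loss history in
#'   `attr(, "lossHistory")`.
#' @export
snnTrain <- function(net, samples, config = trainConfig(),
                     verbose = FALSE) {
  stopifnot(is(samples, "SampleSet"), samples@kind == "spike")
  X <- samples@data
  classes <- sort(unique(samples@labels$gesture))
  if (length(classes) != nrow(net@W2))
    stop("number of gesture classes must equal network output size")
  y <- match(samples@labels$gesture, classes)
  if (any(tabulate(y, length(classes)) == 0)) stop("empty class")
  n <- dim(X)[3]
  nb <- max(1, round(config$batchFraction * n))
  set.seed(config$seed)
  bestLoss <- Inf; wait <- 0
  history <- numeric(0)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    losses <- numeric(0)
    for (start in seq(1, n, by = nb)) {
      idx <- ord[start:min(start + nb - 1, n)]
      Xb <- X[, , idx, drop = FALSE]
      Yb <- matrix(0, length(classes), length(idx))
      Yb[cbind(y[idx], seq_along(idx))] <- 1
      g <- snnBackward(net, Xb, Yb, config$beta)
      cn <- if (is.null(config$clipNorm)) Inf else config$clipNorm
      net@W1 <- net@W1 - config$learningRate * clipGrad(g$gW1, cn)
      net@b1 <- net@b1 - config$learningRate * clipGrad(g$gb1, cn)
      net@W2 <- net@W2 - config$learningRate * clipGrad(g$gW2, cn)
      net@b2 <- net@b2 - config$learningRate * clipGrad(g$gb2, cn)
      losses <- c(losses, g$loss)
    }
    history <- c(history, mean(losses))
    if (verbose) message(sprintf("epoch %d loss %.4f", epoch, mean(losses)))
    if (mean(losses) < bestLoss - 1e-4) {
      bestLoss <- mean(losses); wait <- 0
    } else {
      wait <- wait + 1
      if (wait >= config$patience) break
    }
  }
  attr(net, "classes") <- classes
  attr(net, "lossHistory") <- history
  net
}

#' Predict gesture labels for spike samples
#'
#' @param net a trained [SnnNetwork-class].
#' @param samples a [SampleSet-class] of kind "spike".
#' @param batchSize forward-pass chunk size.
#' @return integer vector of predicted gesture labels.
#' @export
snnPredict <- function(net, samples, batchSize = 512) {
  stopifnot(is(samples, "SampleSet"), samples@kind == "spike")
  classes <- attr(net, "classes")
  if (is.null(classes)) classes <- seq_len(nrow(net@W2))
  X <- samples@data
  n <- dim(X)[3]
  if (n == 0) stop("empty sample set")
  out <- integer(n)
  for (start in seq(1, n, by = batchSize)) {
    idx <- start:min(start + batchSize - 1, n)
    fw <- snnForward(net, X[, , idx, drop = FALSE])
    out[idx] <- classes[max.col(fw$probs)]
  }
  out
}

#' Classification accuracy of an SNN on a test set
#'
#' The ratio of correctly recognised samples to all input samples.
#'
#' @inheritParams snnPredict
#' @return accuracy in [0, 1].
#' @export
snnEvaluate <- function(net, samples, batchSize = 512) {
  mean(snnPredict(net, samples, batchSize) == samples@labels$gesture)
}

#' Mean first-hidden-layer spike release rate over a dataset
#'
#' SRR = total layer-1 spikes / (T x hidden neurons), averaged over samples.
#'
#' @inheritParams snnPredict
#' @return an `SrrValue` whose `srr` is the per-sample mean.
#' @export
hiddenLayerSrr <- function(net, samples, batchSize = 512) {
  stopifnot(is(samples, "SampleSet"), samples@kind == "spike")
  X <- samples@data; n <- dim(X)[3]
  total <- 0
  for (start in seq(1, n, by = batchSize)) {
    idx <- start:min(start + batchSize - 1, n)
    total <- total + sum(snnForward(net, X[, , idx, drop = FALSE])$spikes1)
  }
  structure(list(srr = total / (n * net@timeSteps * nrow(net@W1)),
    n = total, N = nrow(net@W1), T = net@timeSteps * n), class = "SrrValue")
}

#' Write / read an SNN checkpoint
#'
#' Serialises weights, biases, LIF parameters and the class labels to a JSON
#' file with full floating-point precision; the round trip is bit-exact.
#'
#' @param net an [SnnNetwork-class]. @param path file path.
#' @export
writeSnn <- function(net, path) {
  p <- net@params
  # doubles are stored as %.17g strings, which round-trip bit-exactly
  num <- function(x) list(dim = dim(x), values = sprintf("%.17g", x))
  obj <- list(W1 = num(net@W1), b1 = num(net@b1), W2 = num(net@W2),
    b2 = num(net@b2), timeSteps = net@timeSteps,
    params = list(tauMem = p@tauMem, tauSyn = p@tauSyn, vThr2 = p@vThr2,
      penalty = p@penalty, r = p@r, variant = p@variant),
    classes = attr(net, "classes"))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
    null = "null"), path)
  invisible(path)
}

#' @rdname writeSnn
#' @export
readSnn <- function(path) {
  obj <- jsonlite::fromJSON(paste(readLines(path), collapse = "\n"))
  num <- function(x) {
    v <- as.numeric(x$values)
    if (length(x$dim)) array(v, x$dim) else v
  }
  pp <- obj$params
  net <- new("SnnNetwork", W1 = num(obj$W1), b1 = num(obj$b1),
    W2 = num(obj$W2), b2 = num(obj$b2),
    timeSteps = as.integer(obj$timeSteps),
    params = lifParams(pp$tauMem, pp$tauSyn, pp$vThr2, pp$penalty, pp$r,
      pp$variant))
  if (!is.null(obj$classes)) attr(net, "classes") <- as.integer(obj$classes)
  net
}
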