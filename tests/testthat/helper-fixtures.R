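# Shared fixtures, all built in code.

# Tiny LD dataset config: 1 subject, 1 trial, 9 gestures, 2 repetitions.
tinyLdConfig <- function(seed = 5, ...) {
  synthConfig(nSubjects = 1, nTrials = 1, nGestures = 9, nRepetitions = 2,
    channels = "ld", seed = seed, ...)
}

# Cache the tiny LD real/spike sample sets across tests (generation is the
# expensive part).
tinyLdReal <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- samplesFromConfig(tinyLdConfig())
    cache
  }
})

# A 3 x 3 single-array layout for grid-manipulation tests.
toyLayout <- function(rows = 3, cols = 3) {
  arrays <- data.frame(array = 1L, rows = rows, cols = cols, spacing = 10)
  g <- expand.grid(col = seq_len(cols), row = seq_len(rows))
  map <- data.frame(channel = seq_len(rows * cols), array = 1L, row = g$row,
    col = g$col)
  new("ElectrodeLayout", arrays = arrays, map = map)
}

# A recording with a prescribed signal on a toy layout.
toyRecording <- function(signal, layout = toyLayout(),
                         samplingRate = 1000) {
  new("EmgRecording", signal = signal, samplingRate = samplingRate,
    subject = 1L, trial = 1L, gesture = 1L, repetition = 1L,
    layout = layout)
}

# Separable 2-class spike toy: class 1 spikes on channels 1-2, class 2 on
# channels 3-4.
toySpikeSet <- function(nPerClass = 50, T = 100, seed = 2) {
  set.seed(seed)
  n <- 2 * nPerClass
  X <- array(0, c(4, T, n))
  for (i in seq_len(n)) {
    ch <- if (i <= nPerClass) 1:2 else 3:4
    X[ch, , i] <- matrix(rbinom(2 * T, 1, 0.5), 2)
  }
  lab <- data.frame(subject = 1, trial = 1,
    gesture = rep(1:2, each = nPerClass), repetition = 1, window = 1:n)
  new("SampleSet", data = X, labels = lab, kind = "spike")
}

# Random binary spike SampleSet.
randomSpikeSet <- function(ch, T, n, p = 0.2, seed = 1) {
  set.seed(seed)
  new("SampleSet", data = array(rbinom(ch * T * n, 1, p), c(ch, T, n)),
    labels = data.frame(subject = 1, trial = 1,
      gesture = rep_len(1:3, n), repetition = 1, window = 1:n),
    kind = "spike")
}

# Random real-valued SampleSet in [0, 1].
randomRealSet <- function(ch, T, n, seed = 1) {
  set.seed(seed)
  new("SampleSet", data = array(runif(ch * T * n), c(ch, T, n)),
    labels = data.frame(subject = 1, trial = 1,
      gesture = rep_len(1:3, n), repetition = 1, window = 1:n),
    kind = "real")
}

# Independent scalar reference of the SNN forward pass: plain loops over
# neurons and time steps, no matrix algebra shared with the implementation.
scalarSnnForward <- function(net, x) {
  p <- net@params
  tau <- exp(-1 / p@tauMem)
  mu <- if (p@variant == "lif-v") 0 else exp(-1 / p@tauSyn)
  stepLayer <- function(W, b, sIn, U, I) {
    nOut <- nrow(W)
    S <- numeric(nOut)
    for (i in seq_len(nOut)) {
      acc <- 0
      for (j in seq_len(ncol(W))) acc <- acc + W[i, j] * sIn[j]
      I[i] <- mu * I[i] + acc + b[i]
      U[i] <- tau * U[i] + p@r * I[i]
      if (U[i] >= p@vThr2) {
        S[i] <- 1
        U[i] <- U[i] * (1 - p@penalty)
      }
    }
    list(U = U, I = I, S = S)
  }
  h <- nrow(net@W1); o <- nrow(net@W2)
  U1 <- I1 <- numeric(h); U2 <- I2 <- numeric(o)
  acc2 <- numeric(o)
  for (t in seq_len(ncol(x))) {
    l1 <- stepLayer(net@W1, net@b1, x[, t], U1, I1)
    U1 <- l1$U; I1 <- l1$I
    l2 <- stepLayer(net@W2, net@b2, l1$S, U2, I2)
    U2 <- l2$U; I2 <- l2$I
    acc2 <- acc2 + U2
  }
  z <- acc2 / ncol(x)
  e <- exp(z - max(z))
  e / sum(e)
}
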