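test_that("a single LIF step follows the update equations", {
  p <- lifParams()
  tau <- exp(-0.1); mu <- exp(-0.2)
  # pure decay from U = 5, no input
  st <- lifStep(list(U = 5, I = 0), matrix(0, 1, 1), matrix(1, 1, 1), 0, p)
  expect_equal(st$uPre[1, 1], tau * 5, tolerance = 1e-12)
  expect_equal(st$uPre[1, 1], 4.52419, tolerance = 1e-5)
  expect_equal(st$spikes[1, 1], 0)
  # unit synapse driven by a spike every step: hand iteration
  st <- list(U = 0, I = 0)
  us <- numeric(3)
  for (t in 1:3) {
    out <- lifStep(st, matrix(1, 1, 1), matrix(1, 1, 1), 0, p)
    st <- out$state
    us[t] <- out$uPre[1, 1]
  }
  expect_equal(us[1], 1)
  expect_equal(us[2], 2.72357, tolerance = 1e-5)
  expect_equal(us[3], 4.95339, tolerance = 1e-4)
  # reaching threshold emits a spike and resets to a negative value
  out <- lifStep(list(U = 12 / exp(-0.1), I = 0), matrix(0, 1, 1),
    matrix(1, 1, 1), 0, p)
  expect_equal(out$uPre[1, 1], 12)
  expect_equal(out$spikes[1, 1], 1)
  expect_equal(out$state$U[1, 1], 12 * (1 - 1.5))
  expect_lt(out$state$U[1, 1], 0)
  expect_error(lifStep(list(U = 0, I = 0), matrix(0, 2, 1),
    matrix(1, 1, 1), 0, p), "mismatch")
})

test_that("LIF trajectories match the closed forms", {
  p <- lifParams(vThr2 = 1e9)
  tau <- exp(-0.1); mu <- exp(-0.2)
  # no input: U(t) = tau^t U(0)
  st <- list(U = 3, I = 0)
  for (t in 1:20) {
    out <- lifStep(st, matrix(0, 1, 1), matrix(1, 1, 1), 0, p)
    st <- out$state
    expect_equal(st$U[1, 1], tau^t * 3, tolerance = 1e-9)
  }
  # constant drive c: I -> c/(1-mu), U -> c/((1-mu)(1-tau))
  cdrive <- 0.7
  st <- list(U = 0, I = 0)
  for (t in 1:200)
    st <- lifStep(st, matrix(1, 1, 1), matrix(cdrive, 1, 1), 0, p)$state
  expect_equal(st$I[1, 1], cdrive / (1 - mu), tolerance = 1e-6)
  expect_equal(st$U[1, 1], cdrive / ((1 - mu) * (1 - tau)),
    tolerance = 1e-6)
})

test_that("the LIF-V variant is LIF-V-I with the current decay removed", {
  set.seed(5)
  W <- matrix(rnorm(6), 2, 3); b <- c(0.1, -0.1)
  sIn <- matrix(rbinom(3, 1, 0.5))
  stV <- lifStep(list(U = c(1, 2), I = c(5, 5)), sIn, W, b,
    lifParams(variant = "lif-v", vThr2 = 100))
  # mu = 0: current is the instantaneous weighted input, prior I ignored
  expect_equal(stV$state$I, W %*% sIn + b)
  stVi <- lifStep(list(U = c(1, 2), I = c(5, 5)), sIn, W, b,
    lifParams(tauSyn = 1e-9, vThr2 = 100))
  expect_equal(stVi$state$I, stV$state$I, tolerance = 1e-12)
})

test_that("forward pass is symmetric on silent input and normalised", {
  net <- snnNetwork(8, 10, 9, seed = 1)
  fw <- snnForward(net, array(0, c(8, 100, 2)))
  expect_equal(fw$probs, matrix(1 / 9, 2, 9))
  expect_equal(fw$spikes1, c(0, 0))
  set.seed(2)
  sp <- randomSpikeSet(8, 100, 5)
  fw2 <- snnForward(net, sampleData(sp))
  expect_equal(rowSums(fw2$probs), rep(1, 5))
  expect_error(snnForward(net, array(0, c(9, 100, 1))), "channel")
  expect_error(snnForward(net, array(0, c(8, 50, 1))), "timeSteps")
})

test_that("vectorised forward equals the scalar loop reference", {
  for (seed in 1:10) {
    set.seed(seed)
    net <- snnNetwork(4, 3, 2, params = lifParams(vThr2 = 2),
      timeSteps = 20, seed = seed)
    x <- matrix(rbinom(4 * 20, 1, 0.4), 4, 20)
    expect_equal(as.numeric(snnForward(net, x)$probs),
      scalarSnnForward(net, x), tolerance = 1e-10)
  }
})

test_that("surrogate gradient is an even bump with unit mass", {
  beta <- 10
  expect_equal(surrogateGradient(0, beta), beta / 4)
  v <- seq(-5, 5, by = 0.1)
  expect_equal(surrogateGradient(v, beta), surrogateGradient(-v, beta))
  expect_true(all(diff(surrogateGradient(v[v >= 0], beta)) <= 0))
  mass <- integrate(surrogateGradient, -50, 50, beta = beta)$value
  expect_equal(mass, 1, tolerance = 1e-2)
})

test_that("training is deterministic, inert at lr 0 and learns a toy task", {
  toy <- toySpikeSet(20)
  net0 <- snnNetwork(4, 5, 2, seed = 1)
  # lr = 0 leaves weights unchanged
  netz <- snnTrain(net0, toy, trainConfig(learningRate = 0, epochs = 2))
  expect_identical(netz@W1, net0@W1)
  expect_identical(netz@b2, net0@b2)
  # same seed, same trajectory
  n1 <- snnTrain(net0, toy, trainConfig(epochs = 5, seed = 9))
  n2 <- snnTrain(net0, toy, trainConfig(epochs = 5, seed = 9))
  expect_identical(n1@W1, n2@W1)
  expect_identical(n1@W2, n2@W2)
  # separable two-class toy is memorised
  nt <- snnTrain(net0, toy, trainConfig(epochs = 50, seed = 1))
  expect_equal(snnEvaluate(nt, toy), 1)
  expect_equal(snnPredict(nt, toy), sampleLabels(toy)$gesture)
  expect_error(snnTrain(net0, subsetSamples(toy, 1:20),
    trainConfig(epochs = 1)), "classes|empty")
})

test_that("an untrained symmetric net scores at chance on balanced data", {
  set.seed(7)
  sp <- randomSpikeSet(8, 100, 90, p = 0.2, seed = 7)
  sp@labels$gesture <- rep(1:9, each = 10)
  net <- snnNetwork(8, 10, 9, seed = 3)
  acc <- snnEvaluate(net, sp)
  # binomial error band around 1/9
  expect_lt(abs(acc - 1 / 9), 4 * sqrt((1 / 9) * (8 / 9) / 90))
})

test_that("parameter count is sizes plus biases", {
  expect_equal(countParameters(snnNetwork(128, 100, 9)), 13809)
  expect_equal(countParameters(snnNetwork(128, 50, 9)), 6909)
  expect_equal(countParameters(snnNetwork(128, 200, 9)), 27609)
  expect_equal(countParameters(snnNetwork(8, 20, 9)),
    8 * 20 + 20 * 9 + 20 + 9)
})

test_that("hidden-layer SRR is counted over neurons and steps", {
  net <- snnNetwork(4, 10, 2, seed = 1)
  silent <- array(0, c(4, 100, 3))
  expect_equal(hiddenLayerSrr(net, new("SampleSet", data = silent,
    labels = data.frame(subject = 1, trial = 1, gesture = rep(1, 3),
      repetition = 1, window = 1:3), kind = "spike"))$srr, 0)
  # mean layer-1 SRR decreases as V_thr2 rises
  sp <- randomSpikeSet(4, 100, 10, p = 0.3, seed = 4)
  srrs <- vapply(c(-5, -2, 0, 2, 5, 10, 15, 20), function(v) {
    n <- snnNetwork(4, 10, 2, params = lifParams(vThr2 = v), seed = 1)
    hiddenLayerSrr(n, sp)$srr
  }, 0)
  expect_true(all(diff(srrs) <= 1e-12))
  expect_equal(max(srrs), 1)  # every neuron fires every step at V_thr2 = -5
})

test_that("checkpoints round-trip bit-exactly", {
  toy <- toySpikeSet(5)
  net <- snnTrain(snnNetwork(4, 5, 2, seed = 2), toy,
    trainConfig(epochs = 2))
  f <- tempfile(fileext = ".json")
  writeSnn(net, f)
  back <- readSnn(f)
  expect_identical(back@W1, net@W1)
  expect_identical(back@W2, net@W2)
  expect_identical(back@b1, net@b1)
  expect_identical(back@b2, net@b2)
  expect_equal(back@params@tauMem, net@params@tauMem)
  expect_identical(attr(back, "classes"), attr(net, "classes"))
  # predictions identical
  expect_identical(snnPredict(back, toy), snnPredict(net, toy))
})
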