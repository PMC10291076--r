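test_that("LDA places the boundary midway between 1-D class means", {
  set.seed(1)
  x <- matrix(c(rnorm(200, 0, 1), rnorm(200, 2, 1)), ncol = 1)
  y <- rep(1:2, each = 200)
  m <- ldaFit(x, y)
  pr <- ldaPredict(m, matrix(seq(-1, 3, by = 0.01), ncol = 1))
  flip <- seq(-1, 3, by = 0.01)[max(which(pr == 1)) + 1]
  expect_equal(flip, 1, tolerance = 0.15)
})

test_that("LDA matches the brute-force discriminant and MASS::lda", {
  skip_if_not_installed("MASS")
  set.seed(2)
  n <- 60
  X <- rbind(matrix(rnorm(n * 3), ncol = 3),
             matrix(rnorm(n * 3, 1.5), ncol = 3),
             matrix(rnorm(n * 3, -1.5), ncol = 3))
  y <- rep(1:3, each = n)
  m <- ldaFit(X, y, shrinkage = 1e-8)
  # brute-force evaluation of delta_k per test point
  delta <- function(x) {
    vapply(1:3, function(k) {
      mk <- m@means[k, ]
      as.numeric(x %*% m@covInv %*% mk - 0.5 * mk %*% m@covInv %*% mk +
        log(m@priors[k]))
    }, 0)
  }
  Xt <- matrix(rnorm(60), ncol = 3)
  expect_equal(ldaPredict(m, Xt),
    apply(Xt, 1, function(x) which.max(delta(x))))
  ml <- MASS::lda(X, grouping = y)
  expect_gt(mean(ldaPredict(m, Xt) ==
    as.integer(predict(ml, Xt)$class)), 0.95)
})

test_that("LDA separates well-spread classes and not identical ones", {
  set.seed(3)
  n <- 50
  X <- rbind(matrix(rnorm(n * 2, 0), ncol = 2),
             matrix(rnorm(n * 2, 5), ncol = 2),
             matrix(rnorm(n * 2, -5), ncol = 2))
  y <- rep(1:3, each = n)
  m <- ldaFit(X, y)
  expect_gte(mean(ldaPredict(m, X) == y), 0.99)
  # identical class distributions -> chance within binomial error
  X0 <- matrix(rnorm(300 * 2), ncol = 2)
  y0 <- rep(1:2, each = 150)
  acc0 <- mean(ldaPredict(ldaFit(X0, y0), X0) == y0)
  expect_lt(abs(acc0 - 0.5), 4 * sqrt(0.25 / 300))
  expect_error(ldaFit(X, rep(1, length(y))), "2 classes")
})

test_that("LSTM gate counts and gradients are correct", {
  m <- lstmNetwork(3, 4, 2, seed = 1)
  expect_equal(lstmParameterCount(m), 4 * (3 * 4 + 16 + 4) + 4 * 2 + 2)
  # finite-difference check of BPTT on a tiny net
  set.seed(4)
  X <- array(runif(3 * 6 * 4), c(3, 6, 4))
  Y <- spikeEMG:::oneHot(c(1, 2, 1, 2), 2)
  g <- spikeEMG:::lstmBackward(m$params, X, Y)
  lossOf <- function(params) {
    fw <- spikeEMG:::lstmForward(params, X)
    spikeEMG:::softmaxXent(fw$logits, Y)$loss
  }
  eps <- 1e-6
  for (nm in names(m$params)) {
    for (i in seq_len(min(4, length(m$params[[nm]])))) {
      p1 <- m$params; p1[[nm]][i] <- p1[[nm]][i] + eps
      p2 <- m$params; p2[[nm]][i] <- p2[[nm]][i] - eps
      fd <- (lossOf(p1) - lossOf(p2)) / (2 * eps)
      expect_equal(g$grads[[nm]][i], fd, tolerance = 1e-5)
    }
  }
})

test_that("LSTM learns a separable sequence toy and starts at chance", {
  # class 1: constant channel; class 2: alternating channel
  n <- 30; T <- 20
  X <- array(0, c(2, T, 2 * n))
  set.seed(5)
  for (i in seq_len(2 * n)) {
    if (i <= n) X[1, , i] <- 0.8 else X[2, , i] <- rep(c(0.9, 0.1), T / 2)
  }
  lab <- data.frame(subject = 1, trial = 1, gesture = rep(1:2, each = n),
    repetition = 1, window = seq_len(2 * n))
  rs <- new("SampleSet", data = X, labels = lab, kind = "real")
  m0 <- lstmNetwork(2, 6, 2, seed = 1)
  expect_lt(abs(lstmEvaluate(m0, rs) - 0.5), 4 * sqrt(0.25 / (2 * n)))
  mt <- lstmTrain(m0, rs, denseTrainConfig(epochs = 60, seed = 1))
  expect_equal(lstmEvaluate(mt, rs), 1)
  # determinism
  mt2 <- lstmTrain(m0, rs, denseTrainConfig(epochs = 60, seed = 1))
  expect_identical(mt$params, mt2$params)
})

test_that("CNN backprop matches finite differences", {
  arch <- cnnArch(8, gestures = 2, timeSteps = 5)
  m <- cnnNetwork(arch, seed = 1)
  set.seed(6)
  X <- array(runif(5 * 4 * 2 * 4), c(5, 4, 2, 4))
  Y <- spikeEMG:::oneHot(c(1, 2, 2, 1), 2)
  g <- spikeEMG:::cnnBackward(m$params, arch, X, Y)
  lossOf <- function(params) {
    fw <- spikeEMG:::cnnForwardTrain(params, arch, X)
    spikeEMG:::softmaxXent(fw$logits, Y)$loss
  }
  eps <- 1e-5
  for (nm in names(m$params)) {
    for (i in seq_len(min(3, length(m$params[[nm]])))) {
      p1 <- m$params; p1[[nm]][i] <- p1[[nm]][i] + eps
      p2 <- m$params; p2[[nm]][i] <- p2[[nm]][i] - eps
      fd <- (lossOf(p1) - lossOf(p2)) / (2 * eps)
      expect_equal(g$grads[[nm]][i], fd, tolerance = 1e-4,
        label = sprintf("d%s[%d]", nm, i))
    }
  }
})

test_that("CNN has the contracted output shape and learns a toy", {
  arch <- cnnArch(128, gestures = 9, timeSteps = 100)
  m <- cnnNetwork(arch, seed = 1)
  set.seed(7)
  rs <- randomRealSet(128, 100, 4)
  X <- spikeEMG:::reshapeToImage(sampleData(rs), arch$H, arch$W)
  lg <- spikeEMG:::cnnForwardEval(m, X)
  expect_equal(dim(lg), c(9L, 4L))
  # all-zero input with zero-init FC bias -> uniform softmax
  z <- spikeEMG:::cnnForwardEval(m, array(0, c(100, 16, 8, 2)))
  pr <- exp(z) / rep(colSums(exp(z)), each = 9)
  expect_equal(pr, matrix(1 / 9, 9, 2), tolerance = 1e-12)
  # toy: two classes distinguished by which half of the image is lit
  n <- 20
  Xt <- array(0, c(5, 4, 2, 2 * n))
  set.seed(8)
  Xt[, 1:2, , 1:n] <- runif(5 * 2 * 2 * n, 0.5, 1)
  Xt[, 3:4, , (n + 1):(2 * n)] <- runif(5 * 2 * 2 * n, 0.5, 1)
  arch2 <- cnnArch(8, gestures = 2, timeSteps = 5)
  # pack the images back into channel x T samples for the public API
  toSamples <- function(Ximg) {
    nn <- dim(Ximg)[4]
    d <- array(0, c(8, 5, nn))
    for (i in seq_len(nn))
      for (h in 1:4) for (w in 1:2)
        d[(h - 1) * 2 + w, , i] <- Ximg[, h, w, i]
    new("SampleSet", data = d, labels = data.frame(subject = 1, trial = 1,
      gesture = rep(1:2, each = n), repetition = 1,
      window = seq_len(nn)), kind = "real")
  }
  rsT <- toSamples(Xt)
  # full-batch training: batch statistics of tiny mini-batches make the
  # batch-norm layers too noisy to converge on 40 images
  mt <- cnnTrain(cnnNetwork(arch2, seed = 1), rsT,
    denseTrainConfig(epochs = 80, batchFraction = 1, patience = 20,
      seed = 1))
  expect_gte(cnnEvaluate(mt, rsT), 0.95)
})
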