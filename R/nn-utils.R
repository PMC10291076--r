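# Shared utilities for the dense baselines (LSTM, CNN): Adam optimiser and
# softmax cross-entropy.

sigmoid <- function(x) 1 / (1 + exp(-x))

# Adam state for a named list of parameter arrays.
adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

# One Adam update; returns list(params, state).
adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# Softmax cross-entropy on logits (classes x n) against one-hot Y.
# Returns list(loss, probs, grad) with grad = (P - Y)/n.
softmaxXent <- function(logits, Y) {
  P <- softmaxCols(logits)
  list(loss = -mean(colSums(Y * log(pmax(P, 1e-12)))), probs = P,
       grad = (P - Y) / ncol(Y))
}

oneHot <- function(y, K) {
  Y <- matrix(0, K, length(y))
  Y[cbind(y, seq_along(y))] <- 1
  Y
}

# Generic epoch loop shared by the dense baselines: shuffled mini-batches,
# Adam updates, early stop on training-loss plateau.
denseTrainLoop <- function(model, X, y, classes, config, batchFn) {
  n <- if (length(dim(X)) == 3) dim(X)[3] else ncol(X)
  nb <- max(1, round(config$batchFraction * n))
  set.seed(config$seed)
  state <- adamInit(model$params)
  bestLoss <- Inf; wait <- 0; history <- numeric(0)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    losses <- numeric(0)
    for (start in seq(1, n, by = nb)) {
      idx <- ord[start:min(start + nb - 1, n)]
      Yb <- oneHot(match(y[idx], classes), length(classes))
      bg <- batchFn(model$params, X, idx, Yb)
      up <- adamStep(model$params, bg$grads, state, config$learningRate)
      model$params <- up$params; state <- up$state
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
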