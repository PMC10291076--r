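# Evaluation protocols: training-test-ratio sweeps, electrode-shift
# (leave-one-trial-out, user-dependent) and user-independent
# (leave-one-subject-out) cross-validation, encoder/neuron parameter sweeps
# and the four-scheme encoding x neuron ablation. All splits partition at
# repetition/trial/subject granularity, never at window granularity, so
# windows of one repetition can never straddle train and test.

#' Subset a SampleSet by sample index
#'
#' @param samples a [SampleSet-class]. @param idx integer indices.
#' @return the subset [SampleSet-class].
#' @export
subsetSamples <- function(samples, idx) {
  new("SampleSet", data = samples@data[, , idx, drop = FALSE],
    labels = samples@labels[idx, , drop = FALSE], kind = samples@kind,
    meta = samples@meta)
}

#' Split samples by number of training repetitions
#'
#' For every (subject, trial, gesture), the first `N` repetitions in
#' recording order form the training set and the remaining repetitions the
#' test set.
#'
#' @param labels sample label data.frame (needs a `repetition` column).
#' @param N training repetitions, 1 <= N < max repetition.
#' @return list with integer index vectors `train` and `test`.
#' @export
splitByRatio <- function(labels, N) {
  reps <- max(labels$repetition)
  if (N < 1 || N >= reps) stop("N must satisfy 1 <= N < repetitions")
  train <- which(labels$repetition <= N)
  list(train = train, test = setdiff(seq_len(nrow(labels)), train))
}

#' Leave-one-trial-out folds for one subject (electrode-shift protocol)
#'
#' @param labels sample label data.frame.
#' @param subject the subject evaluated (user-dependent).
#' @return list of folds, each `list(train, test, trial)`; indices refer to
#'   `labels` rows.
#' @export
splitLeaveOneTrial <- function(labels, subject) {
  idx <- which(labels$subject == subject)
  trials <- sort(unique(labels$trial[idx]))
  if (length(trials) < 2) stop("need at least 2 trials")
  lapply(trials, function(tr) list(
    train = idx[labels$trial[idx] != tr],
    test = idx[labels$trial[idx] == tr], trial = tr))
}

#' Leave-one-subject-out folds (user-independent protocol)
#'
#' @param labels sample label data.frame.
#' @return list of folds, each `list(train, test, subject)`.
#' @export
splitLeaveOneSubject <- function(labels) {
  subjects <- sort(unique(labels$subject))
  if (length(subjects) < 2) stop("need at least 2 subjects")
  lapply(subjects, function(s) list(
    train = which(labels$subject != s),
    test = which(labels$subject == s), subject = s))
}

#' One-way analysis of variance
#'
#' Standard fixed-effects one-way ANOVA over groups of accuracies, with the
#' degenerate cases defined by continuity: zero between-group variance gives
#' F = 0, p = 1; zero within-group variance with separated means gives
#' F = Inf, p = 0.
#'
#' @param groups list of numeric vectors (>= 2 groups of >= 2 values).
#' @return list with `F` and `p`.
#' @export
oneWayAnova <- function(groups) {
  k <- length(groups)
  if (k < 2 || any(lengths(groups) < 2))
    stop("need >= 2 groups with >= 2 values each")
  n <- lengths(groups)
  N <- sum(n)
  gm <- mean(unlist(groups))
  ssb <- sum(n * (vapply(groups, mean, 0) - gm)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  msb <- ssb / (k - 1); msw <- ssw / (N - k)
  if (msb == 0) return(list(F = 0, p = 1))
  if (msw == 0) return(list(F = Inf, p = 0))
  F <- msb / msw
  list(F = F, p = stats::pf(F, k - 1, N - k, lower.tail = FALSE))
}

#' Protocol configuration
#'
#' @param protocol one of "ratio", "electrode_shift", "user_independent",
#'   "theta_sweep", "vthr2_sweep", "ablation".
#' @param classifier "snn", "lstm", "cnn" or "lda" (the sweeps and the
#'   ablation always run the SNN).
#' @param nRatio training repetitions N for the ratio protocol.
#' @param thetaGrid,vthr2Grid sweep grids; defaults are the standard sweep
#'   orders theta in (-0.4, -0.2, 0, 0.2, 0.4, 0.6, 0.8, 1, 1.5, 2) and
#'   V_thr2 in (-5, -2, 0, 2, 5, 10, 15, 20).
#' @param theta adaptive encoding parameter used outside the theta sweep.
#' @param fixedThreshold fixed-mode encoding threshold (ablation), 0.18.
#' @param vthr2Vi,vthr2V firing thresholds for the LIF-V-I (10) and LIF-V
#'   (0.5) neurons.
#' @param hidden first-hidden-layer size; default 100 for 128 channels and
#'   20 for 8.
#' @param train a [trainConfig()] for the SNN (a [denseTrainConfig()] is
#'   derived from it for LSTM/CNN with Adam lr 0.01).
#' @param seed protocol seed; per-fold seeds derive from it.
#' @param verbose log per-fold progress via `message()`.
#' @return a `ProtocolConfig` list.
#' @export
protocolConfig <- function(protocol = c("ratio", "electrode_shift",
    "user_independent", "theta_sweep", "vthr2_sweep", "ablation"),
    classifier = c("snn", "lstm", "cnn", "lda"), nRatio = 1,
    thetaGrid = c(-0.4, -0.2, 0, 0.2, 0.4, 0.6, 0.8, 1, 1.5, 2),
    vthr2Grid = c(-5, -2, 0, 2, 5, 10, 15, 20), theta = 0.6,
    fixedThreshold = 0.18, vthr2Vi = 10, vthr2V = 0.5, hidden = NULL,
    train = trainConfig(), seed = 1, verbose = FALSE) {
  structure(list(protocol = match.arg(protocol),
    classifier = match.arg(classifier), nRatio = nRatio,
    thetaGrid = thetaGrid, vthr2Grid = vthr2Grid, theta = theta,
    fixedThreshold = fixedThreshold, vthr2Vi = vthr2Vi, vthr2V = vthr2V,
    hidden = hidden, train = train, seed = as.integer(seed),
    verbose = isTRUE(verbose)), class = "ProtocolConfig")
}

#' Read a ProtocolConfig from a YAML file
#'
#' The file's top-level keys mirror the [protocolConfig()] arguments;
#' `train:` may itself be a map of [trainConfig()] arguments.
#'
#' @param path YAML file path.
#' @return a `ProtocolConfig` list.
#' @export
readProtocolConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$train)) y$train <- do.call(trainConfig, y$train)
  do.call(protocolConfig, y)
}

defaultHidden <- function(channels) if (channels >= 128) 100L else 20L

# Train + evaluate one classifier on one fold of real-valued samples.
# Returns accuracy, measured SRRs (test split, SNN only) and the
# operation-count power estimate.
foldResult <- function(trainReal, testReal, classifier, encoder, lif,
                       hidden, trainCfg, seed) {
  ch <- nChannels(trainReal)
  classes <- sort(unique(trainReal@labels$gesture))
  o <- length(classes)
  trainCfg$seed <- seed
  if (classifier == "snn") {
    trainSp <- encodeSamples(trainReal, encoder)
    testSp <- encodeSamples(testReal, encoder)
    net <- snnNetwork(ch, hidden, o, params = lif,
      timeSteps = dim(trainReal@data)[2], seed = seed)
    net <- snnTrain(net, trainSp, trainCfg)
    srr1 <- meanSrr(testSp)
    srr2 <- hiddenLayerSrr(net, testSp)$srr
    acc <- snnEvaluate(net, testSp)
    pw <- powerTotal(snnTotalPower(net@timeSteps, ch, ch, hidden, o,
      srr1, srr2))
    return(list(accuracy = acc, srr1 = srr1, srr2 = srr2, power = pw))
  }
  dc <- denseTrainConfig(epochs = trainCfg$epochs,
    batchFraction = trainCfg$batchFraction, patience = trainCfg$patience,
    seed = seed)
  if (classifier == "lstm") {
    mod <- lstmTrain(lstmNetwork(ch, hidden, o, seed = seed), trainReal, dc)
    return(list(accuracy = lstmEvaluate(mod, testReal), srr1 = NA,
      srr2 = NA,
      power = powerTotal(lstmPower(dim(trainReal@data)[2], ch, hidden, o))))
  }
  if (classifier == "cnn") {
    arch <- cnnArch(ch, o, timeSteps = dim(trainReal@data)[2])
    mod <- cnnTrain(cnnNetwork(arch, seed = seed), trainReal, dc)
    return(list(accuracy = cnnEvaluate(mod, testReal), srr1 = NA,
      srr2 = NA, power = powerTotal(cnnPower(arch$k, arch$k, arch$H,
        arch$W, arch$C, arch$C1, arch$C2, o))))
  }
  mod <- ldaFit(computeTdFeatures(trainReal))
  list(accuracy = ldaEvaluate(mod, computeTdFeatures(testReal)), srr1 = NA,
    srr2 = NA, power = NA)
}

resultRow <- function(protocol, fold, classifier, param, res) {
  data.frame(protocol = protocol, fold = fold, classifier = classifier,
    param = param, accuracy = res$accuracy, srr1 = res$srr1,
    srr2 = res$srr2, power = res$power)
}

#' Run an evaluation protocol over a preprocessed dataset
#'
#' Executes encode -> train -> evaluate per fold (or per sweep grid point)
#' and records accuracy, the mean spike release rate of the test spike
#' samples (SRR1), the mean first-hidden-layer release rate on the test set
#' (SRR2), and the operation-count power estimate using those measured
#' rates. Deterministic under the config seed.
#'
#' @param config a [protocolConfig()].
#' @param samples a [SampleSet-class] of kind "real" (the full dataset; the
#'   protocol performs its own splits).
#' @return a result data.frame: protocol, fold, classifier, param,
#'   accuracy, srr1, srr2, power.
#' @export
runProtocol <- function(config, samples) {
  labels <- samples@labels
  ch <- nChannels(samples)
  hidden <- if (is.null(config$hidden)) defaultHidden(ch) else config$hidden
  enc <- encoderConfig(theta = config$theta)
  lifVi <- lifParams(vThr2 = config$vthr2Vi)
  rows <- list()
  foldN <- 0L  # one seed per fold: grid points / schemes within a fold
               # share it, so comparisons differ only in the parameter
  addFold <- function(protocol, foldId, classifier, param, tr, te, encoder,
                      lif) {
    res <- foldResult(subsetSamples(samples, tr), subsetSamples(samples, te),
      classifier, encoder, lif, hidden, config$train,
      childSeed(config$seed, foldN))
    if (config$verbose)
      message(sprintf("[%s] fold %s %s param %s: accuracy %.3f", protocol,
        foldId, classifier, format(param), res$accuracy))
    rows[[length(rows) + 1]] <<- resultRow(protocol, foldId, classifier,
      param, res)
  }
  if (config$protocol == "ratio") {
    sp <- splitByRatio(labels, config$nRatio)
    foldN <- 1L
    addFold("ratio", 1, config$classifier, config$nRatio, sp$train,
      sp$test, enc, lifVi)
  } else if (config$protocol == "electrode_shift") {
    for (s in sort(unique(labels$subject)))
      for (f in splitLeaveOneTrial(labels, s)) {
        foldN <- foldN + 1L
        addFold("electrode_shift", sprintf("s%d-t%d", s, f$trial),
          config$classifier, NA, f$train, f$test, enc, lifVi)
      }
  } else if (config$protocol == "user_independent") {
    for (f in splitLeaveOneSubject(labels)) {
      foldN <- foldN + 1L
      addFold("user_independent", sprintf("s%d", f$subject),
        config$classifier, NA, f$train, f$test, enc, lifVi)
    }
  } else if (config$protocol == "theta_sweep") {
    sp <- splitByRatio(labels, config$nRatio)
    foldN <- 1L
    for (th in config$thetaGrid)
      addFold("theta_sweep", 1, "snn", th, sp$train, sp$test,
        encoderConfig(theta = th), lifVi)
  } else if (config$protocol == "vthr2_sweep") {
    sp <- splitByRatio(labels, config$nRatio)
    foldN <- 1L
    for (v in config$vthr2Grid)
      addFold("vthr2_sweep", 1, "snn", v, sp$train, sp$test, enc,
        lifParams(vThr2 = v))
  } else if (config$protocol == "ablation") {
    schemes <- list(
      list(name = "adaptive+lif-vi", enc = enc, lif = lifVi),
      list(name = "fixed+lif-vi",
        enc = encoderConfig("fixed", fixedThreshold = config$fixedThreshold),
        lif = lifVi),
      list(name = "adaptive+lif-v", enc = enc,
        lif = lifParams(vThr2 = config$vthr2V, variant = "lif-v")),
      list(name = "fixed+lif-v",
        enc = encoderConfig("fixed", fixedThreshold = config$fixedThreshold),
        lif = lifParams(vThr2 = config$vthr2V, variant = "lif-v")))
    for (s in sort(unique(labels$subject)))
      for (f in splitLeaveOneTrial(labels, s)) {
        foldN <- foldN + 1L
        for (sc in schemes)
          addFold("ablation", sprintf("s%d-t%d", s, f$trial), sc$name, NA,
            f$train, f$test, sc$enc, sc$lif)
      }
  }
  do.call(rbind, rows)
}

#' Write a result table with a JSON run manifest
#'
#' @param results a [runProtocol()] result data.frame.
#' @param dir output directory (created if needed).
#' @param config the [protocolConfig()] used (stored in the manifest).
#' @return `dir`, invisibly.
#' @export
writeResults <- function(results, dir, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(results, file.path(dir, "results.csv"),
    row.names = FALSE)
  manifest <- list(written = format(Sys.time(), tz = "UTC"),
    rows = nrow(results), config = config)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, null = "null",
    force = TRUE), file.path(dir, "manifest.json"))
  invisible(dir)
}
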