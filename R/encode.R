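# Temporal-contrast (incremental) spike encoding. A real-valued window s(t)
# is differenced, diff(t) = s(t+1) - s(t), and a spike is issued wherever
# |diff(t)| reaches a threshold. The threshold is either fixed or adaptive,
# V_thr1 = mean(d) + theta * sd(d) computed from the window's own difference
# statistics, which makes the encoding invariant to positive amplitude
# scaling - the mechanism that confers robustness to electrode shifts and
# inter-subject gain differences.

#' Encoder configuration
#'
#' @param mode "adaptive" (per-channel threshold from the difference
#'   statistics) or "fixed" (constant threshold).
#' @param theta adaptive threshold scale, default 0.6.
#' @param fixedThreshold fixed-mode threshold V_thr1, default 0.18.
#' @param diffStatistic statistics of the absolute differences (default) or
#'   of the signed differences. On oscillatory EMG the signed-difference mean
#'   is near zero, which would drive the threshold negative for the swept
#'   negative theta values; absolute statistics keep every theta meaningful.
#' @param ddof 0 (population standard deviation, default) or 1.
#' @param pooled pool the difference statistics across channels instead of
#'   thresholding each channel by its own distribution.
#' @return an `EncoderConfig` list.
#' @export
encoderConfig <- function(mode = c("adaptive", "fixed"), theta = 0.6,
                          fixedThreshold = 0.18,
                          diffStatistic = c("absolute", "signed"), ddof = 0,
                          pooled = FALSE) {
  mode <- match.arg(mode)
  diffStatistic <- match.arg(diffStatistic)
  if (mode == "fixed" && fixedThreshold <= 0)
    stop("fixedThreshold must be positive in fixed mode")
  stopifnot(ddof %in% c(0, 1))
  structure(list(mode = mode, theta = theta,
    fixedThreshold = fixedThreshold, diffStatistic = diffStatistic,
    ddof = ddof, pooled = pooled), class = "EncoderConfig")
}

#' Adjacent-time-point signal differences
#'
#' @param x channels x T matrix (or numeric vector) with T >= 2.
#' @return channels x (T - 1) matrix of s(t+1) - s(t).
#' @export
incrementalDiff <- function(x) {
  if (is.vector(x)) x <- matrix(x, 1)
  if (ncol(x) < 2) stop("need at least 2 time points")
  x[, -1, drop = FALSE] - x[, -ncol(x), drop = FALSE]
}

#' Adaptive spike threshold from difference statistics
#'
#' V_thr1 = mean(d) + theta * sd(d), where d is the absolute (default) or
#' signed difference sequence and sd uses the configured ddof.
#'
#' @param diffs numeric vector of signal differences.
#' @param theta threshold scale.
#' @param config an [encoderConfig()] supplying `diffStatistic` and `ddof`.
#' @return the threshold (a scalar).
#' @export
adaptiveThreshold <- function(diffs, theta = 0.6,
                              config = encoderConfig(theta = theta)) {
  if (length(diffs) == 0) stop("empty difference sequence")
  d <- if (config$diffStatistic == "absolute") abs(diffs) else diffs
  n <- length(d)
  s <- sqrt(sum((d - mean(d))^2) / max(1, n - config$ddof))
  mean(d) + theta * s
}

# Threshold matrix (channels x 1) for one sample under a config.
sampleThresholds <- function(x, config) {
  d <- incrementalDiff(x)
  if (config$mode == "fixed")
    return(rep(config$fixedThreshold, nrow(x)))
  if (config$pooled)
    return(rep(adaptiveThreshold(as.numeric(d), config$theta, config),
               nrow(x)))
  vapply(seq_len(nrow(x)), function(c)
    adaptiveThreshold(d[c, ], config$theta, config), 0)
}

#' Encode one real-valued sample into a spike sample
#'
#' Per channel, o(1) = 0 and o(t) = 1 iff |diff(t-1)| >= V_thr1 for
#' t = 2..T, so the spike sample has the same length T as its source.
#'
#' @param x channels x T numeric matrix in [0, 1].
#' @param config an [encoderConfig()].
#' @return channels x T binary matrix.
#' @export
encodeSample <- function(x, config = encoderConfig()) {
  if (is.vector(x)) x <- matrix(x, 1)
  thr <- sampleThresholds(x, config)
  d <- abs(incrementalDiff(x))
  cbind(0, (d >= thr) * 1)
}

#' Encode a SampleSet of real-valued windows
#'
#' @param samples a [SampleSet-class] of kind "real".
#' @param config an [encoderConfig()].
#' @return a [SampleSet-class] of kind "spike" carrying encoder provenance
#'   in `meta`.
#' @export
encodeSamples <- function(samples, config = encoderConfig()) {
  stopifnot(is(samples, "SampleSet"), samples@kind == "real")
  d <- samples@data
  out <- array(0, dim(d))
  for (i in seq_len(dim(d)[3]))
    out[, , i] <- encodeSample(d[, , i, drop = FALSE][, , 1], config)
  new("SampleSet", data = out, labels = samples@labels, kind = "spike",
    meta = c(samples@meta, list(encoder = config)))
}

#' Spike release rate
#'
#' SRR = n / (T x N): the number of spikes n over the time window T and the
#' N channels or neurons that could have fired.
#'
#' @param n spike count. @param N channel/neuron count. @param T window
#'   length.
#' @return an `SrrValue` list with `srr`, `n`, `N`, `T`.
#' @export
srrValue <- function(n, N, T) {
  srr <- n / (T * N)
  stopifnot(srr >= 0, srr <= 1)
  structure(list(srr = srr, n = n, N = N, T = T), class = "SrrValue")
}

#' @export
print.SrrValue <- function(x, ...) {
  cat(sprintf("SRR %.4f (%d spikes / %d units x %d steps)\n", x$srr,
    round(x$n), x$N, x$T))
  invisible(x)
}

#' Spike release rate of one spike sample
#'
#' @param spikes channels x T binary matrix.
#' @return an `SrrValue`.
#' @export
spikeSampleSrr <- function(spikes) {
  if (!all(spikes %in% c(0, 1))) stop("spike sample must be binary")
  srrValue(sum(spikes), nrow(spikes), ncol(spikes))
}

#' Mean spike release rate over a spike SampleSet
#'
#' @param samples a [SampleSet-class] of kind "spike".
#' @return mean per-sample SRR (a scalar).
#' @export
meanSrr <- function(samples) {
  stopifnot(is(samples, "SampleSet"), samples@kind == "spike")
  d <- samples@data
  sum(d) / (dim(d)[1] * dim(d)[2] * dim(d)[3])
}
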