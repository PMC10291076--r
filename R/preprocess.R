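# Preprocessing: channel repair, amplitude-based active-segment extraction,
# resampling to 5,000 points, 20-500 Hz FIR band-pass filtering, Min-Max
# normalisation, sliding-window sample extraction and time-domain features.
# The pipeline order is fixed: segment -> resample -> filter -> normalise,
# then windowing.

#' Windowed-sinc FIR band-pass coefficients
#'
#' 50th-order (51-tap) linear-phase Hamming-window FIR band-pass, 20-500 Hz
#' at 1 kHz sampling (the upper edge sits at the Nyquist frequency, so the
#' normalised edge is clipped just below 1).
#'
#' @param order filter order (taps = order + 1).
#' @param low,high band edges in Hz. @param samplingRate Hz.
#' @return numeric vector of `order + 1` coefficients.
#' @export
firBandpassCoefs <- function(order = 50, low = 20, high = 500,
                             samplingRate = 1000) {
  nyq <- samplingRate / 2
  if (high >= nyq) {
    # upper edge at Nyquist: the band-pass degenerates to a high-pass; a
    # 51-tap window leaves residual DC gain at a 20 Hz edge, so the DC
    # response is nulled exactly by removing the tap mean
    h <- as.numeric(signal::fir1(order, low / nyq, type = "high"))
    h - mean(h)
  } else {
    as.numeric(signal::fir1(order, c(low, high) / nyq, type = "pass"))
  }
}

# Causal FIR filtering with zero initial conditions, length-preserving.
firApply <- function(x, h) {
  n <- length(x)
  y <- convolve(x, rev(h), type = "open")
  y[seq_len(n)]
}

# Grid 4-neighbour channel ids (same array) for every channel.
channelNeighbours <- function(layout) {
  m <- layout@map
  lapply(seq_len(nrow(m)), function(i) {
    same <- m$array == m$array[i]
    d <- abs(m$row - m$row[i]) + abs(m$col - m$col[i])
    m$channel[same & d == 1]
  })
}

#' Repair out-of-range channels
#'
#' Channels whose amplitude is beyond a reasonable range (default rule: RMS
#' greater than `factor` times the median channel RMS) are discarded and
#' replaced by the average of their grid-adjacent channels. Refuses to repair
#' more than a small fraction of channels.
#'
#' @param recording an [EmgRecording-class].
#' @param factor outlier rule multiplier on the median channel RMS.
#' @param cap maximum fraction of channels that may be replaced.
#' @param flagged optional explicit integer vector of channels to replace,
#'   bypassing the RMS rule.
#' @return the repaired [EmgRecording-class]; unflagged channels are
#'   bit-identical to the input.
#' @export
repairChannels <- function(recording, factor = 5, cap = 0.05,
                           flagged = NULL) {
  sig <- recording@signal
  if (is.null(flagged)) {
    rms <- sqrt(rowMeans(sig^2))
    flagged <- which(rms > factor * stats::median(rms))
  }
  if (length(flagged) == 0) return(recording)
  if (length(flagged) > max(1, floor(cap * nrow(sig))))
    stop(sprintf("%d channels flagged, exceeds repair cap", length(flagged)))
  nb <- channelNeighbours(recording@layout)
  for (ch in flagged) {
    good <- setdiff(nb[[ch]], flagged)
    if (length(good) == 0)
      stop(sprintf("channel %d cannot be repaired: all neighbours flagged",
                   ch))
    sig[ch, ] <- colMeans(sig[good, , drop = FALSE])
  }
  recording@signal <- sig
  recording
}

#' Locate the active segment of a recording
#'
#' The across-channel mean rectified signal is smoothed by a moving average
#' (default 200 ms) to form an activity envelope; the active segment starts
#' where the envelope first rises to `thresholdFrac` of its peak and ends
#' where it last falls to that level.
#'
#' @param recording an [EmgRecording-class] containing one activity burst.
#' @param thresholdFrac fraction of the envelope peak, default 0.1.
#' @param smoothMs moving-average window in milliseconds.
#' @return integer `c(start, end)`, 1-based inclusive sample indices.
#' @export
segmentActive <- function(recording, thresholdFrac = 0.1, smoothMs = 200) {
  env <- colMeans(abs(recording@signal))
  w <- max(1, round(smoothMs * recording@samplingRate / 1000))
  env <- as.numeric(stats::filter(env, rep(1 / w, w), sides = 2))
  env[is.na(env)] <- 0
  peak <- max(env)
  if (peak <= 0) stop("no activity detected: envelope never exceeds zero")
  above <- which(env >= thresholdFrac * peak)
  if (length(above) == 0) stop("no activity detected")
  c(min(above), max(above))
}

#' Resample a segment to a fixed length
#'
#' Linear interpolation on a uniform grid, per channel. A segment already of
#' the target length is returned value-identical.
#'
#' @param segment channels x samples numeric matrix.
#' @param nOut target length, default 5000 (5 s at 1 kHz).
#' @return channels x `nOut` matrix.
#' @export
resampleSegment <- function(segment, nOut = 5000) {
  if (!is.matrix(segment) || ncol(segment) < 2)
    stop("segment must be a matrix with at least 2 samples")
  len <- ncol(segment)
  xout <- seq(1, len, length.out = nOut)
  t(apply(segment, 1, function(ch)
    stats::approx(seq_len(len), ch, xout = xout)$y))
}

#' Band-pass filter a segment
#'
#' Applies the 20-500 Hz 50th-order FIR filter per channel (causal, zero
#' initial conditions, length-preserving; the startup transient is retained
#' for determinism).
#'
#' @param segment channels x samples matrix at 1 kHz.
#' @param coefs filter coefficients, default [firBandpassCoefs()].
#' @return filtered matrix of the same shape.
#' @export
bandpassFilter <- function(segment, coefs = firBandpassCoefs()) {
  t(apply(segment, 1, firApply, h = coefs))
}

#' Min-Max normalise a segment to [0, 1]
#'
#' Each channel is mapped by (x - min)/(max - min) using the segment's own
#' extrema (or the joint extrema over all channels when
#' `perChannel = FALSE`). A constant channel is set to 0 with a warning.
#'
#' @param segment channels x samples matrix.
#' @param perChannel use each channel's own extrema (default) or the whole
#'   segment's.
#' @return matrix with values in [0, 1].
#' @export
minmaxNormalize <- function(segment, perChannel = TRUE) {
  if (!perChannel) {
    lo <- min(segment); hi <- max(segment)
    if (hi == lo) { warning("constant segment; set to 0"); return(segment * 0) }
    return((segment - lo) / (hi - lo))
  }
  out <- segment
  for (c in seq_len(nrow(segment))) {
    lo <- min(segment[c, ]); hi <- max(segment[c, ])
    if (hi == lo) {
      warning(sprintf("constant channel %d; set to 0", c))
      out[c, ] <- 0
    } else out[c, ] <- (segment[c, ] - lo) / (hi - lo)
  }
  out
}

#' Number of sliding windows in a region
#' @param regionLen,win,step lengths in samples.
#' @export
windowCount <- function(regionLen, win, step) {
  if (regionLen < win) stop("region shorter than window")
  (regionLen - win) %/% step + 1
}

#' Extract sliding windows from the stabilisation phase
#'
#' Windows of length `win` at offsets 0, `step`, 2*`step`, ... within the
#' half-open region `[region[1], region[2])` (0-based sample indices). The
#' default region is the 2nd-to-4th second of a 5,000-point segment, giving
#' 39 windows of 100 ms at 50 ms increment.
#'
#' @param segment channels x samples matrix.
#' @param region 0-based half-open `c(start, end)`.
#' @param win,step window length and increment in samples.
#' @return channels x win x k array of windows.
#' @export
extractWindows <- function(segment, region = c(2000, 4000), win = 100,
                           step = 50) {
  regionLen <- region[2] - region[1]
  k <- windowCount(regionLen, win, step)
  if (region[2] > ncol(segment)) stop("region exceeds segment length")
  out <- array(0, c(nrow(segment), win, k))
  for (i in seq_len(k)) {
    off <- region[1] + (i - 1) * step
    out[, , i] <- segment[, (off + 1):(off + win), drop = FALSE]
  }
  out
}

#' Time-domain features of real-valued samples
#'
#' Per channel and window: MAV (mean absolute value of the mean-subtracted
#' window), VAR (sample variance), WL (waveform length, the summed absolute
#' first difference) and ZC (zero crossings of the mean-subtracted window).
#' Mean subtraction for MAV/ZC restores the standard definitions on windows
#' that were Min-Max normalised to [0, 1] and therefore never cross zero
#' literally.
#'
#' @param samples a [SampleSet-class] of kind "real".
#' @return a [SampleSet-class] of kind "feature" (channels x 4 x n, columns
#'   MAV, VAR, WL, ZC).
#' @export
computeTdFeatures <- function(samples) {
  stopifnot(is(samples, "SampleSet"), samples@kind == "real")
  d <- samples@data
  n <- dim(d)[3]; ch <- dim(d)[1]
  out <- array(0, c(ch, 4, n))
  for (i in seq_len(n)) {
    x <- matrix(d[, , i], ch, dim(d)[2])
    cx <- x - rowMeans(x)
    dx <- x[, -1, drop = FALSE] - x[, -ncol(x), drop = FALSE]
    out[, 1, i] <- rowMeans(abs(cx))
    out[, 2, i] <- apply(x, 1, stats::var)
    out[, 3, i] <- rowSums(abs(dx))
    out[, 4, i] <- rowSums(cx[, -1, drop = FALSE] *
                           cx[, -ncol(cx), drop = FALSE] < 0)
  }
  new("SampleSet", data = out, labels = samples@labels, kind = "feature",
      meta = samples@meta)
}

#' Run the full preprocessing pipeline on one recording
#'
#' segment -> resample to 5,000 points -> 20-500 Hz FIR filter -> Min-Max
#' normalise -> sliding windows over the stabilisation phase.
#'
#' @param recording an [EmgRecording-class].
#' @param repair apply [repairChannels()] first (off by default; the
#'   synthetic generator produces no out-of-range channels).
#' @param region,win,step windowing parameters, see [extractWindows()].
#' @inheritParams minmaxNormalize
#' @return channels x win x k array of real-valued windows in [0, 1].
#' @export
preprocessRecording <- function(recording, repair = FALSE,
                                region = c(2000, 4000), win = 100,
                                step = 50, perChannel = TRUE) {
  if (repair) recording <- repairChannels(recording)
  se <- segmentActive(recording)
  seg <- recording@signal[, se[1]:se[2], drop = FALSE]
  seg <- resampleSegment(seg, 5000)
  seg <- bandpassFilter(seg)
  seg <- minmaxNormalize(seg, perChannel = perChannel)
  extractWindows(seg, region = region, win = win, step = step)
}

#' Preprocess a dataset of recordings into a real-valued SampleSet
#'
#' @param dataset list of [EmgRecording-class].
#' @inheritParams preprocessRecording
#' @return a [SampleSet-class] of kind "real".
#' @export
preprocessDataset <- function(dataset, repair = FALSE,
                              region = c(2000, 4000), win = 100, step = 50,
                              perChannel = TRUE) {
  parts <- lapply(dataset, function(rec) {
    w <- preprocessRecording(rec, repair = repair, region = region,
      win = win, step = step, perChannel = perChannel)
    k <- dim(w)[3]
    list(w = w, lab = data.frame(subject = rec@subject, trial = rec@trial,
      gesture = rec@gesture, repetition = rec@repetition,
      window = seq_len(k)))
  })
  ch <- dim(parts[[1]]$w)[1]; win <- dim(parts[[1]]$w)[2]
  n <- sum(vapply(parts, function(p) dim(p$w)[3], 0L))
  data <- array(0, c(ch, win, n))
  i <- 0
  for (p in parts) {
    k <- dim(p$w)[3]
    data[, , (i + 1):(i + k)] <- p$w
    i <- i + k
  }
  labels <- do.call(rbind, lapply(parts, `[[`, "lab"))
  new("SampleSet", data = data, labels = labels, kind = "real")
}

#' Generate and preprocess samples directly from a synthetic config
#'
#' Streams one recording at a time (generate -> preprocess -> windows), so
#' large datasets never reside in memory as raw signals.
#'
#' @param config a [synthConfig()].
#' @param subjects,trials,gestures,repetitions label subsets (defaults: all).
#' @inheritParams preprocessRecording
#' @return a [SampleSet-class] of kind "real".
#' @export
samplesFromConfig <- function(config, subjects = seq_len(config$nSubjects),
                              trials = seq_len(config$nTrials),
                              gestures = seq_len(config$nGestures),
                              repetitions = seq_len(config$nRepetitions),
                              region = c(2000, 4000), win = 100, step = 50) {
  grid <- expand.grid(repetition = repetitions, gesture = gestures,
    trial = trials, subject = subjects)
  nCh <- if (config$channels == "ld") 8L else 128L
  k <- windowCount(region[2] - region[1], win, step)
  n <- nrow(grid) * k
  data <- array(0, c(nCh, win, n))
  labels <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    rec <- generateRecording(config, grid$subject[i], grid$trial[i],
      grid$gesture[i], grid$repetition[i])
    data[, , ((i - 1) * k + 1):(i * k)] <-
      preprocessRecording(rec, region = region, win = win, step = step)
    labels[[i]] <- data.frame(subject = grid$subject[i],
      trial = grid$trial[i], gesture = grid$gesture[i],
      repetition = grid$repetition[i], window = seq_len(k))
  }
  new("SampleSet", data = data, labels = do.call(rbind, labels),
      kind = "real")
}
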