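# Synthetic sEMG generator.
#
# Surface EMG is modelled as amplitude-modulated band-limited Gaussian noise:
# each channel's signal is (spatial activation gain x gesture envelope) x
# coloured noise (20-500 Hz) plus an independent noise floor. Gestures differ
# by their spatial activation maps over the electrode grids; electrode shift
# is an integer translation of those maps; subjects differ by seeded map
# jitter and gain.

#' High-density 128-channel electrode layout
#'
#' Two 48-channel (6 x 8) arrays with 14 mm spacing (forearm extensor and
#' flexor) and two 16-channel (4 x 4) arrays with 18 mm spacing (biceps,
#' triceps). Channels are numbered array by array, row-major.
#'
#' @return an [ElectrodeLayout-class] with 128 channels.
#' @export
hdLayout <- function() {
  arrays <- data.frame(array = 1:4, rows = c(6, 6, 4, 4),
    cols = c(8, 8, 4, 4), spacing = c(14, 14, 18, 18))
  map <- do.call(rbind, lapply(1:4, function(a) {
    g <- expand.grid(col = seq_len(arrays$cols[a]),
                     row = seq_len(arrays$rows[a]))
    data.frame(array = a, row = g$row, col = g$col)
  }))
  map <- cbind(channel = seq_len(nrow(map)), map)
  new("ElectrodeLayout", arrays = arrays, map = map)
}

#' Low-density 8-channel layout
#'
#' Eight discrete channels, represented as eight 1 x 1 arrays. The channel
#' ids carried in the map are the HD channels chosen by
#' [selectLdChannels()].
#'
#' @param channelIds the HD channel ids the LD montage is taken from;
#'   defaults to `selectLdChannels(hdLayout())`.
#' @return an [ElectrodeLayout-class] with 8 channels.
#' @export
ldLayout <- function(channelIds = selectLdChannels(hdLayout())) {
  stopifnot(length(channelIds) == 8)
  arrays <- data.frame(array = 1:8, rows = 1L, cols = 1L, spacing = NA_real_)
  map <- data.frame(channel = seq_len(8), array = 1:8, row = 1L, col = 1L)
  lay <- new("ElectrodeLayout", arrays = arrays, map = map)
  attr(lay, "sourceChannels") <- as.integer(channelIds)
  lay
}

#' Select the 8 low-density channels from a high-density layout
#'
#' From each 48-channel (6 x 8) array, a centred 6 x 6 electrode matrix is
#' taken, partitioned into four 3 x 3 sub-matrices, and the centre electrode
#' of each sub-matrix is selected: 4 channels per array, 8 in total. The
#' selection is fully deterministic.
#'
#' @param layout an [ElectrodeLayout-class] containing the two 48-channel
#'   arrays.
#' @return integer vector of 8 channel ids.
#' @export
selectLdChannels <- function(layout) {
  a <- layout@arrays
  big <- a$array[a$rows * a$cols == 48]
  if (length(big) < 2)
    stop("layout lacks the two 48-channel arrays")
  unlist(lapply(big[1:2], function(arr) {
    rows <- a$rows[a$array == arr]; cols <- a$cols[a$array == arr]
    # centred 6 x 6 sub-grid; 3 x 3 block centres at offsets 2 and 5 (1-based)
    rOff <- (rows - 6) %/% 2; cOff <- (cols - 6) %/% 2
    centres <- expand.grid(row = rOff + c(2, 5), col = cOff + c(2, 5))
    sapply(seq_len(nrow(centres)), function(i) {
      m <- layout@map
      m$channel[m$array == arr & m$row == centres$row[i] &
                m$col == centres$col[i]]
    })
  }))
}

#' Configuration of the synthetic dataset
#'
#' Defaults follow the acquisition protocol the generator emulates: 8
#' subjects, 5 trials (separate wearings, hence electrode shifts), 9
#' gestures, 8 repetitions, 1 kHz sampling, 5 s repetitions composed of a
#' 2 s onset ramp, 2 s steady plateau and 1 s decay.
#'
#' @param nSubjects,nTrials,nGestures,nRepetitions counts, all >= 1.
#' @param samplingRate Hz. @param duration seconds per repetition.
#' @param channels "hd" (128 channels) or "ld" (8 channels).
#' @param shiftMagnitude maximum trial-level electrode shift in grid units
#'   (integer translation, drawn uniformly per trial).
#' @param subjectVariability scale of subject-level activation-map jitter
#'   and gain spread.
#' @param noiseFloor standard deviation of the additive measurement noise,
#'   relative to a fully active channel's unit amplitude.
#' @param seed master seed; every subject/trial/repetition seed derives from
#'   it, so any sub-collection is independently reproducible.
#' @return a `SynthConfig` list.
#' @export
synthConfig <- function(nSubjects = 8, nTrials = 5, nGestures = 9,
                        nRepetitions = 8, samplingRate = 1000, duration = 5,
                        channels = c("hd", "ld"), shiftMagnitude = 1,
                        subjectVariability = 0.3, noiseFloor = 0.05,
                        seed = 1) {
  channels <- match.arg(channels)
  counts <- c(nSubjects, nTrials, nGestures, nRepetitions)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("subject/trial/gesture/repetition counts must be positive integers")
  if (duration * samplingRate < 200)
    stop("duration too short for windowing")
  structure(list(nSubjects = as.integer(nSubjects),
    nTrials = as.integer(nTrials), nGestures = as.integer(nGestures),
    nRepetitions = as.integer(nRepetitions), samplingRate = samplingRate,
    duration = duration, channels = channels,
    shiftMagnitude = as.integer(shiftMagnitude),
    subjectVariability = subjectVariability, noiseFloor = noiseFloor,
    seed = as.integer(seed)), class = "SynthConfig")
}

# Deterministic 32-bit child-seed derivation (linear congruential mixing).
childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 69069 + as.numeric(k) * 104729 + 1) %%
             2147483563)
}

#' Subject profile: per-gesture spatial activation maps
#'
#' Each gesture activates a smooth Gaussian blob of channels on each array;
#' blob centres are gesture-specific lattice positions perturbed by a
#' subject-specific seeded jitter, and channel gains carry a subject-specific
#' multiplicative log-normal spread. The profile is fully determined by its
#' seed.
#'
#' @param layout the HD [ElectrodeLayout-class] the maps live on.
#' @param nGestures number of gesture classes.
#' @param seed subject seed.
#' @param variability jitter/gain spread scale (0 = identical subjects).
#' @param noiseFloor stored for signal generation.
#' @return a `SubjectProfile` list: `maps` (nGestures x channels, in [0,1]),
#'   `globalGain`, envelope durations `onset`/`steady`/`offset` (s),
#'   `noiseFloor`, `seed`.
#' @export
subjectProfile <- function(layout, nGestures = 9, seed = 1,
                           variability = 0.3, noiseFloor = 0.05) {
  set.seed(childSeed(seed, 17))
  m <- layout@map
  a <- layout@arrays
  maps <- matrix(0, nGestures, nrow(m))
  for (g in seq_len(nGestures)) {
    for (arr in a$array) {
      rows <- a$rows[a$array == arr]; cols <- a$cols[a$array == arr]
      idx <- which(m$array == arr)
      # gesture-specific base centre spread over the grid, subject jitter
      cr <- 1 + ((g * 2 + arr) %% rows) + rnorm(1, 0, variability)
      cc <- 1 + ((g * 3 + 2 * arr) %% cols) + rnorm(1, 0, variability)
      d2 <- (m$row[idx] - cr)^2 + (m$col[idx] - cc)^2
      sigma <- 1.5
      w <- exp(-d2 / (2 * sigma^2))
      # the small arrays carry weaker, secondary activation
      if (rows * cols < 48) w <- 0.4 * w
      maps[g, idx] <- w
    }
    gainJitter <- exp(rnorm(nrow(m), 0, 0.3 * variability))
    maps[g, ] <- pmin(1, maps[g, ] * gainJitter / max(maps[g, ] * gainJitter))
  }
  structure(list(maps = maps, globalGain = exp(rnorm(1, 0, variability / 2)),
    onset = 2, steady = 2, offset = 1, noiseFloor = noiseFloor,
    seed = as.integer(seed)), class = "SubjectProfile")
}

#' Translate a profile's activation maps on the electrode grids
#'
#' Emulates electrode shift in the medial/lateral or distal/proximal
#' directions (no rotation): every gesture's activation map is translated by
#' (`dRow`, `dCol`) grid units on each array independently, with positions
#' shifted off-grid filled by edge replication. Shift (0, 0) is the identity.
#'
#' @param profile a `SubjectProfile`.
#' @param layout the [ElectrodeLayout-class] the maps are indexed by.
#' @param shift integer vector `c(dRow, dCol)`.
#' @return the shifted `SubjectProfile`.
#' @export
applyElectrodeShift <- function(profile, layout, shift) {
  dRow <- as.integer(shift[1]); dCol <- as.integer(shift[2])
  a <- layout@arrays; m <- layout@map
  if (any(abs(dRow) >= a$rows) || any(abs(dCol) >= a$cols))
    stop("shift exceeds grid extent")
  if (dRow == 0 && dCol == 0) return(profile)
  maps <- profile$maps
  for (arr in a$array) {
    rows <- a$rows[a$array == arr]; cols <- a$cols[a$array == arr]
    idx <- which(m$array == arr)
    src <- cbind(pmin(pmax(m$row[idx] - dRow, 1), rows),
                 pmin(pmax(m$col[idx] - dCol, 1), cols))
    # channel at source grid position (edge-replicated)
    lut <- matrix(NA_integer_, rows, cols)
    lut[cbind(m$row[idx], m$col[idx])] <- idx
    maps[, idx] <- maps[, lut[src], drop = FALSE]
  }
  profile$maps <- maps
  profile
}

#' The (unshifted) subject profile a config implies
#'
#' @param config a [synthConfig()].
#' @param subject 1-based subject index.
#' @return the `SubjectProfile` used for this subject's recordings, before
#'   any trial-level electrode shift.
#' @export
subjectProfileFor <- function(config, subject) {
  subjectProfile(hdLayout(), config$nGestures,
    seed = childSeed(config$seed, 1000 + subject),
    variability = config$subjectVariability,
    noiseFloor = config$noiseFloor)
}

# Trial-level shift draw: uniform on {-m..m}^2, seeded per (subject, trial).
trialShift <- function(config, subject, trial) {
  m <- config$shiftMagnitude
  if (m == 0) return(c(0L, 0L))
  set.seed(childSeed(childSeed(config$seed, 1000 + subject), 37 + trial))
  sample(seq(-m, m), 2, replace = TRUE)
}

# Band-limited (20-500 Hz) unit-variance Gaussian noise of length n at 1 kHz.
bandlimitedNoise <- function(n, samplingRate) {
  h <- firBandpassCoefs(samplingRate = samplingRate)
  x <- stats::filter(c(rnorm(length(h) - 1), rnorm(n)), h, sides = 1)
  x <- as.numeric(x[length(h):(length(h) + n - 1)])
  x / sqrt(sum(h^2))
}

# Active-muscle component: band-limited noise under a log-normal amplitude
# modulation with ~20 ms coherence, normalised to unit RMS. The modulation
# makes the marginal distribution leptokurtic (heavy-tailed), as interference
# sEMG is at moderate contraction - grouped motor-unit firings produce
# bursts, not a stationary Gaussian. This matters downstream: an adaptive
# (shape-based) spike encoder fires at a rate set by the amplitude
# *distribution shape*, which for a Gaussian process is the same on every
# channel; the burstiness is what makes active channels distinguishable from
# the Gaussian noise floor in a gain-invariant way.
activeEmgNoise <- function(n, samplingRate, modDepth = 1.3, modMs = 20) {
  g <- bandlimitedNoise(n, samplingRate)
  w <- max(1, round(modMs * samplingRate / 1000))
  pad <- 4 * w
  z <- stats::filter(rnorm(n + 2 * pad), rep(1 / w, w), sides = 2)
  z <- as.numeric(z[(pad + 1):(pad + n)])
  z <- (z - mean(z)) / stats::sd(z)
  x <- g * exp(modDepth * z)
  x / stats::sd(x)
}

# Activity envelope: linear onset ramp, plateau, linear decay.
gestureEnvelope <- function(n, samplingRate, onset = 2, steady = 2,
                            offset = 1) {
  nOn <- round(onset * samplingRate); nSt <- round(steady * samplingRate)
  nOff <- n - nOn - nSt
  c(seq_len(nOn) / nOn, rep(1, nSt),
    if (nOff > 0) seq(nOff - 1, 0) / nOff else numeric(0))
}

#' Generate one synthetic sEMG recording
#'
#' Fully deterministic given the config's master seed and the label tuple:
#' the subject profile, the trial's electrode shift, and the repetition's
#' noise realisation are all derived seeds.
#'
#' @param config a [synthConfig()].
#' @param subject,trial,gesture,repetition 1-based labels within the
#'   configured ranges.
#' @return an [EmgRecording-class].
#' @export
generateRecording <- function(config, subject, trial, gesture, repetition) {
  stopifnot(subject >= 1, subject <= config$nSubjects,
            trial >= 1, trial <= config$nTrials,
            gesture >= 1, gesture <= config$nGestures,
            repetition >= 1, repetition <= config$nRepetitions)
  hd <- hdLayout()
  profile <- applyElectrodeShift(subjectProfileFor(config, subject), hd,
    trialShift(config, subject, trial))
  if (config$channels == "ld") {
    layout <- ldLayout()
    chan <- attr(layout, "sourceChannels")
  } else {
    layout <- hd
    chan <- seq_len(nrow(hd@map))
  }
  n <- round(config$duration * config$samplingRate)
  env <- gestureEnvelope(n, config$samplingRate, profile$onset,
    profile$steady, profile$offset)
  amp <- profile$globalGain * (0.02 + profile$maps[gesture, chan])
  set.seed(childSeed(childSeed(childSeed(config$seed, 1000 + subject),
    37 + trial), gesture * 64 + repetition))
  sig <- matrix(0, length(chan), n)
  for (c in seq_along(chan)) {
    sig[c, ] <- amp[c] * env * activeEmgNoise(n, config$samplingRate) +
      config$noiseFloor * rnorm(n)
  }
  new("EmgRecording", signal = sig, samplingRate = config$samplingRate,
    subject = as.integer(subject), trial = as.integer(trial),
    gesture = as.integer(gesture), repetition = as.integer(repetition),
    layout = layout)
}

#' Generate a full labelled synthetic dataset
#'
#' @param config a [synthConfig()].
#' @return a list of [EmgRecording-class], one per (subject, trial, gesture,
#'   repetition) combination, in that nesting order;
#'   `nSubjects * nTrials * nGestures * nRepetitions` recordings in total.
#' @examples
#' cfg <- synthConfig(nSubjects = 1, nTrials = 1, nGestures = 2,
#'                    nRepetitions = 1, channels = "ld", seed = 7)
#' ds <- generateDataset(cfg)
#' length(ds)
#' @export
generateDataset <- function(config) {
  grid <- expand.grid(repetition = seq_len(config$nRepetitions),
    gesture = seq_len(config$nGestures), trial = seq_len(config$nTrials),
    subject = seq_len(config$nSubjects))
  lapply(seq_len(nrow(grid)), function(i)
    generateRecording(config, grid$subject[i], grid$trial[i],
      grid$gesture[i], grid$repetition[i]))
}

#' Label table of a generated dataset
#'
#' @param dataset a list of [EmgRecording-class].
#' @return data.frame with subject, trial, gesture, repetition per recording.
#' @export
datasetLabels <- function(dataset) {
  do.call(rbind, lapply(dataset, function(r)
    data.frame(subject = r@subject, trial = r@trial, gesture = r@gesture,
               repetition = r@repetition)))
}
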