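test_that("layouts have the documented geometry", {
  hd <- hdLayout()
  expect_equal(nChannels(hd), 128)
  expect_equal(sum(hd@arrays$rows * hd@arrays$cols), 128)
  expect_equal(sort(hd@arrays$rows * hd@arrays$cols), c(16, 16, 48, 48))
  expect_true(validObject(hd))
  ld <- ldLayout()
  expect_equal(nChannels(ld), 8)
})

test_that("LD channel selection picks the centres of the 3x3 blocks", {
  hd <- hdLayout()
  sel <- selectLdChannels(hd)
  expect_length(sel, 8)
  expect_length(unique(sel), 8)
  m <- hd@map[match(sel, hd@map$channel), ]
  # 4 channels from each 48-channel array
  expect_equal(as.integer(table(m$array)), c(4L, 4L))
  # centres of the four 3x3 blocks of the centred 6x6 grid: rows {2, 5},
  # cols offset by 1 -> {3, 6} on the 6 x 8 arrays
  expect_setequal(unique(m$row), c(2, 5))
  expect_setequal(unique(m$col), c(3, 6))
  expect_identical(sel, selectLdChannels(hd))
  expect_error(selectLdChannels(toyLayout()), "48-channel")
})

test_that("generation is deterministic and respects configured counts", {
  cfg <- synthConfig(nSubjects = 1, nTrials = 2, nGestures = 2,
    nRepetitions = 2, channels = "ld", seed = 7)
  d1 <- generateDataset(cfg)
  d2 <- generateDataset(cfg)
  expect_length(d1, 1 * 2 * 2 * 2)
  expect_identical(lapply(d1, signalMatrix), lapply(d2, signalMatrix))
  lab <- datasetLabels(d1)
  expect_equal(nrow(unique(lab)), 8)
  # a different master seed changes the signals
  d3 <- generateRecording(synthConfig(nSubjects = 1, nTrials = 2,
    nGestures = 2, nRepetitions = 2, channels = "ld", seed = 8),
    1, 1, 1, 1)
  expect_false(identical(signalMatrix(d1[[1]]), signalMatrix(d3)))
})

test_that("invalid configurations are rejected", {
  expect_error(synthConfig(nSubjects = 0), "positive")
  expect_error(synthConfig(duration = 0.1), "duration")
})

test_that("active gestures raise amplitude on their high-gain channels", {
  cfg <- synthConfig(nSubjects = 1, nTrials = 1, nGestures = 3,
    nRepetitions = 1, channels = "hd", seed = 11, shiftMagnitude = 0)
  profile <- subjectProfileFor(cfg, 1)
  steady <- 2001:4000
  for (g in 1:3) {
    rec <- generateRecording(cfg, 1, 1, g, 1)
    amp <- rowMeans(abs(signalMatrix(rec)[, steady]))
    hi <- profile$maps[g, ] >= 0.5
    lo <- profile$maps[g, ] <= 0.05
    expect_gt(mean(amp[hi]), mean(amp[lo]))
  }
})

test_that("steady-phase spectrum is concentrated in the 20-500 Hz band", {
  cfg <- synthConfig(nSubjects = 1, nTrials = 1, nGestures = 1,
    nRepetitions = 1, channels = "ld", seed = 3, noiseFloor = 0.01)
  rec <- generateRecording(cfg, 1, 1, 1, 1)
  amp <- rowMeans(abs(signalMatrix(rec)))
  x <- signalMatrix(rec)[which.max(amp), 2001:4000]
  spec <- Mod(fft(x))^2
  freq <- (seq_along(spec) - 1) / length(spec) * 1000
  half <- freq <= 500
  inBand <- half & freq >= 20
  expect_lt(sum(spec[half & !inBand]) / sum(spec[half]), 0.05)
})

test_that("subjects differ but share class structure", {
  p1 <- subjectProfile(hdLayout(), 9, seed = 1)
  p2 <- subjectProfile(hdLayout(), 9, seed = 2)
  self <- cross <- numeric(0)
  for (g in 1:9) {
    expect_lt(cor(p1$maps[g, ], p2$maps[g, ]), 1)
    self <- c(self, cor(p1$maps[g, ], p2$maps[g, ]))
    cross <- c(cross, sapply(setdiff(1:9, g), function(k)
      cor(p1$maps[g, ], p2$maps[k, ])))
  }
  # on average, the same gesture across subjects is more alike than
  # different gestures (individual pairs may overlap under map jitter)
  expect_gt(mean(self), mean(cross) + 0.2)
  # gestures are pairwise distinct within a subject
  cc <- cor(t(p1$maps))
  expect_lt(max(cc[upper.tri(cc)]), 1)
})

test_that("electrode shift translates maps with edge replication", {
  lay <- toyLayout(3, 3)
  profile <- list(maps = matrix(0, 1, 9), globalGain = 1, onset = 2,
    steady = 2, offset = 1, noiseFloor = 0, seed = 1L)
  class(profile) <- "SubjectProfile"
  at <- function(r, c) (r - 1) * 3 + c  # row-major channel index
  profile$maps[1, at(2, 2)] <- 1
  # identity
  expect_identical(applyElectrodeShift(profile, lay, c(0, 0)), profile)
  # single hotspot at (2,2) moves to (3,2) under shift (1,0)
  sh <- applyElectrodeShift(profile, lay, c(1, 0))
  expect_equal(which(sh$maps[1, ] == 1), at(3, 2))
  # interior-supported map is recovered on interior cells by the inverse
  set.seed(4)
  pr <- profile
  pr$maps[1, ] <- runif(9)
  back <- applyElectrodeShift(applyElectrodeShift(pr, lay, c(1, 0)), lay,
    c(-1, 0))
  interior <- at(2, 1:3)
  expect_equal(back$maps[1, interior], pr$maps[1, interior])
  expect_error(applyElectrodeShift(pr, lay, c(3, 0)), "exceeds")
})

test_that("shifted maps keep their gesture identity on average", {
  profile <- subjectProfile(hdLayout(), 9, seed = 6)
  sh <- applyElectrodeShift(profile, hdLayout(), c(1, 1))
  self <- vapply(1:9, function(g)
    cor(sh$maps[g, ], profile$maps[g, ]), 0)
  cross <- unlist(lapply(1:9, function(g)
    sapply(setdiff(1:9, g), function(k)
      cor(sh$maps[g, ], profile$maps[k, ]))))
  # a one-cell shift perturbs amplitudes but the class geometry survives
  expect_gt(mean(self), mean(cross) + 0.2)
  expect_gt(mean(self), 0.5)
})
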