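test_that("channel repair replaces flagged channels by neighbour means", {
  sig <- matrix(rep(1:9, each = 10), 9, 10, byrow = FALSE)
  rec <- toyRecording(sig)
  # nothing flagged -> identical
  expect_identical(repairChannels(rec)@signal, sig)
  # interior channel (2,2) = channel 5 blown up -> mean of its 4 neighbours
  bad <- sig; bad[5, ] <- 1e6
  rep1 <- repairChannels(toyRecording(bad), flagged = 5)
  expect_equal(rep1@signal[5, ], colMeans(bad[c(2, 4, 6, 8), ]))
  expect_identical(rep1@signal[-5, ], bad[-5, ])
  # corner channel 1 -> mean of its 2 neighbours (channels 2 and 4)
  bad2 <- sig; bad2[1, ] <- 1e6
  rep2 <- repairChannels(toyRecording(bad2), flagged = 1)
  expect_equal(rep2@signal[1, ], colMeans(bad2[c(2, 4), ]))
  # the default RMS rule finds the blown-up channel
  expect_equal(repairChannels(toyRecording(bad))@signal[5, ],
    colMeans(bad[c(2, 4, 6, 8), ]))
  # unrepairable: all neighbours flagged too
  expect_error(repairChannels(toyRecording(bad), flagged = c(2, 4, 5, 6, 8),
    cap = 1), "cannot be repaired")
  # cap
  expect_error(repairChannels(toyRecording(bad), flagged = 1:5, cap = 0.05),
    "cap")
})

test_that("active-segment extraction finds threshold crossings", {
  n <- 8000
  # rectangular burst on [1001, 6000]
  env <- rep(0, n); env[1001:6000] <- 1
  sig <- rbind(env, env)
  se <- segmentActive(toyRecording(sig, toyLayout(1, 2)))
  expect_lt(abs(se[1] - 1001), 210)
  expect_lt(abs(se[2] - 6000), 210)
  # all-zero signal errors
  expect_error(segmentActive(toyRecording(matrix(0, 2, n),
    toyLayout(1, 2))), "no activity")
  # triangular envelope peaking at 1 over [0, 4000]: 10% crossings near
  # samples 200 and 3800
  tri <- c(seq(0, 1, length.out = 2000), seq(1, 0, length.out = 2000))
  se2 <- segmentActive(toyRecording(rbind(tri, tri), toyLayout(1, 2)))
  expect_lt(abs(se2[1] - 200), 210)
  expect_lt(abs(se2[2] - 3800), 210)
})

test_that("resampling is linear interpolation with exact identity case", {
  x <- matrix(sin(seq(0, 10, length.out = 5000)), 1)
  expect_equal(resampleSegment(x, 5000), x)
  # linear ramp of length 2500 -> linear ramp of length 5000, same endpoints
  ramp <- matrix(seq(0, 1, length.out = 2500), 1)
  out <- resampleSegment(ramp, 5000)
  expect_equal(dim(out), c(1L, 5000L))
  expect_equal(out[1, ], seq(0, 1, length.out = 5000), tolerance = 1e-12)
  # constants are resampling-invariant
  expect_equal(resampleSegment(matrix(3, 1, 17), 5000),
    matrix(3, 1, 5000))
  expect_error(resampleSegment(matrix(1, 1, 1)), "at least 2")
})

test_that("FIR band-pass has the specified frequency response", {
  h <- firBandpassCoefs()
  expect_length(h, 51)
  # DC attenuation >= 20 dB
  expect_lt(abs(sum(h)), 0.1)
  t <- seq_len(2000)
  dc <- matrix(1, 1, 2000)
  y <- bandpassFilter(dc)
  expect_lt(max(abs(y[1, 200:2000])), 0.1)
  # 100 Hz in-band tone preserved within 3 dB
  tone <- matrix(sin(2 * pi * 100 * t / 1000), 1)
  yt <- bandpassFilter(tone)
  amp <- max(abs(yt[1, 500:1500]))
  expect_gt(amp, 10^(-3 / 20))
  expect_lt(amp, 10^(3 / 20))
  # linearity
  set.seed(1)
  a <- matrix(rnorm(500), 1); b <- matrix(rnorm(500), 1)
  expect_equal(bandpassFilter(2 * a + 3 * b),
    2 * bandpassFilter(a) + 3 * bandpassFilter(b), tolerance = 1e-10)
})

test_that("Min-Max normalisation maps each channel onto [0, 1]", {
  x <- matrix(c(2, 4, 6), 1)
  expect_equal(minmaxNormalize(x), matrix(c(0, 0.5, 1), 1))
  set.seed(2)
  m <- matrix(rnorm(40), 4)
  n1 <- minmaxNormalize(m)
  expect_true(all(n1 >= 0 & n1 <= 1))
  expect_equal(apply(n1, 1, min), rep(0, 4))
  expect_equal(apply(n1, 1, max), rep(1, 4))
  # idempotence and scale invariance
  expect_equal(minmaxNormalize(n1), n1)
  expect_equal(minmaxNormalize(5 * m), n1)
  expect_warning(minmaxNormalize(matrix(1, 1, 5)), "constant")
  # joint mode normalises over the whole segment
  nj <- minmaxNormalize(m, perChannel = FALSE)
  expect_equal(min(nj), 0); expect_equal(max(nj), 1)
})

test_that("window extraction matches the count formula and brute force", {
  seg <- matrix(seq_len(5000), 1, 5000, byrow = TRUE)
  w <- extractWindows(seg)
  expect_equal(dim(w), c(1L, 100L, 39L))
  # offsets are 0, 50, 100, ... within the region
  expect_equal(w[1, 1, 1], 2001)
  expect_equal(w[1, 1, 2], 2051)
  expect_equal(w[1, 100, 39], 2000 + 1900 + 100)
  # boundary: region length == window length -> 1 window
  expect_equal(dim(extractWindows(seg, region = c(0, 100)))[3], 1L)
  # 250-sample region -> 4 windows
  expect_equal(dim(extractWindows(seg, region = c(0, 250)))[3], 4L)
  expect_error(extractWindows(seg, region = c(0, 50)), "shorter")
  # property: count formula equals brute-force offset enumeration
  set.seed(3)
  for (i in 1:50) {
    len <- sample(100:10000, 1)
    win <- sample(10:100, 1)
    step <- sample(5:80, 1)
    if (len < win) next
    brute <- length(seq(0, len - win, by = step))
    expect_equal(windowCount(len, win, step), brute)
  }
})

test_that("time-domain features match hand computation", {
  mk <- function(x) new("SampleSet",
    data = array(x, c(1, length(x), 1)),
    labels = data.frame(subject = 1, trial = 1, gesture = 1,
      repetition = 1, window = 1), kind = "real")
  # constant window -> all four features zero
  f0 <- sampleData(computeTdFeatures(mk(rep(0.4, 8))))
  expect_equal(as.numeric(f0), c(0, 0, 0, 0))
  # WL of [0, 1, 0, 1] is 3
  expect_equal(sampleData(computeTdFeatures(mk(c(0, 1, 0, 1))))[1, 3, 1], 3)
  # [0.2, 0.8, 0.2, 0.8]: centred [-0.3, 0.3, -0.3, 0.3]
  f <- sampleData(computeTdFeatures(mk(c(0.2, 0.8, 0.2, 0.8))))
  expect_equal(f[1, 1, 1], 0.3)   # MAV on centred window
  expect_equal(f[1, 4, 1], 3)     # ZC of centred window
  expect_equal(f[1, 2, 1], var(c(0.2, 0.8, 0.2, 0.8)))
})

test_that("the pipeline yields [0,1] windows with full label bookkeeping", {
  real <- tinyLdReal()
  expect_equal(dim(sampleData(real)), c(8L, 100L, 9L * 2L * 39L))
  expect_true(all(sampleData(real) >= 0 & sampleData(real) <= 1))
  lab <- sampleLabels(real)
  expect_equal(nrow(lab), 702)
  expect_equal(as.integer(table(lab$gesture)), rep(78L, 9))
  expect_equal(max(lab$window), 39)
  # streaming and list-based paths agree
  ds <- generateDataset(tinyLdConfig())
  viaList <- preprocessDataset(ds[1:2])
  expect_equal(sampleData(viaList), sampleData(real)[, , 1:78])
})
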