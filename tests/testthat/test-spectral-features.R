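# Morlet power, band-passed voltage, feature assembly.

sineEpochs <- function(freq, amp = 1, nEp = 3, fs = 500, nSamp = 2 * fs) {
  tt <- (seq_len(nSamp) - 1) / fs - 1
  makeEpochSet(array(rep(amp * sin(2 * pi * freq * tt), each = nEp),
                     c(nEp, 1, nSamp)), sfreq = fs,
               condition = rep(c("stimulus", "iti"), length.out = nEp))
}

smallTfr <- function(fs = 500) {
  tfrConfig(freqsHz = exp(seq(log(4), log(100), length.out = 12)),
            decim = 10L)
}

test_that("a pure sinusoid peaks at its own frequency bin at every time point", {
  cfg <- smallTfr()
  ep <- sineEpochs(10)
  pw <- morletPower(ep, cfg, "E01")
  expect_true(all(pw$power >= 0))
  nearest <- which.min(abs(pw$freqsHz - 10))
  peak <- apply(pw$power[1, , ], 2, which.max)
  expect_true(all(peak == nearest))
})

test_that("the FFT implementation matches direct time-domain convolution", {
  fs <- 500
  cfg <- smallTfr()
  set.seed(12)
  nSamp <- 2 * fs
  ep <- makeEpochSet(array(rnorm(nSamp), c(1, 1, nSamp)), sfreq = fs,
                     condition = "stimulus")
  pw <- morletPower(ep, cfg, "E01")
  x <- ep@data[1, 1, ]
  tRel <- -1 + (seq_len(nSamp) - 1) / fs
  timeIdx <- match(round(pw$timesS, 10), round(tRel, 10))
  for (fi in c(1, 5, 12)) {
    direct <- morletPowerDirect(x, fs, cfg@freqsHz[fi], cfg@nCycles[fi], timeIdx)
    expect_equal(pw$power[1, fi, ], direct, tolerance = 1e-8)
  }
})

test_that("power scales quadratically and is zero for zero input", {
  cfg <- smallTfr()
  p1 <- morletPower(sineEpochs(10, amp = 1), cfg, "E01")
  p2 <- morletPower(sineEpochs(10, amp = 2), cfg, "E01")
  expect_equal(p2$power, 4 * p1$power, tolerance = 1e-8)
  z <- morletPower(makeEpochSet(array(0, c(2, 1, 1000)), sfreq = 500,
                                condition = c("stimulus", "iti")), cfg, "E01")
  expect_equal(max(abs(z$power)), 0)
})

test_that("frequencies above Nyquist and unknown channels are refused", {
  ep <- sineEpochs(10, fs = 200, nSamp = 800)
  bad <- tfrConfig(freqsHz = c(10, 150), nCycles = c(3, 3))
  expect_error(morletPower(ep, bad, "E01"), "Nyquist")
  expect_error(morletPower(ep, smallTfr(), "nope"), "unknown channel")
})

test_that("edge cropping keeps features clear of wavelet boundary support", {
  cfg <- smallTfr()
  ep <- sineEpochs(10)
  pw <- morletPower(ep, cfg, "E01")
  crop <- 2.5 * max(cfg@nCycles / (2 * pi * cfg@freqsHz))
  expect_true(all(pw$timesS >= -1 + crop - 1e-9))
  expect_true(all(pw$timesS <= 1 - crop + 1e-9))
})

test_that("the voltage band-pass has the required stop/pass-band behavior", {
  cfg <- smallTfr()
  rms <- function(v) sqrt(mean(v^2))
  # 60 Hz is attenuated below 5% of input RMS
  out60 <- bandpassVoltage(sineEpochs(60), cfg, "E01")
  idx60 <- sineEpochs(60)@data[1, 1, ]
  expect_lt(rms(out60$voltage[1, ]) / rms(idx60), 0.05)
  # 10 Hz passes above 90%
  out10 <- bandpassVoltage(sineEpochs(10), cfg, "E01")
  expect_gt(rms(out10$voltage[1, ]) / rms(sineEpochs(10)@data[1, 1, ]), 0.90)
  # near-idempotence on white noise: a second pass only re-attenuates the
  # Butterworth transition band, leaving the pass band essentially unchanged
  set.seed(5)
  fs <- 500
  ep <- makeEpochSet(array(rnorm(2 * fs * 2), c(2, 1, 2 * fs)), sfreq = fs,
                     condition = c("stimulus", "iti"))
  once <- bandpassVoltage(ep, cfg, "E01")$voltage
  ep2 <- ep
  for (e in 1:2) {
    bf <- signal::butter(4, cfg@bandpassHz / (fs / 2), type = "pass")
    ep2@data[e, 1, ] <- signal::filtfilt(bf, ep@data[e, 1, ])
  }
  twice <- bandpassVoltage(ep2, cfg, "E01")$voltage
  expect_lt(rms(twice - once) / rms(once), 0.2)
  expect_gt(cor(as.vector(twice), as.vector(once)), 0.98)
})

test_that("feature assembly is dimensionally exact and invertible", {
  cfg <- smallTfr()
  ep <- noiseEpochs(nPerClass = 3, nCh = 1, nSamp = 1000, sfreq = 500, seed = 2)
  fe <- contactFeatures(ep, cfg, "E01")
  nf <- length(featureFreqs(fe))
  nt <- length(featureTimes(fe))
  expect_equal(ncol(featureMatrix(fe)), (nf + 1) * nt)
  # grid row 1..nf are log power, final row the band-passed voltage
  pw <- morletPower(ep, cfg, "E01")
  vb <- bandpassVoltage(ep, cfg, "E01")
  g1 <- unflattenGrid(featureMatrix(fe)[1, ], nf + 1)
  expect_equal(g1[seq_len(nf), ], log10(pw$power[1, , ]), tolerance = 1e-12)
  expect_equal(g1[nf + 1, ], vb$voltage[1, ], tolerance = 1e-12)
  # flatten/unflatten are exact inverses
  expect_identical(flattenGrid(g1), featureMatrix(fe)[1, ])
  # axis mismatch is refused
  vb2 <- vb
  vb2$timesS <- vb$timesS + 0.01
  expect_error(buildFeatureMatrix(pw, vb2, cfg, ep), "time axes differ")
})

test_that("log power turns amplitude scaling into an additive shift", {
  cfg <- smallTfr()
  ep <- noiseEpochs(nPerClass = 2, nCh = 1, nSamp = 1000, sfreq = 500, seed = 8)
  ep2 <- ep
  ep2@data <- ep@data * 5
  f1 <- contactFeatures(ep, cfg, "E01")
  f2 <- contactFeatures(ep2, cfg, "E01")
  nf <- length(featureFreqs(f1))
  nt <- length(featureTimes(f1))
  powRows <- as.vector(outer(seq_len(nf), (seq_len(nt) - 1) * (nf + 1), "+"))
  expect_equal(featureMatrix(f2)[, powRows] - featureMatrix(f1)[, powRows],
               matrix(2 * log10(5), 4, length(powRows)), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("standardization statistics come from the training epochs only", {
  set.seed(9)
  X <- matrix(rnorm(40 * 30, mean = 3, sd = 2), 40, 30)
  std <- standardizeFeatures(X, trainIdx = 1:25)
  expect_equal(colMeans(std$X[1:25, ]), rep(0, 30), tolerance = 1e-12)
  expect_equal(apply(std$X[1:25, ], 2, sd), rep(1, 30), tolerance = 1e-12)
  # held-out epochs use the same statistics
  expect_equal(std$X[26, ], (X[26, ] - std$center) / std$scale)
})
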