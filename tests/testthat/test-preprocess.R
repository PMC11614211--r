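# Re-referencing, epoching and rejection.

test_that("average reference removes the instantaneous channel mean", {
  # identical channels collapse to zero
  same <- new("SEEGRecording", data = matrix(rep(sin(1:300), 3), 3, 300,
                                             byrow = TRUE),
              sfreqHz = 100, channelNames = c("a", "b", "c"))
  expect_equal(max(abs(recordingData(averageReference(same)))), 0)
  # an already zero-mean pair is unchanged
  x <- rnorm(200)
  pair <- new("SEEGRecording", data = rbind(x, -x), sfreqHz = 100,
              channelNames = c("p", "n"))
  expect_equal(recordingData(averageReference(pair)), recordingData(pair),
               ignore_attr = TRUE)
  # defining property + idempotence on random data
  set.seed(4)
  rec <- new("SEEGRecording", data = matrix(rnorm(5 * 1000), 5, 1000),
             sfreqHz = 500, channelNames = letters[1:5])
  ref <- averageReference(rec)
  expect_lt(max(abs(colMeans(recordingData(ref)))), 1e-10)
  expect_equal(recordingData(averageReference(ref)), recordingData(ref),
               tolerance = 1e-12)
  one <- new("SEEGRecording", data = matrix(rnorm(100), 1, 100), sfreqHz = 100,
             channelNames = "solo")
  expect_error(averageReference(one), "single channel")
})

# hand-built schedule with constant jitters
flatSchedule <- function(nTrials, iti, fixation = 0.5) {
  onset <- numeric(nTrials)
  t <- 5
  for (i in seq_len(nTrials)) {
    t <- t + fixation
    onset[i] <- t
    t <- t + 1 + iti
  }
  data.frame(onset_s = onset, modality = rep(MODALITIES <- c("arabic", "dots", "spoken", "beeps"),
                                             length.out = nTrials),
             quantity = rep(5L, nTrials), is_catch = FALSE,
             fixation_dur_s = fixation, iti_dur_s = iti)
}

test_that("stimulus epochs cover [-1, +1] s around onset and recover raw samples", {
  fs <- 100
  n <- 6000
  rec <- new("SEEGRecording", data = rbind(seq_len(n), -seq_len(n)), sfreqHz = fs,
             channelNames = c("u", "d"))
  sched <- flatSchedule(4, iti = 3.5)
  ep <- extractEpochs(rec, sched, seed = 1)
  stim <- which(epochCondition(ep) == "stimulus")
  # trial at onset 10.0 s spans absolute time [9, 11) s, i.e. samples 901..1100
  o1 <- sched$onset_s[1]
  e1 <- stim[which.min(abs(ep@alignS[stim] - o1))]
  expect_equal(ep@alignS[e1], o1)
  i0 <- round(o1 * fs) - fs + 1
  expect_equal(epochData(ep)[e1, 1, ], seq(i0, i0 + 2 * fs - 1))
  expect_equal(epochData(ep)[e1, 2, ], -seq(i0, i0 + 2 * fs - 1))
})

test_that("ITI feasibility follows the baseline guard", {
  fs <- 100
  mk <- function(iti, nTrials = 6) {
    sched <- flatSchedule(nTrials, iti = iti)
    n <- ceiling((max(sched$onset_s) + 1 + iti + 5) * fs)
    rec <- new("SEEGRecording", data = matrix(rnorm(2 * n), 2, n), sfreqHz = fs,
               channelNames = c("x", "y"))
    list(rec = rec, sched = sched)
  }
  # 3.5 s gaps host one baseline per trial: classes fully matched
  a <- mk(3.5)
  ep <- extractEpochs(a$rec, a$sched, seed = 1)
  expect_equal(sum(epochCondition(ep) == "stimulus"), 6)
  expect_equal(sum(epochCondition(ep) == "iti"), 6)
  # baseline alignment points respect the guard and the window fits the gap
  iti <- which(epochCondition(ep) == "iti")
  stim <- a$sched$onset_s
  for (i in iti) {
    prev <- max(stim[stim + 1 <= ep@alignS[i]])
    expect_gte(ep@alignS[i], prev + 1 + 1.99)
  }
  # 1.5 s gaps can never satisfy the guard
  b <- mk(1.5)
  expect_error(extractEpochs(b$rec, b$sched, seed = 1), "guard")
})

test_that("epoch classes stay balanced under mixed gap lengths", {
  cfg <- synthConfig(nContacts = 2, presentationsPerModality = 20)
  sched <- buildSchedule(cfg, seed = 31)
  sim <- simulateRecording(sched, cfg, seed = 31)
  ep <- extractEpochs(sim$recording, sched, seed = 2)
  expect_equal(sum(epochCondition(ep) == "stimulus"),
               sum(epochCondition(ep) == "iti"))
  # only gaps of at least guard + 1 s yield baselines
  feasible <- sum(sched$iti_dur_s >= 2.99)
  expect_lte(sum(epochCondition(ep) == "iti"), feasible + 1)
})

# brute-force re-implementation of the cross-validated threshold objective
thresholdOracle <- function(epochs, nCandidates, folds, seed) {
  d <- dim(epochs@data)
  p2p <- vapply(seq_len(d[1]), function(e)
    max(vapply(seq_len(d[2]), function(c) diff(range(epochs@data[e, c, ])), 0)), 0)
  grid <- seq(min(p2p), max(p2p), length.out = nCandidates)
  foldId <- oracleWithSeed(childSeed(seed, "reject-folds"),
                           sample(rep_len(seq_len(folds), d[1])))
  score <- numeric(nCandidates)
  for (f in seq_len(folds)) {
    med <- apply(epochs@data[foldId == f, , , drop = FALSE], c(2, 3), median)
    for (g in seq_along(grid)) {
      surv <- foldId != f & p2p <= grid[g]
      if (!any(surv)) { score[g] <- score[g] + Inf; next }
      mn <- apply(epochs@data[surv, , , drop = FALSE], c(2, 3), mean)
      score[g] <- score[g] + sqrt(mean((mn - med)^2))
    }
  }
  grid[which.min(score)]
}

test_that("rejection threshold matches the brute-force CV objective and excludes outliers", {
  ep <- noiseEpochs(nPerClass = 12, nCh = 2, nSamp = 200, seed = 7)
  ep@data[5, 1, ] <- ep@data[5, 1, ] * 20          # one gross outlier epoch
  thr <- estimateRejectionThreshold(ep, nCandidates = 25, folds = 5, seed = 9)
  expect_equal(thr, thresholdOracle(ep, 25, 5, 9), tolerance = 1e-12)
  p2p <- vapply(seq_len(24), function(e)
    max(vapply(1:2, function(c) diff(range(ep@data[e, c, ])), 0)), 0)
  expect_lt(thr, p2p[5])
  # scale equivariance
  ep2 <- ep
  ep2@data <- ep@data * 3.7
  thr2 <- estimateRejectionThreshold(ep2, nCandidates = 25, folds = 5, seed = 9)
  expect_equal(thr2, 3.7 * thr, tolerance = 1e-8)
  # identical epochs: anything at or above the common peak-to-peak is optimal
  same <- makeEpochSet(array(rep(sin(1:100), each = 12), c(12, 1, 100)))
  thr3 <- estimateRejectionThreshold(same, seed = 1)
  expect_gte(thr3, diff(range(sin(1:100))) - 1e-12)
  expect_error(estimateRejectionThreshold(noiseEpochs(nPerClass = 4), seed = 1),
               "at least 10")
})

test_that("epoch rejection masks exceedances and re-balances classes", {
  ep <- noiseEpochs(nPerClass = 40, nCh = 2, nSamp = 100, seed = 3)
  expect_true(all(keptMask(dropBadEpochs(ep, Inf, seed = 1))))
  # a single spiked epoch is exactly the one removed (classes re-balanced)
  p2pAll <- vapply(seq_len(80), function(e)
    max(vapply(1:2, function(c) diff(range(ep@data[e, c, ])), 0)), 0)
  thr <- 2 * max(p2pAll)                     # generous threshold
  spiked <- ep
  spiked@data[7, 2, 50] <- spiked@data[7, 2, 50] + 2 * thr
  out <- dropBadEpochs(spiked, thr, seed = 1)
  expect_false(keptMask(out)[7])
  # epoch 7 is a stimulus epoch, so one iti epoch is dropped to re-balance
  kept <- keptMask(out)
  expect_equal(sum(kept & epochCondition(out) == "stimulus"),
               sum(kept & epochCondition(out) == "iti"))
  expect_equal(sum(!kept), 2)
  # 3 stimulus epochs above threshold leave 37 per class
  three <- ep
  for (e in c(1, 3, 9)) three@data[e, 1, 10] <- three@data[e, 1, 10] + 2 * thr
  out3 <- dropBadEpochs(three, thr, seed = 1)
  kept3 <- keptMask(out3)
  expect_equal(sum(kept3 & epochCondition(out3) == "stimulus"), 37)
  expect_equal(sum(kept3 & epochCondition(out3) == "iti"), 37)
  expect_error(dropBadEpochs(ep, 1e-9, seed = 1), "all epochs")
})
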