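# Task-schedule and recording synthesis.

test_that("schedules honor trial counts, jitter bounds and catch rate", {
  for (ppm in c(5, 40)) {
    for (rate in c(0, 0.1, 0.2)) {
      cfg <- synthConfig(nContacts = 1, presentationsPerModality = ppm,
                         catchRate = rate)
      s <- buildSchedule(cfg, seed = 3)
      stim <- s[!s$is_catch, ]
      expect_equal(unname(table(stim$modality)[c("arabic", "dots", "spoken", "beeps")]),
                   rep(ppm, 4), ignore_attr = TRUE)
      expect_true(all(s$fixation_dur_s >= 0.5 & s$fixation_dur_s <= 1.5))
      expect_true(all(s$iti_dur_s >= 1.5 & s$iti_dur_s <= 3.5))
      expect_true(all(s$quantity %in% 1:9))
      expect_true(all(diff(s$onset_s) > 0))
      # consecutive trials non-overlapping: next onset after offset + iti
      n <- nrow(s)
      expect_true(all(s$onset_s[-1] >= s$onset_s[-n] + 1 + s$iti_dur_s[-n] - 1e-9))
      # catch fraction within one trial of the configured rate
      expect_lte(abs(sum(s$is_catch) - rate * nrow(s)), 1)
    }
  }
})

test_that("schedules are pure functions of (config, seed)", {
  cfg <- synthConfig(nContacts = 2, presentationsPerModality = 10)
  expect_identical(buildSchedule(cfg, seed = 11), buildSchedule(cfg, seed = 11))
  expect_false(identical(buildSchedule(cfg, seed = 11), buildSchedule(cfg, seed = 12)))
})

test_that("invalid synthesis configurations are rejected", {
  expect_error(synthConfig(nContacts = 0), "nContacts")
  expect_error(synthConfig(nContacts = 1, presentationsPerModality = 0),
               "presentationsPerModality")
  expect_error(synthConfig(nContacts = 1, catchRate = 1.2), "catchRate")
  expect_error(synthConfig(nContacts = 2,
                           regionLabels = c(A = "x", A = "y")), "unique")
  # an effect band at or above Nyquist is rejected at configuration time
  expect_error(synthConfig(nContacts = 1, sfreqHz = 120,
                           regionLabels = c(CH01 = "r"),
                           effects = list(effectSpec("CH01", bandHz = c(70, 110),
                                                     windowS = c(0, 0.5),
                                                     magnitude = 2))),
               "Nyquist")
})

test_that("effect-free background follows the configured 1/f spectrum", {
  for (expo in c(1, 2)) {
    cfg <- synthConfig(nContacts = 1, presentationsPerModality = 8,
                       noise = noiseModel(oneOverFExponent = expo))
    s <- buildSchedule(cfg, seed = 4)
    sim <- simulateRecording(s, cfg, seed = 4)
    slope <- welchSlope(recordingData(sim$recording)[1, ], 1000)
    expect_lt(abs(slope + expo), 0.25)
  }
})

test_that("planted band increases raise the in-window envelope (Hilbert oracle)", {
  cfg <- synthConfig(nContacts = 2, presentationsPerModality = 10,
                     regionLabels = c(CH01 = "a", CH02 = "b"),
                     effects = list(effectSpec("CH01", bandHz = c(70, 150),
                                               windowS = c(0, 0.5), magnitude = 3)))
  s <- buildSchedule(cfg, seed = 6)
  sim <- simulateRecording(s, cfg, seed = 6)
  fs <- 1000
  env <- bandEnvelope(recordingData(sim$recording)[1, ], c(70, 150), fs)
  onsets <- s$onset_s[!s$is_catch]
  post <- vapply(onsets, function(o) mean(env[round((o + 0.05) * fs):round((o + 0.45) * fs)]), 0)
  pre <- vapply(onsets, function(o) mean(env[round((o - 0.6) * fs):round((o - 0.2) * fs)]), 0)
  expect_gt(mean(post - pre), 0)
  expect_lt(t.test(post, pre, paired = TRUE, alternative = "greater")$p.value, 1e-6)
  # untouched channel shows no such shift
  env2 <- bandEnvelope(recordingData(sim$recording)[2, ], c(70, 150), fs)
  post2 <- vapply(onsets, function(o) mean(env2[round((o + 0.05) * fs):round((o + 0.45) * fs)]), 0)
  pre2 <- vapply(onsets, function(o) mean(env2[round((o - 0.6) * fs):round((o - 0.2) * fs)]), 0)
  expect_gt(t.test(post2, pre2, paired = TRUE, alternative = "greater")$p.value, 0.01)
  # manifest records the planted effect and its trials
  expect_length(sim$manifest, 1)
  expect_identical(sim$manifest[[1]]$contact, "CH01")
  expect_equal(sim$manifest[[1]]$trial_onsets_s, onsets)
})

test_that("effect detectability grows monotonically with magnitude", {
  es <- vapply(c(1.5, 3, 6), function(mag) {
    cfg <- synthConfig(nContacts = 1, presentationsPerModality = 10,
                       regionLabels = c(CH01 = "a"),
                       effects = list(effectSpec("CH01", bandHz = c(70, 150),
                                                 windowS = c(0, 0.5),
                                                 magnitude = mag)))
    s <- buildSchedule(cfg, seed = 9)
    sim <- simulateRecording(s, cfg, seed = 9)
    fs <- 1000
    env <- bandEnvelope(recordingData(sim$recording)[1, ], c(70, 150), fs)
    onsets <- s$onset_s[!s$is_catch]
    post <- vapply(onsets, function(o) mean(env[round((o + 0.05) * fs):round((o + 0.45) * fs)]), 0)
    pre <- vapply(onsets, function(o) mean(env[round((o - 0.6) * fs):round((o - 0.2) * fs)]), 0)
    mean(post - pre) / sd(post - pre)
  }, 0)
  expect_true(all(diff(es) > 0))
})

test_that("zero-noise ERP simulation is the exact repeated template", {
  cfg <- synthConfig(nContacts = 1, presentationsPerModality = 3,
                     regionLabels = c(CH01 = "a"),
                     noise = noiseModel(amplitudeUv = 0),
                     effects = list(effectSpec("CH01", bandHz = c(4, 8),
                                               windowS = c(0, 0.5), magnitude = 2,
                                               erpAmplitude = 40)))
  s <- buildSchedule(cfg, seed = 2)
  sim <- simulateRecording(s, cfg, seed = 2)
  x <- recordingData(sim$recording)[1, ]
  fs <- 1000
  tt <- seq(0, 0.6, by = 1 / fs)
  tmpl <- 40 * (exp(-(tt - 0.12)^2 / (2 * 0.03^2)) -
                0.6 * exp(-(tt - 0.28)^2 / (2 * 0.06^2)))
  expected <- numeric(length(x))
  for (o in s$onset_s[!s$is_catch]) {
    i0 <- round(o * fs) + 1
    expected[i0:(i0 + length(tmpl) - 1)] <-
      expected[i0:(i0 + length(tmpl) - 1)] + tmpl
  }
  expect_equal(x, expected, tolerance = 1e-12)
})

test_that("recordings are deterministic in (config, seed)", {
  cfg <- smallCohortConfig(nContacts = 2, ppm = 3)
  s <- buildSchedule(cfg, seed = 8)
  a <- simulateRecording(s, cfg, seed = 8)
  b <- simulateRecording(s, cfg, seed = 8)
  expect_identical(recordingData(a$recording), recordingData(b$recording))
  c <- simulateRecording(s, cfg, seed = 9)
  expect_false(identical(recordingData(a$recording), recordingData(c$recording)))
})

test_that("electrode tables map contacts to regions and reject bad input", {
  cfg <- synthConfig(nContacts = 3,
                     regionLabels = c(A = "superiortemporal", B = "putamen",
                                      C = "superiorparietal"))
  tab <- makeElectrodeTable(cfg)
  expect_equal(tab$name, c("A", "B", "C"))
  expect_equal(tab$region, c("superiortemporal", "putamen", "superiorparietal"))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeElectrodesTSV(tab, path)
  expect_identical(readElectrodesTSV(path), tab)
  expect_error(writeElectrodesTSV(data.frame(name = c("A", "A"),
                                             region = c("x", "y")), path),
               "duplicate")
  expect_error(synthConfig(nContacts = 2, regionLabels = c(A = "x")),
               "one label per contact")
})
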