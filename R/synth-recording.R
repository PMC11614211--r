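# Continuous-recording synthesis: 1/f background plus planted band-limited
# amplitude changes and evoked potentials at scheduled stimulus onsets.

# 1/f^a noise by spectral shaping of white Gaussian noise
pinkNoise <- function(n, exponent, rmsUv, sfreq) {
  if (rmsUv == 0) return(numeric(n))
  white <- stats::rnorm(n)
  if (exponent == 0) return(white * rmsUv / stats::sd(white))
  k <- seq_len(n) - 1
  freq <- pmin(k, n - k) * sfreq / n
  scale <- ifelse(freq > 0, freq^(-exponent / 2), 0)
  x <- Re(stats::fft(stats::fft(white) * scale, inverse = TRUE)) / n
  x * rmsUv / stats::sd(x)
}

# smooth gain curve: 1 outside windows, ramping to `gain` inside each window
# with raised-cosine ramps of `rampS` seconds
gainCurve <- function(n, sfreq, windows, gain, rampS = 0.05) {
  g <- rep(1, n)
  for (w in windows) {
    i0 <- max(1L, round(w[1] * sfreq) + 1L)
    i1 <- min(n, round(w[2] * sfreq))
    if (i1 <= i0) next
    len <- i1 - i0 + 1L
    ramp <- min(round(rampS * sfreq), floor(len / 2))
    prof <- rep(1, len)
    if (ramp > 0) {
      u <- seq_len(ramp) / ramp
      prof[seq_len(ramp)] <- 0.5 - 0.5 * cos(pi * u)
      prof[len - ramp + seq_len(ramp)] <- rev(0.5 - 0.5 * cos(pi * u))
    }
    g[i0:i1] <- 1 + (gain - 1) * prof
  }
  g
}

# deterministic biphasic evoked-potential template (0-0.6 s after onset)
erpTemplate <- function(sfreq, amplitudeUv) {
  t <- seq(0, 0.6, by = 1 / sfreq)
  amplitudeUv * (exp(-(t - 0.12)^2 / (2 * 0.03^2)) -
                 0.6 * exp(-(t - 0.28)^2 / (2 * 0.06^2)))
}

# exact (brick-wall) spectral band split, zero phase; keeps the planted
# in-band amplitude change at its nominal magnitude
bandFilter <- function(x, bandHz, sfreq) {
  n <- length(x)
  k <- seq_len(n) - 1
  freq <- pmin(k, n - k) * sfreq / n
  mask <- freq >= bandHz[1] & freq <= bandHz[2]
  Re(stats::fft(stats::fft(x) * mask, inverse = TRUE)) / n
}

#' Simulate a continuous multichannel recording with planted effects
#'
#' Each channel carries independent 1/f background noise. For every
#' [EffectSpec-class] in the configuration, the band component of the target
#' channel (4th-order zero-phase Butterworth band-pass) is multiplied by a
#' smooth cosine-ramped gain inside the effect window of each matching
#' non-catch stimulus trial: gain `magnitude` for increases, `1/magnitude`
#' for decreases. A nonzero `erpAmplitude` additionally adds a fixed
#' biphasic evoked-potential template at each matching stimulus onset.
#'
#' @param schedule schedule `data.frame` from [buildSchedule()].
#' @param config a [SynthConfig-class].
#' @param seed integer seed; `(config, seed)` fully determine the output.
#' @return a list with elements `recording` (a [SEEGRecording-class] spanning
#'   all trials plus 5 s padding on both ends) and `manifest` (one record per
#'   planted effect, including the affected trial onsets).
#' @export
#' @examples
#' cfg <- synthConfig(nContacts = 2, presentationsPerModality = 3)
#' sim <- simulateRecording(buildSchedule(cfg, 1), cfg, seed = 1)
#' sim$recording
simulateRecording <- function(schedule, config, seed = config@seed) {
  stopifnot(is(config, "SynthConfig"))
  validObject(config)
  checkSchedule(schedule)
  chans <- contactNames(config)
  fs <- config@sfreqHz
  for (ef in config@effects) {
    if (!ef@contact %in% chans)
      stopf("effect references unknown contact '%s'", ef@contact)
    if (ef@bandHz[2] >= fs / 2)
      stopf("effect band %.1f-%.1f Hz reaches Nyquist (%g Hz)",
            ef@bandHz[1], ef@bandHz[2], fs / 2)
  }
  durS <- scheduleDuration(schedule)
  n <- as.integer(durS * fs)
  nm <- config@noise
  data <- matrix(0, nrow = length(chans), ncol = n,
                 dimnames = list(chans, NULL))
  withSeed(seed, {
    for (ci in seq_along(chans)) {
      x <- pinkNoise(n, nm@oneOverFExponent, nm@amplitudeUv, fs)
      if (length(nm@lineFreqHz) == 1 && nm@amplitudeUv > 0) {
        tt <- (seq_len(n) - 1) / fs
        x <- x + 0.2 * nm@amplitudeUv * sin(2 * pi * nm@lineFreqHz * tt)
      }
      data[ci, ] <- x
    }
    NULL
  })
  manifest <- vector("list", length(config@effects))
  for (ei in seq_along(config@effects)) {
    ef <- config@effects[[ei]]
    ci <- match(ef@contact, chans)
    sel <- !schedule$is_catch & schedule$modality %in% ef@modalities
    onsets <- schedule$onset_s[sel]
    gain <- if (ef@direction == "increase") ef@magnitude else 1 / ef@magnitude
    if (gain != 1 && any(data[ci, ] != 0)) {
      xb <- bandFilter(data[ci, ], ef@bandHz, fs)
      wins <- lapply(onsets, function(o) o + ef@windowS)
      g <- gainCurve(n, fs, wins, gain)
      data[ci, ] <- (data[ci, ] - xb) + g * xb
    }
    if (ef@erpAmplitude != 0) {
      tmpl <- erpTemplate(fs, ef@erpAmplitude)
      for (o in onsets) {
        i0 <- round(o * fs) + 1L
        idx <- i0:min(n, i0 + length(tmpl) - 1L)
        data[ci, idx] <- data[ci, idx] + tmpl[seq_along(idx)]
      }
    }
    manifest[[ei]] <- list(
      contact = ef@contact, modalities = ef@modalities,
      band_hz = ef@bandHz, window_s = ef@windowS,
      direction = ef@direction, magnitude = ef@magnitude,
      erp_amplitude_uv = ef@erpAmplitude, trial_onsets_s = onsets)
  }
  rec <- new("SEEGRecording", data = data, sfreqHz = fs, channelNames = chans)
  list(recording = rec, manifest = manifest)
}

#' Build the contact-to-region electrode table
#'
#' @param config a [SynthConfig-class] whose `regionLabels` cover all contacts.
#' @return a `data.frame` with columns `name` and `region`, one row per
#'   contact; round-trips losslessly through [writeElectrodesTSV()] /
#'   [readElectrodesTSV()].
#' @export
makeElectrodeTable <- function(config) {
  stopifnot(is(config, "SynthConfig"))
  validObject(config)
  data.frame(name = names(config@regionLabels),
             region = unname(config@regionLabels),
             stringsAsFactors = FALSE)
}
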