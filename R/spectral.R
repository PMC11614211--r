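# Morlet time-frequency power features with an appended band-passed voltage
# row, flattened into the per-epoch classifier feature vector.

#' Configure the time-frequency feature grid
#'
#' Defaults: 50 log-spaced wavelet frequencies from 3 to 250 Hz with
#' `freq/2` cycles (minimum 3), temporal decimation by 25 (a 40 samples/s
#' feature grid at a 1000 Hz recording rate), and a 0.1-40 Hz band for the
#' appended voltage row. The lower frequency bound is set by the epoch
#' length: a wavelet needs its full support inside the 2 s epoch after
#' symmetric edge cropping.
#'
#' @param freqsHz strictly increasing frequencies within [1, 250] Hz.
#' @param nCycles per-frequency cycle counts (> 0).
#' @param decim temporal decimation factor.
#' @param bandpassHz band (Hz) for the appended voltage row.
#' @param logPower apply log10 to wavelet power (default TRUE).
#' @return a [TFRConfig-class].
#' @export
tfrConfig <- function(freqsHz = exp(seq(log(3), log(250), length.out = 50)),
                      nCycles = pmax(freqsHz / 2, 3), decim = 25L,
                      bandpassHz = c(0.1, 40), logPower = TRUE) {
  new("TFRConfig", freqsHz = as.numeric(freqsHz), nCycles = as.numeric(nCycles),
      decim = as.integer(decim), bandpassHz = as.numeric(bandpassHz),
      logPower = isTRUE(logPower))
}

# Gaussian SD (s) of each wavelet and the truncation half-width in samples.
# Wavelets are truncated at +/- 2.5 SD; the same extent defines the
# symmetric edge crop.
waveletSigma <- function(cfg) cfg@nCycles / (2 * pi * cfg@freqsHz)
waveletHalfWidth <- function(cfg, fs) as.integer(round(2.5 * waveletSigma(cfg) * fs))

# indices (into the epoch sample axis) of the cropped, decimated feature
# time grid, and the corresponding times
tfrTimeGrid <- function(cfg, epochs) {
  fs <- epochs@sfreqHz
  S <- dim(epochs@data)[3]
  tRel <- epochs@windowS[1] + (seq_len(S) - 1) / fs
  cropS <- max(2.5 * waveletSigma(cfg))
  keep <- which(tRel >= epochs@windowS[1] + cropS &
                tRel <= epochs@windowS[2] - cropS)
  if (!length(keep))
    stopf("edge cropping (%.2f s per side) leaves no usable time points; use higher minimum frequency or fewer cycles", cropS)
  sel <- keep[seq(1, length(keep), by = cfg@decim)]
  list(idx = sel, timesS = tRel[sel])
}

#' Morlet wavelet power for one channel
#'
#' Convolves each epoch with complex Morlet wavelets (Gaussian-windowed
#' sinusoids, unit-energy normalized, truncated at 2.5 SD) via FFT and
#' returns squared magnitude on the cropped, decimated feature time grid.
#' Edge samples within the half-support of the longest wavelet are cropped
#' symmetrically so that no feature is contaminated by epoch boundaries.
#'
#' @param epochs an [EpochSet-class].
#' @param cfg a [TFRConfig-class]; all frequencies must lie below Nyquist.
#' @param channel channel name.
#' @return a list: `power` (epochs x nFreqs x nTimes non-negative array),
#'   `freqsHz`, `timesS`.
#' @export
morletPower <- function(epochs, cfg, channel) {
  stopifnot(is(epochs, "EpochSet"), is(cfg, "TFRConfig"))
  validObject(cfg)
  ci <- match(channel, epochs@channelNames)
  if (is.na(ci)) stopf("unknown channel '%s'", channel)
  fs <- epochs@sfreqHz
  if (max(cfg@freqsHz) >= fs / 2)
    stopf("wavelet frequency %.1f Hz is at or above Nyquist (%g Hz)",
          max(cfg@freqsHz), fs / 2)
  S <- dim(epochs@data)[3]
  nEp <- dim(epochs@data)[1]
  hw <- waveletHalfWidth(cfg, fs)
  if (any(2L * hw + 1L > S))
    stopf("epoch length (%d samples) shorter than the longest wavelet support (%d samples)",
          S, max(2L * hw + 1L))
  grid <- tfrTimeGrid(cfg, epochs)
  E <- t(epochs@data[, ci, , drop = TRUE])
  if (nEp == 1L) E <- matrix(epochs@data[1, ci, ], ncol = 1)
  nfft <- stats::nextn(S + 2L * max(hw), c(2, 3))
  FE <- stats::mvfft(rbind(E, matrix(0, nfft - S, nEp)))
  power <- array(0, dim = c(nEp, length(cfg@freqsHz), length(grid$idx)))
  sigma <- waveletSigma(cfg)
  for (fi in seq_along(cfg@freqsHz)) {
    tw <- (-hw[fi]:hw[fi]) / fs
    w <- exp(2i * pi * cfg@freqsHz[fi] * tw) * exp(-tw^2 / (2 * sigma[fi]^2))
    w <- w / sqrt(sum(Mod(w)^2))
    wf <- stats::fft(c(w, rep(0, nfft - length(w))))
    conv <- stats::mvfft(FE * wf, inverse = TRUE) / nfft
    power[, fi, ] <- t(Mod(conv[grid$idx + hw[fi], , drop = FALSE])^2)
  }
  list(power = power, freqsHz = cfg@freqsHz, timesS = grid$timesS)
}

#' Band-passed voltage trace on the feature time grid
#'
#' Zero-phase 4th-order Butterworth band-pass (default 0.1-40 Hz) of one
#' channel's epochs, sampled at the same cropped, decimated time points as
#' the wavelet power grid so the trace can be appended as the final grid
#' row.
#'
#' @param epochs an [EpochSet-class].
#' @param cfg a [TFRConfig-class] (supplies the band and the time grid).
#' @param channel channel name.
#' @return a list: `voltage` (epochs x nTimes matrix), `timesS`.
#' @export
bandpassVoltage <- function(epochs, cfg, channel) {
  stopifnot(is(epochs, "EpochSet"), is(cfg, "TFRConfig"))
  ci <- match(channel, epochs@channelNames)
  if (is.na(ci)) stopf("unknown channel '%s'", channel)
  fs <- epochs@sfreqHz
  band <- cfg@bandpassHz
  if (band[1] <= 0 || band[2] >= fs / 2)
    stopf("band-pass (%g, %g) Hz must lie strictly inside (0, Nyquist)", band[1], band[2])
  grid <- tfrTimeGrid(cfg, epochs)
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  nEp <- dim(epochs@data)[1]
  voltage <- matrix(0, nEp, length(grid$idx))
  for (e in seq_len(nEp)) {
    y <- signal::filtfilt(bf, epochs@data[e, ci, ])
    voltage[e, ] <- y[grid$idx]
  }
  list(voltage = voltage, timesS = grid$timesS)
}

#' Assemble per-epoch feature grids and flatten them
#'
#' Stacks the wavelet power rows (log10-transformed when configured) with
#' the band-passed voltage trace as the final row of each epoch's
#' (nFreqs + 1) x nTimes grid, and flattens the grids column-major into the
#' classifier feature vectors. [unflattenGrid()] inverts the flattening
#' exactly.
#'
#' @param power output of [morletPower()].
#' @param voltage output of [bandpassVoltage()] on the same time axis.
#' @param cfg the [TFRConfig-class] used.
#' @param epochs the [EpochSet-class] the grids came from (supplies labels).
#' @param channel channel name recorded on the result.
#' @return an [EpochFeatureSet-class].
#' @export
buildFeatureMatrix <- function(power, voltage, cfg, epochs, channel = "") {
  stopifnot(is(cfg, "TFRConfig"), is(epochs, "EpochSet"))
  if (!isTRUE(all.equal(power$timesS, voltage$timesS)))
    stopf("power and voltage time axes differ")
  nEp <- dim(power$power)[1]
  if (nrow(voltage$voltage) != nEp) stopf("power and voltage epoch counts differ")
  if (nEp != nEpochs(epochs)) stopf("feature grids and EpochSet epoch counts differ")
  nf <- length(power$freqsHz)
  nt <- length(power$timesS)
  P <- power$power
  if (cfg@logPower) P <- log10(pmax(P, .Machine$double.xmin))
  A <- array(0, dim = c(nf + 1L, nt, nEp))
  A[seq_len(nf), , ] <- aperm(P, c(2, 3, 1))
  A[nf + 1L, , ] <- t(voltage$voltage)
  feats <- t(matrix(A, (nf + 1L) * nt, nEp))
  new("EpochFeatureSet", features = feats, freqsHz = power$freqsHz,
      timesS = power$timesS, channel = channel,
      condition = epochs@condition, modality = epochs@modality)
}

#' Compute one contact's full feature set
#'
#' Convenience wrapper: wavelet power plus band-passed voltage for one
#' channel of the kept epochs, assembled into an [EpochFeatureSet-class].
#'
#' @param epochs an [EpochSet-class] (only kept epochs are used).
#' @param cfg a [TFRConfig-class].
#' @param channel channel name.
#' @return an [EpochFeatureSet-class].
#' @export
contactFeatures <- function(epochs, cfg, channel) {
  ep <- keptEpochs(epochs)
  pw <- morletPower(ep, cfg, channel)
  vb <- bandpassVoltage(ep, cfg, channel)
  buildFeatureMatrix(pw, vb, cfg, ep, channel = channel)
}

#' Flatten / unflatten a feature grid
#'
#' The feature vector is the column-major flattening of the
#' (nFreqs + 1) x nTimes grid; these two helpers are exact inverses.
#'
#' @param grid a (nFreqs + 1) x nTimes matrix.
#' @param v a flattened feature vector.
#' @param nRows number of grid rows (nFreqs + 1).
#' @return `flattenGrid`: a numeric vector; `unflattenGrid`: a matrix.
#' @export
flattenGrid <- function(grid) as.vector(grid)

#' @rdname flattenGrid
#' @export
unflattenGrid <- function(v, nRows) matrix(v, nrow = nRows)

#' Standardize features on training statistics
#'
#' Per-feature mean and SD are computed on the training epochs only and
#' applied to all epochs; features constant on the training set get unit
#' scale.
#'
#' @param X epochs x features matrix.
#' @param trainIdx indices of training epochs.
#' @return a list: `X` (standardized matrix), `center`, `scale`.
#' @export
standardizeFeatures <- function(X, trainIdx) {
  Xtr <- X[trainIdx, , drop = FALSE]
  n <- nrow(Xtr)
  center <- colMeans(Xtr)
  scale <- sqrt(pmax(colSums(Xtr^2) - n * center^2, 0) / (n - 1))
  scale[!is.finite(scale) | scale == 0] <- 1
  list(X = sweep(sweep(X, 2, center), 2, scale, "/"), center = center, scale = scale)
}
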