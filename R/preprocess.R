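# Re-referencing, epoch extraction and amplitude-based trial rejection.

#' Common average reference
#'
#' Subtracts the instantaneous mean across channels from every channel, the
#' standard sEEG montage for increasing sensitivity to high-frequency
#' broadband activity.
#'
#' @param rec a [SEEGRecording-class] with at least 2 channels.
#' @return the re-referenced [SEEGRecording-class]; column means are zero to
#'   numerical tolerance. Idempotent.
#' @export
averageReference <- function(rec) {
  stopifnot(is(rec, "SEEGRecording"))
  if (nrow(rec@data) < 2)
    stopf("average reference undefined for a single channel")
  ref <- colMeans(rec@data)
  new("SEEGRecording", data = sweep(rec@data, 2, ref),
      sfreqHz = rec@sfreqHz, channelNames = rec@channelNames)
}

#' Extract balanced stimulus and inter-trial epochs
#'
#' Cuts one (-1, +1) s stimulus epoch per non-catch trial, aligned to
#' stimulus onset, and one matched inter-trial (ITI) baseline epoch per gap
#' where it fits: the baseline alignment point must lie at least
#' `itiGuardS` after the preceding stimulus offset (the default 1.99 s lets
#' evoked activity return to baseline) and the 2 s window must end before
#' the next fixation onset. The window is centred in the eligible interval;
#' gaps shorter than `itiGuardS + 1` s yield no baseline epoch. Classes are
#' then balanced by seeded uniform subsampling of the larger class.
#'
#' @param rec a (re-referenced) [SEEGRecording-class].
#' @param schedule schedule `data.frame` from [buildSchedule()] or
#'   [readEventsTSV()].
#' @param itiGuardS baseline guard in seconds (default 1.99).
#' @param seed integer seed for the balancing subsample.
#' @return an [EpochSet-class] with equal stimulus and ITI counts.
#' @export
extractEpochs <- function(rec, schedule, itiGuardS = 1.99, seed = 1L) {
  stopifnot(is(rec, "SEEGRecording"))
  checkSchedule(schedule)
  fs <- rec@sfreqHz
  nSamp <- ncol(rec@data)
  winSamp <- as.integer(round(fs))           # one second each side
  halfWin <- 1.0
  keep <- !schedule$is_catch
  stim <- schedule[keep, , drop = FALSE]
  n <- nrow(schedule)

  aligns <- numeric(0); conds <- character(0); mods <- character(0)
  for (i in seq_len(nrow(stim))) {
    a <- stim$onset_s[i]
    i0 <- round(a * fs) - winSamp + 1L
    if (i0 < 1L || i0 + 2L * winSamp - 1L > nSamp) {
      warnf("stimulus epoch at %.2f s exceeds recording bounds; skipped", a)
      next
    }
    aligns <- c(aligns, a); conds <- c(conds, "stimulus")
    mods <- c(mods, stim$modality[i])
  }
  # ITI baselines: one candidate per inter-trial gap (catch trials also
  # delimit gaps); window centred in [offset + guard - 1, next fixation]
  for (i in seq_len(n)) {
    offset <- schedule$onset_s[i] + STIMULUS_DUR_S
    nextFix <- if (i < n) schedule$onset_s[i + 1] - schedule$fixation_dur_s[i + 1]
               else offset + schedule$iti_dur_s[i]
    lo <- offset + itiGuardS - halfWin
    if (nextFix - lo < 2 * halfWin) next
    a <- (lo + nextFix) / 2
    i0 <- round(a * fs) - winSamp + 1L
    if (i0 < 1L || i0 + 2L * winSamp - 1L > nSamp) next
    aligns <- c(aligns, a); conds <- c(conds, "iti"); mods <- c(mods, NA_character_)
  }
  if (!any(conds == "iti"))
    stopf("no inter-trial gap can host a baseline epoch (guard %.2f s)", itiGuardS)
  if (!any(conds == "stimulus")) stopf("no stimulus epoch fits the recording")

  ord <- order(aligns)
  aligns <- aligns[ord]; conds <- conds[ord]; mods <- mods[ord]
  # balance classes by subsampling the larger one
  si <- which(conds == "stimulus"); ii <- which(conds == "iti")
  m <- min(length(si), length(ii))
  pick <- withSeed(childSeed(seed, "epoch-balance"), {
    sort(c(if (length(si) > m) sample(si, m) else si,
           if (length(ii) > m) sample(ii, m) else ii))
  })
  aligns <- aligns[pick]; conds <- conds[pick]; mods <- mods[pick]

  nep <- length(aligns)
  data <- array(0, dim = c(nep, nrow(rec@data), 2L * winSamp))
  for (e in seq_len(nep)) {
    i0 <- round(aligns[e] * fs) - winSamp + 1L
    data[e, , ] <- rec@data[, i0:(i0 + 2L * winSamp - 1L)]
  }
  new("EpochSet", data = data, sfreqHz = fs, channelNames = rec@channelNames,
      windowS = c(-halfWin, halfWin), condition = conds, modality = mods,
      alignS = aligns, keptMask = rep(TRUE, nep))
}

# per-epoch maximum-over-channels peak-to-peak amplitude
epochPeakToPeak <- function(epochs) {
  d <- dim(epochs@data)
  m <- matrix(epochs@data, d[1] * d[2], d[3])    # (epoch, channel) x sample
  p2p <- matrix(apply(m, 1, function(v) max(v) - min(v)), d[1], d[2])
  apply(p2p, 1, max)
}

#' Estimate the global peak-to-peak rejection threshold
#'
#' Cross-validated selection of a single peak-to-peak amplitude cutoff: over
#' a grid of candidate thresholds spanning the observed per-epoch maximum
#' peak-to-peak range, the threshold is chosen to minimize the
#' cross-validated RMSE between the mean of threshold-surviving training
#' epochs and the median of validation epochs. This is the global-threshold
#' criterion of cross-validated artifact rejection, without channel-level
#' repair.
#'
#' @param epochs an [EpochSet-class] with at least 10 epochs.
#' @param nCandidates grid size (default 30).
#' @param folds cross-validation folds (default 5).
#' @param seed integer seed for the fold split.
#' @return the selected threshold in microvolts peak-to-peak. Scale
#'   equivariant: scaling the data by `c > 0` scales the result by `c`.
#' @export
estimateRejectionThreshold <- function(epochs, nCandidates = 30, folds = 5,
                                       seed = 1L) {
  stopifnot(is(epochs, "EpochSet"))
  nep <- nEpochs(epochs)
  if (nep < 10) stopf("threshold estimation needs at least 10 epochs (got %d)", nep)
  p2p <- epochPeakToPeak(epochs)
  grid <- seq(min(p2p), max(p2p), length.out = nCandidates)
  foldId <- withSeed(childSeed(seed, "reject-folds"),
                     sample(rep_len(seq_len(folds), nep)))
  # flatten to epochs x (channel, sample) once; fold medians and running
  # survivor means are then plain column operations
  d <- dim(epochs@data)
  flat <- matrix(epochs@data, d[1], d[2] * d[3])
  score <- numeric(nCandidates)
  for (f in seq_len(folds)) {
    tr <- which(foldId != f)
    va <- which(foldId == f)
    med <- apply(flat[va, , drop = FALSE], 2, stats::median)
    # survivors are nested in the threshold: accumulate epoch sums in
    # ascending peak-to-peak order
    trOrd <- tr[order(p2p[tr])]
    sums <- apply(flat[trOrd, , drop = FALSE], 2, cumsum)
    if (length(trOrd) == 1L) sums <- matrix(sums, nrow = 1)
    nSurv <- findInterval(grid, p2p[trOrd])
    for (g in seq_len(nCandidates)) {
      if (nSurv[g] == 0L) { score[g] <- score[g] + Inf; next }
      mn <- sums[nSurv[g], ] / nSurv[g]
      score[g] <- score[g] + sqrt(mean((mn - med)^2))
    }
  }
  grid[which.min(score)]
}

#' Reject epochs above a peak-to-peak threshold and re-balance
#'
#' Masks out every epoch whose maximum-over-channels peak-to-peak amplitude
#' exceeds `threshold`, then re-balances the surviving classes by seeded
#' uniform subsampling of the larger class, so that the binomial chance
#' level of the downstream contrast stays at 0.5.
#'
#' @param epochs an [EpochSet-class].
#' @param threshold peak-to-peak cutoff in microvolts (> 0).
#' @param seed integer seed for the balancing subsample.
#' @return the [EpochSet-class] with an updated `keptMask`.
#' @export
dropBadEpochs <- function(epochs, threshold, seed = 1L) {
  stopifnot(is(epochs, "EpochSet"))
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold) ||
      threshold <= 0)
    stopf("'threshold' must be positive")   # +Inf keeps everything
  p2p <- epochPeakToPeak(epochs)
  kept <- epochs@keptMask & (p2p <= threshold)
  if (!any(kept)) stopf("all epochs exceed the rejection threshold")
  si <- which(kept & epochs@condition == "stimulus")
  ii <- which(kept & epochs@condition == "iti")
  m <- min(length(si), length(ii))
  if (m == 0) stopf("rejection removed an entire class")
  pick <- withSeed(childSeed(seed, "drop-balance"), {
    sort(c(if (length(si) > m) sample(si, m) else si,
           if (length(ii) > m) sample(ii, m) else ii))
  })
  mask <- rep(FALSE, nEpochs(epochs))
  mask[pick] <- TRUE
  initialize(epochs, keptMask = mask)
}
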