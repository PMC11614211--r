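# Constructors for the synthetic-cohort configuration objects.

#' Specify a planted ground-truth effect
#'
#' @param contact channel name carrying the effect.
#' @param modalities character subset of
#'   `c("arabic", "dots", "spoken", "beeps")` whose trials express the effect.
#' @param bandHz length-2 frequency band in Hz (within `[1, 250]`).
#' @param windowS length-2 window in seconds relative to stimulus onset
#'   (within `[-1, 1]`).
#' @param direction `"increase"` or `"decrease"` of band amplitude.
#' @param magnitude dimensionless multiplier on the baseline band amplitude
#'   (> 0). An `"increase"` scales the in-window band component by
#'   `magnitude`, a `"decrease"` by `1/magnitude`.
#' @param erpAmplitude evoked-potential peak amplitude in microvolts
#'   (0 disables the evoked component).
#' @return an [EffectSpec-class] object.
#' @export
#' @examples
#' effectSpec("CH01", c("spoken", "beeps"), bandHz = c(70, 150),
#'            windowS = c(0, 0.5), magnitude = 3)
effectSpec <- function(contact, modalities = MODALITIES, bandHz, windowS,
                       direction = c("increase", "decrease"), magnitude,
                       erpAmplitude = 0) {
  direction <- match.arg(direction)
  new("EffectSpec", contact = contact, modalities = modalities,
      bandHz = as.numeric(bandHz), windowS = as.numeric(windowS),
      direction = direction, magnitude = as.numeric(magnitude),
      erpAmplitude = as.numeric(erpAmplitude))
}

#' Specify the 1/f background-noise model
#'
#' @param oneOverFExponent spectral exponent a of the 1/f^a power spectrum
#'   (default 1, i.e. pink noise).
#' @param amplitudeUv RMS amplitude in microvolts (default 20).
#' @param lineFreqHz optional mains frequency in Hz; `NULL` (default)
#'   disables the mains component.
#' @return a [NoiseModel-class] object.
#' @export
noiseModel <- function(oneOverFExponent = 1, amplitudeUv = 20, lineFreqHz = NULL) {
  new("NoiseModel", oneOverFExponent = as.numeric(oneOverFExponent),
      amplitudeUv = as.numeric(amplitudeUv),
      lineFreqHz = if (is.null(lineFreqHz)) numeric(0) else as.numeric(lineFreqHz))
}

#' Configure a synthetic sEEG cohort
#'
#' The defaults reproduce the task's delivery conditions: 40 presentations of
#' each of the four number modalities, 10% catch trials, 0.5-1.5 s jittered
#' fixation, 1 s stimulus, 1.5-3.5 s jittered inter-trial period, sampled at
#' 1000 Hz over a pink-noise background.
#'
#' @param nContacts number of channels.
#' @param sfreqHz sampling rate (default 1000).
#' @param presentationsPerModality stimulus trials per modality (default 40).
#' @param catchRate fraction of all trials that are catch trials (default 0.10).
#' @param effects list of [EffectSpec-class] objects (default none).
#' @param noise a [NoiseModel-class] (default [noiseModel()]).
#' @param regionLabels named character vector, contact name -> region label.
#'   Defaults to contacts `CH01..CHnn` labelled `"unknown"`.
#' @param seed default integer seed.
#' @return a [SynthConfig-class] object.
#' @export
#' @examples
#' cfg <- synthConfig(nContacts = 4)
#' sched <- buildSchedule(cfg, seed = 1)
#' table(sched$modality[!sched$is_catch])
synthConfig <- function(nContacts, sfreqHz = 1000,
                        presentationsPerModality = 40, catchRate = 0.10,
                        effects = list(), noise = noiseModel(),
                        regionLabels = NULL, seed = 1L) {
  nContacts <- as.integer(nContacts)
  if (is.na(nContacts) || nContacts < 1L)
    stopf("'nContacts' must be a positive count")
  if (!isNum(catchRate) || catchRate < 0 || catchRate >= 1)
    stopf("'catchRate' must be a fraction in [0, 1)")
  ppm <- as.integer(presentationsPerModality)
  if (is.na(ppm) || ppm < 1L)
    stopf("'presentationsPerModality' must be a positive count")
  if (is.null(regionLabels)) {
    regionLabels <- rep("unknown", nContacts)
    names(regionLabels) <- sprintf("CH%02d", seq_len(nContacts))
  }
  if (length(regionLabels) == 0 && nContacts > 0)
    stopf("'regionLabels' is empty but %d contacts were requested", nContacts)
  new("SynthConfig", nContacts = nContacts, sfreqHz = as.numeric(sfreqHz),
      presentationsPerModality = ppm, catchRate = as.numeric(catchRate),
      effects = effects, noise = noise, regionLabels = regionLabels,
      seed = as.integer(seed))
}

#' Contact names of a synthetic configuration
#' @param config a [SynthConfig-class].
#' @return character vector of contact names.
#' @export
contactNames <- function(config) {
  stopifnot(is(config, "SynthConfig"))
  names(config@regionLabels)
}
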