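#' @import methods
NULL

MODALITIES <- c("arabic", "dots", "spoken", "beeps")

# ---------------------------------------------------------------------------
# Synthetic-data configuration classes
# ---------------------------------------------------------------------------

#' Planted spectral effect specification
#'
#' Describes one ground-truth effect carried by a synthetic contact: a
#' band-limited amplitude change (and/or an evoked potential) applied in a
#' time window around stimulus onset on trials of the given modalities.
#'
#' @slot contact channel name carrying the effect.
#' @slot modalities subset of `c("arabic","dots","spoken","beeps")`.
#' @slot bandHz length-2 numeric, frequency band in Hz within [1, 250].
#' @slot windowS length-2 numeric, window in seconds relative to stimulus
#'   onset, within [-1, 1].
#' @slot direction `"increase"` or `"decrease"` of band amplitude.
#' @slot magnitude dimensionless multiplier (> 0) on baseline band amplitude.
#' @slot erpAmplitude evoked-potential amplitude in microvolts (0 = none).
#' @export
setClass("EffectSpec", representation(
  contact = "character", modalities = "character",
  bandHz = "numeric", windowS = "numeric",
  direction = "character", magnitude = "numeric", erpAmplitude = "numeric"))

setValidity("EffectSpec", function(object) {
  msg <- character()
  if (!isString(object@contact)) msg <- c(msg, "'contact' must be one channel name")
  if (!length(object@modalities) || !all(object@modalities %in% MODALITIES))
    msg <- c(msg, "'modalities' must be a non-empty subset of the four formats")
  if (length(object@bandHz) != 2 || object@bandHz[1] >= object@bandHz[2] ||
      object@bandHz[1] < 1 || object@bandHz[2] > 250)
    msg <- c(msg, "'bandHz' must be an increasing pair within [1, 250] Hz")
  if (length(object@windowS) != 2 || object@windowS[1] >= object@windowS[2] ||
      object@windowS[1] < -1 || object@windowS[2] > 1)
    msg <- c(msg, "'windowS' must be an increasing pair within [-1, 1] s")
  if (!object@direction %in% c("increase", "decrease"))
    msg <- c(msg, "'direction' must be 'increase' or 'decrease'")
  if (!isNum(object@magnitude) || object@magnitude <= 0)
    msg <- c(msg, "'magnitude' must be > 0")
  if (!isNum(object@erpAmplitude)) msg <- c(msg, "'erpAmplitude' must be numeric")
  if (length(msg)) msg else TRUE
})

#' Background-noise model for synthetic recordings
#'
#' @slot oneOverFExponent spectral exponent of the 1/f^a background (>= 0).
#' @slot amplitudeUv RMS amplitude in microvolts (>= 0; 0 gives a silent
#'   background so that deterministic evoked components can be inspected).
#' @slot lineFreqHz optional mains frequency in Hz (numeric(0) = none).
#' @export
setClass("NoiseModel", representation(
  oneOverFExponent = "numeric", amplitudeUv = "numeric", lineFreqHz = "numeric"))

setValidity("NoiseModel", function(object) {
  msg <- character()
  if (!isNum(object@oneOverFExponent) || object@oneOverFExponent < 0)
    msg <- c(msg, "'oneOverFExponent' must be >= 0")
  if (!isNum(object@amplitudeUv) || object@amplitudeUv < 0)
    msg <- c(msg, "'amplitudeUv' must be >= 0")
  if (length(object@lineFreqHz) > 1 ||
      (length(object@lineFreqHz) == 1 && object@lineFreqHz <= 0))
    msg <- c(msg, "'lineFreqHz' must be empty or a positive frequency")
  if (length(msg)) msg else TRUE
})

#' Synthetic-cohort configuration
#'
#' @slot nContacts number of channels.
#' @slot sfreqHz sampling rate in samples/second.
#' @slot presentationsPerModality stimulus trials per modality (default 40).
#' @slot catchRate fraction of all trials that are catch trials (default 0.10).
#' @slot effects list of [EffectSpec-class] objects.
#' @slot noise a [NoiseModel-class].
#' @slot regionLabels named character: contact name -> anatomical region label.
#' @slot seed default integer seed for schedule/recording generation.
#' @export
setClass("SynthConfig", representation(
  nContacts = "integer", sfreqHz = "numeric",
  presentationsPerModality = "integer", catchRate = "numeric",
  effects = "list", noise = "NoiseModel", regionLabels = "character",
  seed = "integer"))

setValidity("SynthConfig", function(object) {
  msg <- character()
  if (object@nContacts < 1L) msg <- c(msg, "'nContacts' must be >= 1")
  if (!isNum(object@sfreqHz) || object@sfreqHz <= 0)
    msg <- c(msg, "'sfreqHz' must be positive")
  if (object@presentationsPerModality < 1L)
    msg <- c(msg, "'presentationsPerModality' must be >= 1")
  if (!isNum(object@catchRate) || object@catchRate < 0 || object@catchRate >= 1)
    msg <- c(msg, "'catchRate' must be in [0, 1)")
  if (length(object@regionLabels) != object@nContacts)
    msg <- c(msg, "'regionLabels' must provide one label per contact")
  if (is.null(names(object@regionLabels)) || anyDuplicated(names(object@regionLabels)))
    msg <- c(msg, "'regionLabels' names (contact names) must be unique")
  if (anyNA(object@regionLabels) || any(!nzchar(object@regionLabels)))
    msg <- c(msg, "'regionLabels' must be non-empty strings")
  for (ef in object@effects) {
    if (!is(ef, "EffectSpec")) { msg <- c(msg, "'effects' must contain EffectSpec objects"); break }
    if (!ef@contact %in% names(object@regionLabels))
      msg <- c(msg, sprintf("effect references unknown contact '%s'", ef@contact))
    if (ef@bandHz[2] >= object@sfreqHz / 2)
      msg <- c(msg, sprintf("effect band upper edge %.1f Hz is at or above Nyquist", ef@bandHz[2]))
  }
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Signal containers
# ---------------------------------------------------------------------------

#' Continuous multichannel sEEG recording
#'
#' @slot data channels x samples voltage matrix in microvolts.
#' @slot sfreqHz sampling rate in samples/second.
#' @slot channelNames unique channel names, one per row of `data`.
#' @export
setClass("SEEGRecording", representation(
  data = "matrix", sfreqHz = "numeric", channelNames = "character"))

setValidity("SEEGRecording", function(object) {
  msg <- character()
  if (!is.numeric(object@data)) msg <- c(msg, "'data' must be numeric")
  if (any(!is.finite(object@data))) msg <- c(msg, "'data' contains non-finite samples")
  if (length(object@channelNames) != nrow(object@data))
    msg <- c(msg, "one channel name per data row required")
  if (anyDuplicated(object@channelNames)) msg <- c(msg, "channel names must be unique")
  if (!isNum(object@sfreqHz) || object@sfreqHz <= 0) msg <- c(msg, "'sfreqHz' must be positive")
  if (length(msg)) msg else TRUE
})

#' Epoched data aligned to stimulus onsets and inter-trial baselines
#'
#' Both conditions use the fixed (-1, +1) s window: stimulus epochs are
#' aligned to stimulus onset, inter-trial (ITI) epochs to a baseline point in
#' the stimulus-free gap. Class counts are balanced by construction.
#'
#' @slot data epochs x channels x samples array (microvolts).
#' @slot sfreqHz sampling rate.
#' @slot channelNames channel names.
#' @slot windowS length-2 numeric epoch window in seconds, `c(-1, 1)`.
#' @slot condition per-epoch label, `"stimulus"` or `"iti"`.
#' @slot modality per-epoch modality (`NA` for ITI epochs).
#' @slot alignS per-epoch absolute alignment time in seconds.
#' @slot keptMask per-epoch logical; FALSE after artifact rejection.
#' @export
setClass("EpochSet", representation(
  data = "array", sfreqHz = "numeric", channelNames = "character",
  windowS = "numeric", condition = "character", modality = "character",
  alignS = "numeric", keptMask = "logical"))

setValidity("EpochSet", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3) msg <- c(msg, "'data' must be epochs x channels x samples")
  else {
    if (length(object@condition) != d[1]) msg <- c(msg, "'condition' length != n epochs")
    if (length(object@modality) != d[1]) msg <- c(msg, "'modality' length != n epochs")
    if (length(object@alignS) != d[1]) msg <- c(msg, "'alignS' length != n epochs")
    if (length(object@keptMask) != d[1]) msg <- c(msg, "'keptMask' length != n epochs")
    if (length(object@channelNames) != d[2]) msg <- c(msg, "'channelNames' length != n channels")
  }
  if (!all(object@condition %in% c("stimulus", "iti")))
    msg <- c(msg, "'condition' must be 'stimulus' or 'iti'")
  if (length(object@windowS) != 2 || object@windowS[1] >= object@windowS[2])
    msg <- c(msg, "'windowS' must be an increasing pair")
  if (length(msg)) msg else TRUE
})

#' Time-frequency feature configuration
#'
#' @slot freqsHz strictly increasing wavelet centre frequencies in [1, 250] Hz.
#' @slot nCycles per-frequency Morlet cycle counts (> 0).
#' @slot decim temporal decimation factor applied to the feature time grid.
#' @slot bandpassHz band for the appended voltage row (default 0.1-40 Hz).
#' @slot logPower apply log10 to wavelet power (default TRUE).
#' @export
setClass("TFRConfig", representation(
  freqsHz = "numeric", nCycles = "numeric", decim = "integer",
  bandpassHz = "numeric", logPower = "logical"))

setValidity("TFRConfig", function(object) {
  msg <- character()
  f <- object@freqsHz
  if (!length(f) || any(diff(f) <= 0)) msg <- c(msg, "'freqsHz' must be strictly increasing")
  if (any(f < 1) || any(f > 250)) msg <- c(msg, "'freqsHz' must lie within [1, 250] Hz")
  if (length(object@nCycles) != length(f) || any(object@nCycles <= 0))
    msg <- c(msg, "'nCycles' must be positive, one per frequency")
  if (object@decim < 1L) msg <- c(msg, "'decim' must be >= 1")
  if (length(object@bandpassHz) != 2 || object@bandpassHz[1] <= 0 ||
      object@bandpassHz[1] >= object@bandpassHz[2])
    msg <- c(msg, "'bandpassHz' must be an increasing positive pair")
  if (length(msg)) msg else TRUE
})

#' Per-epoch classifier features for one contact
#'
#' Row-wise flattened (nFreqs + 1) x nTimes grids: rows 1..nFreqs are Morlet
#' power (log10 if configured), the final row is the band-passed voltage
#' trace on the same time grid. `features[i, ]` is the column-major
#' flattening of epoch i's grid; [unflattenGrid()] inverts it exactly.
#'
#' @slot features epochs x ((nFreqs + 1) * nTimes) numeric matrix.
#' @slot freqsHz frequency axis of the grid rows.
#' @slot timesS time axis (seconds relative to alignment) of the grid columns.
#' @slot channel contact name the features belong to.
#' @slot condition per-epoch `"stimulus"`/`"iti"` label.
#' @slot modality per-epoch modality (`NA` for ITI epochs).
#' @export
setClass("EpochFeatureSet", representation(
  features = "matrix", freqsHz = "numeric", timesS = "numeric",
  channel = "character", condition = "character", modality = "character"))

setValidity("EpochFeatureSet", function(object) {
  msg <- character()
  p <- (length(object@freqsHz) + 1L) * length(object@timesS)
  if (ncol(object@features) != p)
    msg <- c(msg, "feature width must equal (nFreqs + 1) * nTimes")
  if (length(object@condition) != nrow(object@features))
    msg <- c(msg, "'condition' length != n epochs")
  if (length(object@modality) != nrow(object@features))
    msg <- c(msg, "'modality' length != n epochs")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Results containers
# ---------------------------------------------------------------------------

#' Binomial null specification for decoding accuracy
#'
#' @slot p0 chance probability (0.5 for a balanced two-class contrast).
#' @slot nObs observation count of the null (per the study design, the
#'   number of presentations of each modality).
#' @slot alpha significance level.
#' @export
setClass("NullSpec", representation(p0 = "numeric", nObs = "integer", alpha = "numeric"))

setValidity("NullSpec", function(object) {
  msg <- character()
  if (!isNum(object@p0) || object@p0 <= 0 || object@p0 >= 1)
    msg <- c(msg, "'p0' must be in (0, 1)")
  if (object@nObs < 1L) msg <- c(msg, "'nObs' must be >= 1")
  if (!isNum(object@alpha) || object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "'alpha' must be in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Cross-validated decoding result for one contact and format
#'
#' @slot contact channel name.
#' @slot format modality or `"all"`.
#' @slot nTest number of pooled held-out test observations.
#' @slot nCorrect number of correct held-out predictions.
#' @slot accuracy pooled cross-validated accuracy.
#' @slot pValue exact binomial upper-tail probability.
#' @slot significant TRUE when `pValue < alpha` of the null spec.
#' @slot null the [NullSpec-class] used.
#' @slot folds per-fold list: `testIdx`, `center`, `scale`, `basis` (feature
#'   x component PCA axes), `explained` (component variances), `svmW`,
#'   `svmB`, `pred`, `decision`.
#' @slot freqsHz,timesS feature-grid axes for back-projection.
#' @export
setClass("ContactResult", representation(
  contact = "character", format = "character",
  nTest = "integer", nCorrect = "integer", accuracy = "numeric",
  pValue = "numeric", significant = "logical", null = "NullSpec",
  folds = "list", freqsHz = "numeric", timesS = "numeric"))

setValidity("ContactResult", function(object) {
  msg <- character()
  if (object@accuracy < 0 || object@accuracy > 1) msg <- c(msg, "'accuracy' outside [0, 1]")
  if (object@nCorrect > object@nTest) msg <- c(msg, "'nCorrect' > 'nTest'")
  if (!identical(object@significant, object@pValue < object@null@alpha))
    msg <- c(msg, "'significant' inconsistent with pValue and alpha")
  if (length(msg)) msg else TRUE
})

#' Significant time-frequency clusters from a sign-flip permutation test
#'
#' @slot clusters list of clusters, each with `cells` (linear indices into
#'   the grid), `mass` (sum of t-values), `sign`, `pValue`, `significant`.
#' @slot tMap observed one-sample t map, (nFreqs + 1) x nTimes.
#' @slot threshold cluster-forming t threshold.
#' @slot permMax permutation distribution of the maximum absolute cluster mass.
#' @slot alpha significance level.
#' @slot nPerm number of sign-flip permutations.
#' @export
setClass("ClusterSet", representation(
  clusters = "list", tMap = "matrix", threshold = "numeric",
  permMax = "numeric", alpha = "numeric", nPerm = "integer"))

setValidity("ClusterSet", function(object) {
  msg <- character()
  for (cl in object@clusters) {
    if (!all(c("cells", "mass", "sign", "pValue", "significant") %in% names(cl))) {
      msg <- c(msg, "each cluster needs cells/mass/sign/pValue/significant"); break
    }
    if (cl$pValue <= 0 || cl$pValue > 1) { msg <- c(msg, "cluster p-values must be in (0, 1]"); break }
  }
  if (length(msg)) msg else TRUE
})

#' Group-level time-frequency feature maps
#'
#' Three grids sharing the feature-space shape: the proportion of analyzed
#' contacts with a significant cluster covering each point; among those, the
#' proportion whose covering cluster is positive (NA where uncovered); and
#' the mean decoding accuracy of covering contacts (NA where uncovered).
#'
#' @slot proportionSignificant,proportionPositive,classificationValue
#'   (nFreqs + 1) x nTimes matrices.
#' @slot freqsHz,timesS grid axes.
#' @slot nContacts number of contacts analyzed (the denominator).
#' @slot format the format the maps summarize.
#' @export
setClass("FeatureMapBundle", representation(
  proportionSignificant = "matrix", proportionPositive = "matrix",
  classificationValue = "matrix", freqsHz = "numeric", timesS = "numeric",
  nContacts = "integer", format = "character"))

setValidity("FeatureMapBundle", function(object) {
  msg <- character()
  dm <- dim(object@proportionSignificant)
  if (!identical(dim(object@proportionPositive), dm) ||
      !identical(dim(object@classificationValue), dm))
    msg <- c(msg, "all three maps must share one shape")
  ps <- object@proportionSignificant
  if (any(ps < 0 | ps > 1, na.rm = TRUE)) msg <- c(msg, "proportions must lie in [0, 1]")
  if (any(!is.na(object@proportionPositive) & ps == 0))
    msg <- c(msg, "directionality defined where no cluster covers the point")
  if (any(!is.na(object@classificationValue) & ps == 0))
    msg <- c(msg, "classification value defined where no cluster covers the point")
  if (length(msg)) msg else TRUE
})
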