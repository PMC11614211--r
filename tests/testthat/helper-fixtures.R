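# Programmatic fixtures shared across test files.

`%||%` <- function(a, b) if (is.null(a)) b else a

# EpochSet straight from an epochs x channels x samples array
makeEpochSet <- function(data, sfreq = 200, condition = NULL, modality = NULL,
                         window = c(-1, 1)) {
  n <- dim(data)[1]
  if (is.null(condition)) condition <- rep(c("stimulus", "iti"), length.out = n)
  if (is.null(modality)) modality <- rep(NA_character_, n)
  new("EpochSet", data = data, sfreqHz = sfreq,
      channelNames = sprintf("E%02d", seq_len(dim(data)[2])),
      windowS = window, condition = condition, modality = modality,
      alignS = seq_len(n), keptMask = rep(TRUE, n))
}

# balanced Gaussian-noise epochs
noiseEpochs <- function(nPerClass = 10, nCh = 2, nSamp = 400, sfreq = 200,
                        sd = 1, seed = 1) {
  set.seed(seed)
  n <- 2 * nPerClass
  makeEpochSet(array(rnorm(n * nCh * nSamp, sd = sd), c(n, nCh, nSamp)),
               sfreq = sfreq,
               condition = rep(c("stimulus", "iti"), each = nPerClass))
}

# EpochFeatureSet from a raw feature matrix (grid nRows x nTimes)
makeFeatureSet <- function(X, nRows, nTimes, condition, modality = NULL,
                           channel = "T01") {
  if (is.null(modality)) modality <- rep(NA_character_, nrow(X))
  new("EpochFeatureSet", features = X,
      freqsHz = seq(4, 100, length.out = nRows - 1),
      timesS = seq(-0.5, 0.5, length.out = nTimes), channel = channel,
      condition = condition, modality = modality)
}

# minimal valid ContactResult for group-level tests
makeResult <- function(contact, format, accuracy, alpha = 0.01,
                       nTest = 40L, freqs = 1:4, times = 1:5) {
  nCorrect <- as.integer(round(accuracy * nTest))
  p <- binomialP(nCorrect, nullSpec(nObs = nTest, alpha = alpha))
  new("ContactResult", contact = contact, format = format, nTest = nTest,
      nCorrect = nCorrect, accuracy = accuracy, pValue = p,
      significant = p < alpha, null = nullSpec(nObs = nTest, alpha = alpha),
      folds = list(), freqsHz = as.numeric(freqs), timesS = as.numeric(times))
}

# minimal ClusterSet with given significant clusters on an nr x nt grid
makeClusterSet <- function(cells, signs, nr, nt, alpha = 0.01) {
  cl <- Map(function(cc, sg) list(cells = cc,
                                  mass = (if (sg == "positive") 3 else -3) * length(cc),
                                  sign = sg, pValue = 0.001, significant = TRUE),
            cells, signs)
  new("ClusterSet", clusters = cl, tMap = matrix(0, nr, nt), threshold = 2.5,
      permMax = rep(1, 100), alpha = alpha, nPerm = 100L)
}

# small synthetic cohort used by several end-to-end tests
smallCohortConfig <- function(nContacts = 4, ppm = 12,
                              effects = list(
                                effectSpec("CH01", bandHz = c(70, 150),
                                           windowS = c(0, 0.5), magnitude = 3))) {
  labels <- stats::setNames(rep(c("superiortemporal", "putamen"),
                                length.out = nContacts),
                            sprintf("CH%02d", seq_len(nContacts)))
  synthConfig(nContacts = nContacts, presentationsPerModality = ppm,
              effects = effects, regionLabels = labels)
}

# the acceptance cohort: 16 contacts, 6 planted effects
# (2 broadband increases, 2 theta increases, 1 alpha increase,
#  1 alpha-beta desynchronization)
recoveryCohortConfig <- function() {
  labels <- stats::setNames(
    c("superiortemporal", "superiortemporal", "superiorparietal",
      "superiorparietal", "inferiorparietal", "precentral",
      "putamen", "fusiform", "lingual", "superiorfrontal", "middletemporal",
      "putamen", "fusiform", "lingual", "superiorfrontal", "middletemporal"),
    sprintf("CH%02d", 1:16))
  effects <- list(
    effectSpec("CH01", bandHz = c(70, 150), windowS = c(0, 0.5), magnitude = 3),
    effectSpec("CH02", bandHz = c(70, 150), windowS = c(0, 0.5), magnitude = 3),
    effectSpec("CH03", bandHz = c(4, 8), windowS = c(0, 0.8), magnitude = 3),
    effectSpec("CH04", bandHz = c(4, 8), windowS = c(0, 0.8), magnitude = 3),
    effectSpec("CH05", bandHz = c(8, 12), windowS = c(0, 0.8), magnitude = 3),
    effectSpec("CH06", bandHz = c(8, 25), windowS = c(0.1, 0.8),
               direction = "decrease", magnitude = 3))
  synthConfig(nContacts = 16, effects = effects, regionLabels = labels)
}

effectContacts <- function(config) {
  unique(vapply(config@effects, function(e) e@contact, ""))
}

# planted (band x window) mask on a feature grid, voltage row excluded
plantedMask <- function(effect, freqs, times) {
  nr <- length(freqs) + 1L
  mask <- matrix(FALSE, nr, length(times))
  mask[which(freqs >= effect@bandHz[1] & freqs <= effect@bandHz[2]),
       which(times >= effect@windowS[1] & times <= effect@windowS[2])] <- TRUE
  mask
}
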