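#' Accessors for seegDecode containers
#'
#' Small accessor methods exposing the slots of the package's S4 containers.
#'
#' @name accessors
#' @aliases channelNames samplingRate recordingData epochData epochCondition
#'   epochModality keptMask nEpochs featureMatrix featureFreqs featureTimes
#'   accuracy pValue isSignificant clusters significantClusters
NULL

#' @rdname accessors
#' @export
setMethod("channelNames", "SEEGRecording", function(x) x@channelNames)
#' @rdname accessors
#' @export
setMethod("channelNames", "EpochSet", function(x) x@channelNames)
#' @rdname accessors
#' @export
setMethod("samplingRate", "SEEGRecording", function(x) x@sfreqHz)
#' @rdname accessors
#' @export
setMethod("samplingRate", "EpochSet", function(x) x@sfreqHz)
#' @rdname accessors
#' @export
setMethod("recordingData", "SEEGRecording", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("epochData", "EpochSet", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("epochCondition", "EpochSet", function(x) x@condition)
#' @rdname accessors
#' @export
setMethod("epochCondition", "EpochFeatureSet", function(x) x@condition)
#' @rdname accessors
#' @export
setMethod("epochModality", "EpochSet", function(x) x@modality)
#' @rdname accessors
#' @export
setMethod("epochModality", "EpochFeatureSet", function(x) x@modality)
#' @rdname accessors
#' @export
setMethod("keptMask", "EpochSet", function(x) x@keptMask)
#' @rdname accessors
#' @export
setMethod("nEpochs", "EpochSet", function(x) dim(x@data)[1])
#' @rdname accessors
#' @export
setMethod("nEpochs", "EpochFeatureSet", function(x) nrow(x@features))
#' @rdname accessors
#' @export
setMethod("featureMatrix", "EpochFeatureSet", function(x) x@features)
#' @rdname accessors
#' @export
setMethod("featureFreqs", "EpochFeatureSet", function(x) x@freqsHz)
#' @rdname accessors
#' @export
setMethod("featureTimes", "EpochFeatureSet", function(x) x@timesS)
#' @rdname accessors
#' @export
setMethod("accuracy", "ContactResult", function(x) x@accuracy)
#' @rdname accessors
#' @export
setMethod("pValue", "ContactResult", function(x) x@pValue)
#' @rdname accessors
#' @export
setMethod("isSignificant", "ContactResult", function(x) x@significant)
#' @rdname accessors
#' @export
setMethod("clusters", "ClusterSet", function(x) x@clusters)
#' @rdname accessors
#' @export
setMethod("significantClusters", "ClusterSet",
          function(x) Filter(function(cl) isTRUE(cl$significant), x@clusters))

#' Subset an EpochSet by epoch index
#'
#' @param x an `EpochSet`.
#' @param i epoch indices (integer or logical).
#' @param j,...,drop ignored.
#' @return an `EpochSet` containing the selected epochs.
#' @export
setMethod("[", "EpochSet", function(x, i, j, ..., drop = FALSE) {
  new("EpochSet",
      data = x@data[i, , , drop = FALSE], sfreqHz = x@sfreqHz,
      channelNames = x@channelNames, windowS = x@windowS,
      condition = x@condition[i], modality = x@modality[i],
      alignS = x@alignS[i], keptMask = x@keptMask[i])
})

#' Subset an EpochFeatureSet by epoch index
#'
#' @param x an `EpochFeatureSet`.
#' @param i epoch indices (integer or logical).
#' @param j,...,drop ignored.
#' @return an `EpochFeatureSet` containing the selected epochs.
#' @export
setMethod("[", "EpochFeatureSet", function(x, i, j, ..., drop = FALSE) {
  new("EpochFeatureSet",
      features = x@features[i, , drop = FALSE], freqsHz = x@freqsHz,
      timesS = x@timesS, channel = x@channel,
      condition = x@condition[i], modality = x@modality[i])
})

#' Drop epochs masked out by artifact rejection
#'
#' @param x an `EpochSet`.
#' @return an `EpochSet` restricted to epochs with `keptMask == TRUE`.
#' @export
keptEpochs <- function(x) {
  stopifnot(is(x, "EpochSet"))
  x[which(x@keptMask)]
}

# ---- show methods ---------------------------------------------------------

setMethod("show", "SEEGRecording", function(object) {
  cat(sprintf("SEEGRecording: %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(object@data), ncol(object@data), object@sfreqHz,
              ncol(object@data) / object@sfreqHz))
  cat("  channels:", paste(utils::head(object@channelNames, 6), collapse = ", "),
      if (length(object@channelNames) > 6) "..." else "", "\n")
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("EpochSet: %d epochs x %d channels x %d samples @ %g Hz\n",
              d[1], d[2], d[3], object@sfreqHz))
  cat(sprintf("  window [%g, %g] s; stimulus %d / iti %d; kept %d\n",
              object@windowS[1], object@windowS[2],
              sum(object@condition == "stimulus"), sum(object@condition == "iti"),
              sum(object@keptMask)))
})

setMethod("show", "EpochFeatureSet", function(object) {
  cat(sprintf("EpochFeatureSet [%s]: %d epochs x %d features (%d freqs + voltage row, %d times)\n",
              object@channel, nrow(object@features), ncol(object@features),
              length(object@freqsHz), length(object@timesS)))
})

setMethod("show", "ContactResult", function(object) {
  cat(sprintf("ContactResult %s [%s]: accuracy %.3f (%d/%d), binomial p = %.4g%s\n",
              object@contact, object@format, object@accuracy, object@nCorrect,
              object@nTest, object@pValue,
              if (object@significant) " *" else ""))
})

setMethod("show", "ClusterSet", function(object) {
  ns <- sum(vapply(object@clusters, function(cl) isTRUE(cl$significant), logical(1)))
  cat(sprintf("ClusterSet: %d clusters (%d significant at alpha = %g), t threshold %.3f, %d permutations\n",
              length(object@clusters), ns, object@alpha, object@threshold, object@nPerm))
})

setMethod("show", "FeatureMapBundle", function(object) {
  cat(sprintf("FeatureMapBundle [%s]: %d x %d grid over %d contacts; coverage %.1f%%\n",
              object@format, nrow(object@proportionSignificant),
              ncol(object@proportionSignificant), object@nContacts,
              100 * mean(object@proportionSignificant > 0)))
})
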