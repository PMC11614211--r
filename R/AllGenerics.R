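# Accessor generics. Slot access from user code goes through these.

#' @rdname accessors
#' @param x an object.
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("recordingData", function(x) standardGeneric("recordingData"))

#' @rdname accessors
#' @export
setGeneric("epochData", function(x) standardGeneric("epochData"))

#' @rdname accessors
#' @export
setGeneric("epochCondition", function(x) standardGeneric("epochCondition"))

#' @rdname accessors
#' @export
setGeneric("epochModality", function(x) standardGeneric("epochModality"))

#' @rdname accessors
#' @export
setGeneric("keptMask", function(x) standardGeneric("keptMask"))

#' @rdname accessors
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))

#' @rdname accessors
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname accessors
#' @export
setGeneric("featureFreqs", function(x) standardGeneric("featureFreqs"))

#' @rdname accessors
#' @export
setGeneric("featureTimes", function(x) standardGeneric("featureTimes"))

#' @rdname accessors
#' @export
setGeneric("accuracy", function(x) standardGeneric("accuracy"))

#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname accessors
#' @export
setGeneric("isSignificant", function(x) standardGeneric("isSignificant"))

#' @rdname accessors
#' @export
setGeneric("clusters", function(x) standardGeneric("clusters"))

#' @rdname accessors
#' @export
setGeneric("significantClusters", function(x) standardGeneric("significantClusters"))
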