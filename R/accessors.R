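#' Accessors for criticalTC objects
#'
#' Slot access for the core S4 containers. Prefer these over `@`.
#'
#' @param object a criticalTC S4 object.
#' @return the corresponding component; see the class documentation.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("networkWeights", function(object) standardGeneric("networkWeights"))
#' @rdname accessors
#' @export
setMethod("networkWeights", "WeightMatrix", function(object) object@weights)

#' @rdname accessors
#' @export
setGeneric("inhibitoryNeurons", function(object) standardGeneric("inhibitoryNeurons"))
#' @rdname accessors
#' @export
setMethod("inhibitoryNeurons", "WeightMatrix", function(object) object@inhibitory)

#' @rdname accessors
#' @export
setGeneric("populationActivity", function(object) standardGeneric("populationActivity"))
#' @rdname accessors
#' @export
setMethod("populationActivity", "ActivityTrace", function(object) object@populationActivity)

#' @rdname accessors
#' @export
setGeneric("raster", function(object) standardGeneric("raster"))
#' @rdname accessors
#' @export
setMethod("raster", "ActivityTrace", function(object) object@raster)

#' @rdname accessors
#' @export
setGeneric("samples", function(object) standardGeneric("samples"))
#' @rdname accessors
#' @export
setMethod("samples", "Recording", function(object) object@samples)

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setMethod("samplingRate", "Recording", function(object) object@rate)

#' @rdname accessors
#' @export
setGeneric("channelLabels", function(object) standardGeneric("channelLabels"))
#' @rdname accessors
#' @export
setMethod("channelLabels", "Recording", function(object) object@labels)
#' @rdname accessors
#' @export
setMethod("channelLabels", "PowerSeries", function(object) object@labels)

#' @rdname accessors
#' @export
setGeneric("badChannels", function(object) standardGeneric("badChannels"))
#' @rdname accessors
#' @export
setMethod("badChannels", "Recording", function(object) object@bad)

#' @rdname accessors
#' @export
setGeneric("maskIntervals", function(object) standardGeneric("maskIntervals"))
#' @rdname accessors
#' @export
setMethod("maskIntervals", "Recording", function(object) object@maskIntervals)

#' @rdname accessors
#' @export
setGeneric("powerValues", function(object) standardGeneric("powerValues"))
#' @rdname accessors
#' @export
setMethod("powerValues", "PowerSeries", function(object) object@values)

#' @rdname accessors
#' @export
setGeneric("validBins", function(object) standardGeneric("validBins"))
#' @rdname accessors
#' @export
setMethod("validBins", "PowerSeries", function(object) object@valid)

#' @rdname accessors
#' @export
setGeneric("acfMatrix", function(object) standardGeneric("acfMatrix"))
#' @rdname accessors
#' @export
setMethod("acfMatrix", "AcfSet", function(object) object@acfs)

#' @rdname accessors
#' @export
setGeneric("tcSeconds", function(object) standardGeneric("tcSeconds"))
#' @rdname accessors
#' @export
setMethod("tcSeconds", "TcValue", function(object) object@tc)

#' @rdname accessors
#' @export
setGeneric("isCapped", function(object) standardGeneric("isCapped"))
#' @rdname accessors
#' @export
setMethod("isCapped", "TcValue", function(object) object@capped)

#' @rdname accessors
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))
#' @rdname accessors
#' @export
setMethod("pValue", "TestResult", function(object) object@pValue)

#' @rdname accessors
#' @export
setGeneric("relativeEffect", function(object) standardGeneric("relativeEffect"))
#' @rdname accessors
#' @export
setMethod("relativeEffect", "TestResult", function(object) object@relativeEffect)
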