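#' @rdname montage-accessors
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' @rdname montage-accessors
#' @export
setGeneric("channelPositions", function(x) standardGeneric("channelPositions"))

#' @rdname montage-accessors
#' @export
setGeneric("channelGroups", function(x) standardGeneric("channelGroups"))

#' @rdname epochset-accessors
#' @export
setGeneric("epochData", function(x) standardGeneric("epochData"))

#' @rdname epochset-accessors
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' @rdname epochset-accessors
#' @export
setGeneric("epochTime", function(x) standardGeneric("epochTime"))

#' @rdname epochset-accessors
#' @export
setGeneric("targetTime", function(x) standardGeneric("targetTime"))

#' @rdname epochset-accessors
#' @export
setGeneric("trialInfo", function(x) standardGeneric("trialInfo"))

#' @rdname epochset-accessors
#' @export
setGeneric("montage", function(x) standardGeneric("montage"))

#' @rdname epochset-accessors
#' @export
setGeneric("epochUnits", function(x) standardGeneric("epochUnits"))

#' @rdname epochset-accessors
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' @rdname tfr-accessors
#' @export
setGeneric("tfrPower", function(x) standardGeneric("tfrPower"))

#' @rdname tfr-accessors
#' @export
setGeneric("tfrFrequencies", function(x) standardGeneric("tfrFrequencies"))

#' @rdname tfr-accessors
#' @export
setGeneric("tfrTime", function(x) standardGeneric("tfrTime"))

#' @rdname cluster-accessors
#' @export
setGeneric("clusters", function(x) standardGeneric("clusters"))

#' @rdname cluster-accessors
#' @export
setGeneric("nullSizes", function(x) standardGeneric("nullSizes"))
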