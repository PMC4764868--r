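#' @rdname TimeSeriesVolume-class
#' @param x a TimeSeriesVolume.
#' @export
setGeneric("nTimepoints", function(x) standardGeneric("nTimepoints"))

#' @rdname TimeSeriesVolume-class
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname TimeSeriesVolume-class
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' @rdname TimeSeriesVolume-class
#' @export
setGeneric("timepointsMin", function(x) standardGeneric("timepointsMin"))

#' @rdname TimeSeriesVolume-class
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname TimeSeriesVolume-class
#' @param timepoint timepoint index (1-based).
#' @param channel channel index or name.
#' @export
setGeneric("getVolume",
           function(x, timepoint, channel) standardGeneric("getVolume"))

#' @rdname TimeSeriesVolume-class
#' @export
setGeneric("validMask", function(x, timepoint) standardGeneric("validMask"))

#' @rdname SyntheticSeries-class
#' @param x a SyntheticSeries.
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname SyntheticSeries-class
#' @export
setGeneric("appliedDrift", function(x) standardGeneric("appliedDrift"))

#' @rdname SyntheticSeries-class
#' @export
setGeneric("imageSeries", function(x) standardGeneric("imageSeries"))

#' @rdname SpikeTrialSet-class
#' @param x a SpikeTrialSet.
#' @export
setGeneric("spikeTrials", function(x) standardGeneric("spikeTrials"))

#' @rdname SpikeTrialSet-class
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))
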