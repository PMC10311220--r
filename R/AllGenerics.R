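#' Number of spikes in a train
#' @param x a [SpikeTrain-class].
#' @return integer spike count.
#' @export
setGeneric("nSpikes", function(x) standardGeneric("nSpikes"))

#' Spike times accessor
#' @param x a [SpikeTrain-class].
#' @return numeric vector of spike times in seconds.
#' @export
setGeneric("spikeTimes", function(x) standardGeneric("spikeTimes"))

#' Recording duration accessor
#' @param x a [SpikeTrain-class] or [VoltageTrace-class].
#' @return duration in seconds.
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))

#' Electrode label accessor
#' @param x a [SpikeTrain-class] or [VoltageTrace-class].
#' @return single character electrode label.
#' @export
setGeneric("electrodeId", function(x) standardGeneric("electrodeId"))

#' Sampling rate accessor
#' @param x a [VoltageTrace-class].
#' @return sampling rate in Hz.
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' Voltage samples accessor
#' @param x a [VoltageTrace-class].
#' @return numeric vector of samples in microvolts.
#' @export
setGeneric("voltageSamples", function(x) standardGeneric("voltageSamples"))

#' Channel accessors for an image pair
#' @param x an [ImagePair-class].
#' @return numeric intensity matrix.
#' @export
setGeneric("channelA", function(x) standardGeneric("channelA"))

#' @rdname channelA
#' @export
setGeneric("channelB", function(x) standardGeneric("channelB"))

#' Arbor node table accessor
#' @param x an [Arbor-class].
#' @return the SWC-style node data.frame.
#' @export
setGeneric("arborNodes", function(x) standardGeneric("arborNodes"))

#' Soma node id accessor
#' @param x an [Arbor-class].
#' @return the root (soma) node id.
#' @export
setGeneric("somaId", function(x) standardGeneric("somaId"))
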