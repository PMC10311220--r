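#' @describeIn SpikeTrain-class number of spikes.
#' @param x object.
#' @export
setMethod("nSpikes", "SpikeTrain", function(x) length(x@times))

#' @describeIn SpikeTrain-class spike times in seconds.
#' @export
setMethod("spikeTimes", "SpikeTrain", function(x) x@times)

#' @describeIn SpikeTrain-class recording duration in seconds.
#' @export
setMethod("duration", "SpikeTrain", function(x) x@duration)

#' @describeIn SpikeTrain-class electrode label.
#' @export
setMethod("electrodeId", "SpikeTrain", function(x) x@electrodeId)

#' @describeIn VoltageTrace-class trace duration in seconds
#'   (samples / sampling rate).
#' @param x object.
#' @export
setMethod("duration", "VoltageTrace",
          function(x) length(x@samples) / x@samplingRate)

#' @describeIn VoltageTrace-class electrode label.
#' @export
setMethod("electrodeId", "VoltageTrace", function(x) x@electrodeId)

#' @describeIn VoltageTrace-class sampling rate in Hz.
#' @export
setMethod("samplingRate", "VoltageTrace", function(x) x@samplingRate)

#' @describeIn VoltageTrace-class voltage samples in microvolts.
#' @export
setMethod("voltageSamples", "VoltageTrace", function(x) x@samples)

#' @describeIn ImagePair-class first channel intensities.
#' @param x object.
#' @export
setMethod("channelA", "ImagePair", function(x) x@channelA)

#' @describeIn ImagePair-class second channel intensities.
#' @export
setMethod("channelB", "ImagePair", function(x) x@channelB)

#' @describeIn Arbor-class SWC node table.
#' @param x object.
#' @export
setMethod("arborNodes", "Arbor", function(x) x@nodes)

#' @describeIn Arbor-class root (soma) node id.
#' @export
setMethod("somaId", "Arbor", function(x) x@somaId)

setMethod("show", "SpikeTrain", function(object) {
  cat("SpikeTrain on electrode", object@electrodeId, "\n")
  cat(" ", length(object@times), "spikes over", object@duration, "s")
  if (length(object@times)) {
    cat(sprintf(" (%.2f spikes/min)",
                length(object@times) / (object@duration / 60)))
  }
  cat("\n")
})

setMethod("show", "VoltageTrace", function(object) {
  cat("VoltageTrace on electrode", object@electrodeId, "\n")
  cat(sprintf("  %d samples at %g Hz (%.3f s), range [%.2f, %.2f] uV\n",
              length(object@samples), object@samplingRate,
              length(object@samples) / object@samplingRate,
              min(object@samples), max(object@samples)))
})

setMethod("show", "ImagePair", function(object) {
  d <- dim(object@channelA)
  cat(sprintf("ImagePair %d x %d pixels", d[1], d[2]))
  if (!is.na(object@pixelSize)) cat(sprintf(" (%g um/px)", object@pixelSize))
  cat("\n")
})

setMethod("show", "Arbor", function(object) {
  cat(sprintf("Arbor with %d nodes, soma id %g\n",
              nrow(object@nodes), object@somaId))
})
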