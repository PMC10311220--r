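#' @import methods
NULL

#' SpikeTrain: sorted spike times from one electrode
#'
#' Container for the spike times detected (or simulated) on a single
#' electrode over a recording of known duration. Times are seconds from
#' recording onset, strictly increasing, within \code{[0, duration)}.
#' Amplitudes (microvolts, at the spike extremum) are optional; when present
#' there is one per spike.
#'
#' @slot electrodeId single character label.
#' @slot times numeric vector of spike times in seconds, strictly increasing.
#' @slot duration recording duration in seconds (> 0).
#' @slot amplitudes numeric vector of spike amplitudes in microvolts;
#'   either length 0 or one per spike.
#'
#' @seealso [SpikeTrain()] constructor, [detectSpikes()], [detectBursts()]
#' @exportClass SpikeTrain
setClass("SpikeTrain",
  representation(
    electrodeId = "character",
    times = "numeric",
    duration = "numeric",
    amplitudes = "numeric"
  ),
  prototype(
    electrodeId = "E1", times = numeric(0), duration = 1, amplitudes = numeric(0)
  )
)

setValidity("SpikeTrain", function(object) {
  msg <- character(0)
  if (length(object@electrodeId) != 1L) {
    msg <- c(msg, "electrodeId must be a single label")
  }
  if (length(object@duration) != 1L || !is.finite(object@duration) ||
      object@duration <= 0) {
    msg <- c(msg, "duration must be a single positive finite number")
  }
  t <- object@times
  if (length(t)) {
    if (any(!is.finite(t))) msg <- c(msg, "spike times must be finite")
    else {
      if (is.unsorted(t, strictly = TRUE)) {
        msg <- c(msg, "spike times must be strictly increasing")
      }
      if (min(t) < 0 || max(t) >= object@duration) {
        msg <- c(msg, "spike times must lie in [0, duration)")
      }
    }
  }
  if (length(object@amplitudes) &&
      length(object@amplitudes) != length(t)) {
    msg <- c(msg, "amplitudes must be empty or one per spike")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SpikeTrain
#'
#' @param times numeric vector of spike times (seconds), strictly increasing.
#' @param duration recording duration in seconds.
#' @param electrodeId electrode label.
#' @param amplitudes optional spike amplitudes (microvolts), one per spike.
#' @return A [SpikeTrain-class] object.
#' @examples
#' st <- SpikeTrain(c(0.1, 0.2, 0.5), duration = 60)
#' nSpikes(st)
#' @export
SpikeTrain <- function(times, duration, electrodeId = "E1",
                       amplitudes = numeric(0)) {
  new("SpikeTrain",
      electrodeId = as.character(electrodeId),
      times = as.numeric(times), duration = as.numeric(duration),
      amplitudes = as.numeric(amplitudes))
}

#' VoltageTrace: a continuous extracellular voltage recording
#'
#' Uniformly sampled extracellular voltage from one electrode, in microvolts.
#'
#' @slot samples numeric vector of voltage samples (microvolts), all finite.
#' @slot samplingRate sampling frequency in Hz (> 0).
#' @slot electrodeId single character label.
#'
#' @seealso [VoltageTrace()], [bandpassFilter()], [detectSpikes()]
#' @exportClass VoltageTrace
setClass("VoltageTrace",
  representation(
    samples = "numeric",
    samplingRate = "numeric",
    electrodeId = "character"
  ),
  prototype(samples = 0, samplingRate = 12500, electrodeId = "E1")
)

setValidity("VoltageTrace", function(object) {
  msg <- character(0)
  if (length(object@samplingRate) != 1L || !is.finite(object@samplingRate) ||
      object@samplingRate <= 0) {
    msg <- c(msg, "samplingRate must be a single positive number (Hz)")
  }
  if (length(object@samples) < 1L) msg <- c(msg, "trace must have >= 1 sample")
  if (any(!is.finite(object@samples))) {
    msg <- c(msg, "all samples must be finite")
  }
  if (length(object@electrodeId) != 1L) {
    msg <- c(msg, "electrodeId must be a single label")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a VoltageTrace
#'
#' @param samples voltage samples in microvolts.
#' @param samplingRate sampling rate in Hz.
#' @param electrodeId electrode label.
#' @return A [VoltageTrace-class] object.
#' @export
VoltageTrace <- function(samples, samplingRate, electrodeId = "E1") {
  new("VoltageTrace", samples = as.numeric(samples),
      samplingRate = as.numeric(samplingRate),
      electrodeId = as.character(electrodeId))
}

#' ImagePair: two aligned single-channel intensity images
#'
#' Two fluorescence channels of the same field (e.g. axonal Tuj1 and
#' somatodendritic MAP2), stored as non-negative numeric matrices of
#' identical shape.
#'
#' @slot channelA,channelB numeric matrices, same dimensions, finite and >= 0.
#' @slot pixelSize physical pixel size in micrometres per pixel (NA if unknown).
#'
#' @seealso [ImagePair()], [colocalize()], [manders()]
#' @exportClass ImagePair
setClass("ImagePair",
  representation(
    channelA = "matrix",
    channelB = "matrix",
    pixelSize = "numeric"
  ),
  prototype(channelA = matrix(0, 1, 1), channelB = matrix(0, 1, 1),
            pixelSize = NA_real_)
)

setValidity("ImagePair", function(object) {
  msg <- character(0)
  if (!identical(dim(object@channelA), dim(object@channelB))) {
    msg <- c(msg, "channelA and channelB must have identical dimensions")
  }
  for (nm in c("channelA", "channelB")) {
    ch <- slot(object, nm)
    if (!is.numeric(ch)) msg <- c(msg, paste(nm, "must be numeric"))
    else if (any(!is.finite(ch)) || any(ch < 0)) {
      msg <- c(msg, paste(nm, "intensities must be finite and >= 0"))
    }
  }
  if (length(object@pixelSize) != 1L) {
    msg <- c(msg, "pixelSize must be a single number (or NA)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an ImagePair
#'
#' @param channelA,channelB numeric intensity matrices of identical shape.
#' @param pixelSize micrometres per pixel; NA when unknown.
#' @return An [ImagePair-class] object.
#' @export
ImagePair <- function(channelA, channelB, pixelSize = NA_real_) {
  new("ImagePair", channelA = channelA, channelB = channelB,
      pixelSize = as.numeric(pixelSize))
}

#' Arbor: a rooted tree tracing of a cell's processes
#'
#' A traced arbor with SWC semantics: a table of nodes (id, type, x, y, z,
#' radius, parent) forming a single tree rooted at the soma node. Coordinates
#' are micrometres. \code{parent = -1} marks the root.
#'
#' @slot nodes data.frame with columns \code{id}, \code{type}, \code{x},
#'   \code{y}, \code{z}, \code{radius}, \code{parent}.
#' @slot somaId id of the soma (root) node.
#'
#' @seealso [Arbor()], [readSWC()], [shollProfile()], [branchMorphometrics()]
#' @exportClass Arbor
setClass("Arbor",
  representation(nodes = "data.frame", somaId = "numeric"),
  prototype(
    nodes = data.frame(id = 1, type = 1, x = 0, y = 0, z = 0,
                       radius = 1, parent = -1),
    somaId = 1
  )
)

setValidity("Arbor", function(object) {
  nd <- object@nodes
  req <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!all(req %in% names(nd))) {
    return(paste("nodes must have columns:", paste(req, collapse = ", ")))
  }
  msg <- character(0)
  if (anyDuplicated(nd$id)) msg <- c(msg, "node ids must be unique")
  roots <- nd$id[nd$parent == -1]
  if (length(roots) != 1L) {
    msg <- c(msg, "arbor must have exactly one root (parent = -1)")
  } else if (length(object@somaId) != 1L || object@somaId != roots) {
    msg <- c(msg, "somaId must be the single root node")
  }
  nonroot <- nd$parent[nd$parent != -1]
  if (!all(nonroot %in% nd$id)) {
    msg <- c(msg, "every parent id must resolve to a node")
  }
  if (any(!is.finite(as.matrix(nd[, c("x", "y", "z")])))) {
    msg <- c(msg, "coordinates must be finite")
  }
  # acyclicity: walking parents from every node must reach the root
  if (!length(msg)) {
    parent_of <- stats::setNames(nd$parent, nd$id)
    n <- nrow(nd)
    for (v in nd$id) {
      steps <- 0L
      while (v != -1) {
        v <- parent_of[[as.character(v)]]
        steps <- steps + 1L
        if (steps > n) return("nodes must not form a cycle")
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct an Arbor
#'
#' @param nodes data.frame with SWC columns
#'   (\code{id,type,x,y,z,radius,parent}); \code{parent = -1} for the root.
#' @return An [Arbor-class] object rooted at the single \code{parent = -1} node.
#' @export
Arbor <- function(nodes) {
  nodes <- as.data.frame(nodes)
  soma <- nodes$id[nodes$parent == -1]
  new("Arbor", nodes = nodes, somaId = as.numeric(soma[1]))
}
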