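## Parameter blocks: validated plain lists. Defaults are the recording and
## analysis settings of the study design this package supports (200-3000 Hz
## band, 6 x RMS threshold, 100 ms ISI exclusion, 5-spike / 100 ms / 250 ms
## burst rule, 25-pixel rolling ball, top 10% TOS, 5 um junction filter,
## 50-200 / 200-400 / 400-600 um zones).

stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' Spike detection parameters
#'
#' Settings for [bandpassFilter()] and [detectSpikes()]: the passband of the
#' zero-phase Butterworth filter, the threshold multiplier applied to the RMS
#' of the filtered signal, the crossing polarity, and a dead time forbidding
#' two detections within one refractory-scale window.
#'
#' @param bandLow,bandHigh passband edges in Hz (defaults 200 and 3000).
#' @param thresholdMultiplier threshold = multiplier x RMS (default 6).
#' @param polarity which threshold crossings count: `"negative"` (default),
#'   `"positive"` or `"both"`.
#' @param deadTime minimum separation between detected spikes, seconds
#'   (default 0.001).
#' @param robustNoise if TRUE estimate the noise level by the
#'   median-absolute-deviation instead of the RMS (useful for very bursty
#'   traces where spikes inflate the RMS; default FALSE keeps the plain
#'   RMS rule).
#' @return a validated list of class `"SpikeDetectionParams"`.
#' @export
spikeDetectionParams <- function(bandLow = 200, bandHigh = 3000,
                                 thresholdMultiplier = 6,
                                 polarity = c("negative", "positive", "both"),
                                 deadTime = 0.001, robustNoise = FALSE) {
  polarity <- match.arg(polarity)
  if (!(bandLow > 0 && bandLow < bandHigh)) {
    stopf("need 0 < bandLow < bandHigh (got %g, %g)", bandLow, bandHigh)
  }
  if (thresholdMultiplier <= 0) stopf("thresholdMultiplier must be > 0")
  if (deadTime < 0) stopf("deadTime must be >= 0")
  structure(list(bandLow = bandLow, bandHigh = bandHigh,
                 thresholdMultiplier = thresholdMultiplier,
                 polarity = polarity, deadTime = deadTime,
                 robustNoise = robustNoise),
            class = "SpikeDetectionParams")
}

#' Firing-rate parameters
#'
#' @param isiExclusion interspike intervals greater than this (seconds) are
#'   excluded from the mean ISI (default 0.1, i.e. 100 ms).
#' @param activeMinSpikes an electrode is "active" when it has at least this
#'   many spikes over the recording (default 2, i.e. more than one spike).
#' @return a validated list of class `"RateParams"`.
#' @export
rateParams <- function(isiExclusion = 0.1, activeMinSpikes = 2) {
  if (isiExclusion <= 0) stopf("isiExclusion must be > 0")
  if (activeMinSpikes < 1) stopf("activeMinSpikes must be >= 1")
  structure(list(isiExclusion = isiExclusion,
                 activeMinSpikes = as.integer(activeMinSpikes)),
            class = "RateParams")
}

#' Burst detection parameters
#'
#' The ISI-based burst rule: a burst needs at least `minSpikes` spikes, is
#' initiated by an ISI of at most `isiInit` and continued by ISIs of at most
#' `isiContinue`.
#'
#' @param minSpikes minimum spikes per burst (default 5).
#' @param isiInit maximum first ISI of a burst, seconds (default 0.1).
#' @param isiContinue maximum ISI sustaining a burst, seconds (default 0.25).
#' @return a validated list of class `"BurstParams"`.
#' @export
burstParams <- function(minSpikes = 5, isiInit = 0.1, isiContinue = 0.25) {
  if (minSpikes < 2) stopf("minSpikes must be >= 2")
  if (!(isiInit > 0 && isiInit <= isiContinue)) {
    stopf("need 0 < isiInit <= isiContinue (got %g, %g)", isiInit, isiContinue)
  }
  structure(list(minSpikes = as.integer(minSpikes), isiInit = isiInit,
                 isiContinue = isiContinue),
            class = "BurstParams")
}

#' Colocalization parameters
#'
#' @param ballDiameter rolling-ball diameter in pixels for background
#'   subtraction (default 25).
#' @param topFraction fraction of highest-intensity pixels selected per
#'   channel for the threshold overlap score (default 0.10).
#' @param maskMethod `"otsu"` (per-channel Otsu threshold) or `"fixed"`.
#' @param fixedThresholdA,fixedThresholdB fixed signal thresholds (strict
#'   `>` comparison) when `maskMethod = "fixed"`.
#' @return a validated list of class `"ColocParams"`.
#' @export
colocParams <- function(ballDiameter = 25, topFraction = 0.10,
                        maskMethod = c("otsu", "fixed"),
                        fixedThresholdA = NULL, fixedThresholdB = NULL) {
  maskMethod <- match.arg(maskMethod)
  if (ballDiameter < 3) stopf("ballDiameter must be >= 3 pixels")
  if (!(topFraction > 0 && topFraction <= 1)) {
    stopf("topFraction must be in (0, 1]")
  }
  if (maskMethod == "fixed" &&
      (is.null(fixedThresholdA) || is.null(fixedThresholdB))) {
    stopf("maskMethod 'fixed' requires fixedThresholdA and fixedThresholdB")
  }
  structure(list(ballDiameter = ballDiameter, topFraction = topFraction,
                 maskMethod = maskMethod,
                 fixedThresholdA = fixedThresholdA,
                 fixedThresholdB = fixedThresholdB),
            class = "ColocParams")
}

#' Sholl analysis parameters
#'
#' @param step radial step between concentric circles, micrometres
#'   (default 5).
#' @param rMax largest radius; defaults to the farthest node distance.
#' @return a validated list of class `"ShollParams"`.
#' @export
shollParams <- function(step = 5, rMax = NULL) {
  if (step <= 0) stopf("step must be > 0")
  if (!is.null(rMax) && rMax < step) stopf("rMax must be >= step")
  structure(list(step = step, rMax = rMax), class = "ShollParams")
}

#' Branch morphometry parameters
#'
#' @param minJunctionBranch side processes shorter than this (micrometres)
#'   do not count as junctions (default 5).
#' @param minMainBranch junction-free processes from the soma shorter than
#'   this are not counted as main branches (default 10).
#' @return a validated list of class `"MorphometryParams"`.
#' @export
morphometryParams <- function(minJunctionBranch = 5, minMainBranch = 10) {
  if (minJunctionBranch <= 0 || minMainBranch <= 0) {
    stopf("both length floors must be > 0")
  }
  structure(list(minJunctionBranch = minJunctionBranch,
                 minMainBranch = minMainBranch),
            class = "MorphometryParams")
}

#' Zone specification around a circular aggregate
#'
#' Distance bands measured from the aggregate *perimeter* (not its centre):
#' a cell at distance d from the centre falls in band (inner, outer] when
#' `inner <= d - radius < outer`.
#'
#' @param center aggregate centre, `c(x, y)` in micrometres.
#' @param radius aggregate radius in micrometres.
#' @param bands list of `c(inner, outer)` distances from the perimeter in
#'   micrometres; default the three zones 50-200, 200-400 and 400-600.
#' @return a validated list of class `"ZoneSpec"`.
#' @export
zoneSpec <- function(center = c(0, 0), radius,
                     bands = list(c(50, 200), c(200, 400), c(400, 600))) {
  if (radius <= 0) stopf("radius must be > 0")
  if (length(center) != 2L) stopf("center must be c(x, y)")
  b <- do.call(rbind, bands)
  if (any(b[, 1] >= b[, 2])) stopf("each band needs inner < outer")
  if (nrow(b) > 1 && any(b[-1, 1] < b[-nrow(b), 2])) {
    stopf("bands must be non-overlapping and increasing")
  }
  structure(list(center = as.numeric(center), radius = radius,
                 bands = lapply(bands, as.numeric)),
            class = "ZoneSpec")
}
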