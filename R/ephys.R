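#' Zero-phase bandpass filter of an extracellular trace
#'
#' Applies a 4th-order Butterworth bandpass (default 200-3000 Hz) forward and
#' backward ([signal::filtfilt()]) so the filtered trace has zero phase
#' distortion and spike times are not shifted.
#'
#' @param trace a [VoltageTrace-class].
#' @param params a [spikeDetectionParams()] block (the passband edges are
#'   used).
#' @param order Butterworth order (default 4).
#' @return a [VoltageTrace-class] of the same length and sampling rate.
#' @examples
#' tr <- VoltageTrace(sin(2 * pi * 1000 * (0:12499) / 12500), 12500)
#' f <- bandpassFilter(tr)
#' @export
bandpassFilter <- function(trace, params = spikeDetectionParams(), order = 4) {
  fs <- samplingRate(trace)
  nyq <- fs / 2
  if (params$bandHigh >= nyq) {
    stopf("bandHigh (%g Hz) must be below the Nyquist frequency (%g Hz)",
          params$bandHigh, nyq)
  }
  bf <- signal::butter(order, c(params$bandLow, params$bandHigh) / nyq,
                       type = "pass")
  out <- signal::filtfilt(bf, voltageSamples(trace))
  VoltageTrace(out, fs, electrodeId(trace))
}

## Noise level of a filtered (zero-mean) trace. Default: RMS, so that
## threshold = k * RMS implements the "k SD from the RMS" rule (RMS == SD for
## a zero-mean signal). Robust alternative: MAD-based SD estimate, which
## bursty traces do not inflate.
noiseLevel <- function(x, robust = FALSE) {
  if (robust) stats::mad(x, center = 0) else sqrt(mean(x^2))
}

#' Detect spikes by threshold crossing
#'
#' Implements RMS-multiple thresholding: the threshold is
#' `thresholdMultiplier` times the noise level of the (bandpass-filtered)
#' trace, where the noise level is the RMS of the filtered signal (equal to
#' its SD for the zero-mean output of the bandpass). Each excursion beyond
#' the threshold on the configured polarity yields one spike, timed at the
#' sample of the excursion's extremum; successive spikes are at least
#' `deadTime` apart (larger excursion wins).
#'
#' @param trace a [VoltageTrace-class].
#' @param params a [spikeDetectionParams()] block.
#' @param filter if TRUE (default) bandpass-filter the trace first; set FALSE
#'   when passing an already-filtered trace.
#' @return a [SpikeTrain-class] with per-spike amplitudes (microvolts at the
#'   extremum).
#' @examples
#' sim <- genSpikeTrain(spikeTrainSpec(nBursts = 2, spikesPerBurst = 6,
#'                                     duration = 10))
#' v <- genVoltageTrace(spikeTimes(sim$train),
#'                      voltageSpec(duration = 10, samplingRate = 12500))
#' st <- detectSpikes(v$trace)
#' @export
detectSpikes <- function(trace, params = spikeDetectionParams(),
                         filter = TRUE) {
  if (any(!is.finite(voltageSamples(trace)))) {
    stopf("trace contains non-finite samples")
  }
  filt <- if (filter) bandpassFilter(trace, params) else trace
  x <- voltageSamples(filt)
  fs <- samplingRate(filt)
  thr <- params$thresholdMultiplier * noiseLevel(x, params$robustNoise)

  over <- switch(params$polarity,
                 negative = x < -thr,
                 positive = x > thr,
                 both = abs(x) > thr)
  if (thr == 0) over <- rep(FALSE, length(x))  # strict crossing of zero
  if (!any(over)) {
    return(SpikeTrain(numeric(0), duration(trace), electrodeId(trace)))
  }

  # contiguous supra-threshold excursions
  r <- rle(over)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  starts <- starts[keep]; ends <- ends[keep]

  peak_idx <- integer(length(starts))
  peak_amp <- numeric(length(starts))
  for (k in seq_along(starts)) {
    seg <- x[starts[k]:ends[k]]
    j <- which.max(abs(seg))
    peak_idx[k] <- starts[k] + j - 1L
    peak_amp[k] <- seg[j]
  }

  # enforce dead time: keep the larger excursion of any too-close pair
  if (params$deadTime > 0 && length(peak_idx) > 1L) {
    min_gap <- params$deadTime * fs
    keep_i <- rep(TRUE, length(peak_idx))
    last <- 1L
    for (k in 2:length(peak_idx)) {
      if (peak_idx[k] - peak_idx[last] < min_gap) {
        if (abs(peak_amp[k]) > abs(peak_amp[last])) {
          keep_i[last] <- FALSE; last <- k
        } else keep_i[k] <- FALSE
      } else last <- k
    }
    peak_idx <- peak_idx[keep_i]; peak_amp <- peak_amp[keep_i]
  }

  SpikeTrain((peak_idx - 1L) / fs, duration(trace), electrodeId(trace),
             amplitudes = peak_amp)
}

#' Per-electrode firing-rate metrics
#'
#' Computes the mean interspike interval after excluding ISIs greater than
#' `isiExclusion` (default 100 ms), the mean firing frequency as the inverse
#' of that mean ISI, spikes per minute, the mean spike amplitude, and the
#' active-electrode flag (more than one spike over the recording, by
#' default).
#'
#' @param train a [SpikeTrain-class].
#' @param params a [rateParams()] block.
#' @return a list of class `"ElectrodeRateMetrics"` with fields
#'   `spikesPerMinute`, `meanISI` (s; NA when no ISI passes the exclusion),
#'   `meanFiringRate` (Hz; NA likewise), `meanAmplitude` (uV; NA when the
#'   train has no amplitudes), `isActive`, `nSpikes`.
#' @examples
#' st <- SpikeTrain(c(0, 0.05, 0.10, 0.30, 0.35), duration = 60)
#' rateMetrics(st)  # mean ISI 0.05 s, 20 Hz, 5 spikes/min
#' @export
rateMetrics <- function(train, params = rateParams()) {
  if (duration(train) <= 0) stopf("duration must be > 0")
  t <- spikeTimes(train)
  n <- length(t)
  isis <- if (n >= 2) diff(t) else numeric(0)
  kept <- isis[isis <= params$isiExclusion]
  mean_isi <- if (length(kept)) mean(kept) else NA_real_
  amp <- train@amplitudes
  structure(list(
    spikesPerMinute = n / (duration(train) / 60),
    meanISI = mean_isi,
    meanFiringRate = if (is.na(mean_isi)) NA_real_ else 1 / mean_isi,
    meanAmplitude = if (length(amp)) mean(amp) else NA_real_,
    isActive = n >= params$activeMinSpikes,
    nSpikes = n
  ), class = "ElectrodeRateMetrics")
}

#' Short-time power spectrogram
#'
#' Short-time Fourier power of a trace, restricted to frequencies up to
#' `fMax` (default 100 Hz), for visualizing the oscillatory (burst-rhythm)
#' dynamics of spontaneous activity.
#'
#' @param trace a [VoltageTrace-class] (any signal sampled in time; see
#'   [rateSignal()] for deriving a firing-rate signal from spike times).
#' @param window STFT window length in seconds.
#' @param overlapFraction fractional window overlap in `[0, 1)`.
#' @param fMax highest frequency bin retained, Hz (default 100).
#' @return a list of class `"Spectrogram"`: `power` (frequency x time, >= 0),
#'   `freq` (Hz), `time` (s, window centres).
#' @examples
#' fs <- 1000; tt <- (0:(10 * fs - 1)) / fs
#' sg <- spectrogram(VoltageTrace(sin(2 * pi * 10 * tt), fs), window = 1)
#' sg$freq[apply(sg$power, 2, which.max)]  # 10 Hz in every slice
#' @export
spectrogram <- function(trace, window = 1, overlapFraction = 0.5,
                        fMax = 100) {
  fs <- samplingRate(trace)
  if (fMax > fs / 2) {
    stopf("fMax (%g Hz) exceeds the Nyquist frequency (%g Hz)", fMax, fs / 2)
  }
  nwin <- round(window * fs)
  if (nwin < 8) stopf("window must cover at least 8 samples")
  if (overlapFraction < 0 || overlapFraction >= 1) {
    stopf("overlapFraction must be in [0, 1)")
  }
  sg <- signal::specgram(voltageSamples(trace), n = nwin, Fs = fs,
                         overlap = floor(nwin * overlapFraction))
  keep <- sg$f <= fMax
  structure(list(power = abs(sg$S[keep, , drop = FALSE])^2,
                 freq = sg$f[keep], time = sg$t),
            class = "Spectrogram")
}

#' Smoothed firing-rate signal from spike times
#'
#' Bins spike times at `fs` Hz and convolves with a Gaussian kernel, giving
#' the instantaneous-rate signal whose spectrogram exposes burst rhythms
#' (e.g. the low- vs high-frequency bands of short bursts vs a long dense
#' burst in a super-burst).
#'
#' @param train a [SpikeTrain-class].
#' @param fs output sampling rate in Hz (default 200).
#' @param smoothSd Gaussian smoothing SD in seconds (default 0.02).
#' @return a [VoltageTrace-class] holding the rate signal (spikes/s).
#' @export
rateSignal <- function(train, fs = 200, smoothSd = 0.02) {
  n <- max(1L, round(duration(train) * fs))
  counts <- tabulate(pmin(n, floor(spikeTimes(train) * fs) + 1L), nbins = n)
  half <- max(1L, ceiling(4 * smoothSd * fs))
  kt <- (-half:half) / fs
  kern <- exp(-0.5 * (kt / smoothSd)^2)
  kern <- kern / sum(kern)
  rate <- stats::filter(counts * fs, kern, sides = 2)
  rate[is.na(rate)] <- 0
  VoltageTrace(as.numeric(rate), fs, electrodeId(train))
}
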