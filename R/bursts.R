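#' Detect bursts by the ISI rule
#'
#' Scans interspike intervals in order. A candidate burst opens at spike i
#' when the ISI to the next spike is at most `isiInit`; it extends while
#' subsequent ISIs are at most `isiContinue`; it closes at the first ISI
#' above `isiContinue` (or at the end of the train). Candidates with fewer
#' than `minSpikes` spikes are discarded. Scanning resumes after the closing
#' gap, so no spike belongs to more than one burst.
#'
#' @param train a [SpikeTrain-class] (times sorted; enforced by the class).
#' @param params a [burstParams()] block (defaults: at least 5 spikes,
#'   100 ms to initiate, 250 ms to continue).
#' @return a data.frame of class `"BurstTable"`, one row per burst:
#'   `iStart`, `iEnd` (spike indices into the train), `tStart`, `tEnd`
#'   (seconds), `nSpikes`, `duration` (s). Zero rows when no bursts.
#' @examples
#' st <- SpikeTrain(c(0, 0.02, 0.04, 0.06, 0.08), duration = 1)
#' detectBursts(st)  # one 5-spike burst of duration 0.08 s
#' @export
detectBursts <- function(train, params = burstParams()) {
  t <- spikeTimes(train)
  if (is.unsorted(t, strictly = FALSE)) stopf("spike times must be sorted")
  n <- length(t)
  out <- list()
  i <- 1L
  while (i < n) {
    if (t[i + 1L] - t[i] <= params$isiInit) {
      j <- i + 1L
      while (j < n && t[j + 1L] - t[j] <= params$isiContinue) j <- j + 1L
      if (j - i + 1L >= params$minSpikes) {
        out[[length(out) + 1L]] <-
          c(iStart = i, iEnd = j, tStart = t[i], tEnd = t[j],
            nSpikes = j - i + 1L, duration = t[j] - t[i])
      }
      i <- j + 1L  # resume after the closing gap; no reopening
    } else {
      i <- i + 1L
    }
  }
  res <- if (length(out)) {
    as.data.frame(do.call(rbind, out))
  } else {
    data.frame(iStart = numeric(0), iEnd = numeric(0), tStart = numeric(0),
               tEnd = numeric(0), nSpikes = numeric(0), duration = numeric(0))
  }
  class(res) <- c("BurstTable", "data.frame")
  res
}

#' Burst-structure metrics
#'
#' Summarizes a train's detected bursts: bursts per minute, mean spikes per
#' burst, mean burst duration, mean interburst interval (gap from each
#' burst's end to the next burst's start), and burstiness — the ratio of
#' spikes within bursts to all spikes, which equals 1 when all spiking
#' occurs in bursts and 0 when none does.
#'
#' @param train the [SpikeTrain-class] the bursts came from; must contain at
#'   least one spike (burstiness is undefined on a silent electrode).
#' @param bursts the [detectBursts()] table for `train`.
#' @return a list of class `"BurstMetrics"`: `burstsPerMinute`,
#'   `meanSpikesPerBurst`, `meanBurstDuration` (s), `meanInterburstInterval`
#'   (s; NA with fewer than two bursts), `burstiness` in `[0, 1]`,
#'   `nBursts`, `nSpikesInBursts`, `nSpikes`.
#' @examples
#' st <- SpikeTrain(c(seq(0, 0.08, 0.02), 1, 2, 3, 4, 5), duration = 60)
#' burstMetrics(st, detectBursts(st))$burstiness  # 5 of 10 spikes -> 0.5
#' @export
burstMetrics <- function(train, bursts) {
  n_total <- nSpikes(train)
  if (n_total == 0L) stopf("burstiness is undefined on an empty train")
  nb <- nrow(bursts)
  in_bursts <- if (nb) sum(bursts$nSpikes) else 0
  ibi <- if (nb >= 2) {
    mean(bursts$tStart[-1] - bursts$tEnd[-nb])
  } else NA_real_
  structure(list(
    burstsPerMinute = nb / (duration(train) / 60),
    meanSpikesPerBurst = if (nb) mean(bursts$nSpikes) else NA_real_,
    meanBurstDuration = if (nb) mean(bursts$duration) else NA_real_,
    meanInterburstInterval = ibi,
    burstiness = in_bursts / n_total,
    nBursts = nb,
    nSpikesInBursts = in_bursts,
    nSpikes = n_total
  ), class = "BurstMetrics")
}

#' Raster plot of spike trains with burst shading
#'
#' @param trains a list of [SpikeTrain-class] objects (one row each).
#' @param params burst parameters used to shade detected bursts; NULL to
#'   skip burst detection.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the list of burst tables (NULL when `params` is NULL).
#' @export
plotRaster <- function(trains, params = burstParams(), ...) {
  nr <- length(trains)
  dur <- max(vapply(trains, duration, 0))
  graphics::plot(NA, xlim = c(0, dur), ylim = c(0.5, nr + 0.5),
                 xlab = "time (s)", ylab = "electrode", yaxt = "n", ...)
  graphics::axis(2, at = seq_len(nr),
                 labels = vapply(trains, electrodeId, ""))
  tabs <- vector("list", nr)
  for (k in seq_len(nr)) {
    if (!is.null(params)) {
      b <- detectBursts(trains[[k]], params)
      tabs[[k]] <- b
      if (nrow(b)) {
        graphics::rect(b$tStart, k - 0.4, b$tEnd, k + 0.4,
                       col = grDevices::adjustcolor("orange", 0.3),
                       border = NA)
      }
    }
    t <- spikeTimes(trains[[k]])
    if (length(t)) graphics::segments(t, k - 0.35, t, k + 0.35)
  }
  invisible(tabs)
}
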