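## Seeded evaluation that leaves the caller's RNG stream untouched, so every
## generator is a pure function of its spec (including the seed).
withSeed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Specification of a synthetic burst-structured spike train
#'
#' Describes a train of `nBursts` regular bursts (each `spikesPerBurst`
#' spikes at `intraBurstISI` spacing) separated by at least
#' `interBurstGap`, plus isolated noise spikes kept well clear of every
#' burst window so they can never join or seed a burst.
#'
#' @param nBursts number of bursts (>= 0).
#' @param spikesPerBurst spikes per burst (>= 1).
#' @param intraBurstISI within-burst interspike interval, seconds.
#' @param interBurstGap minimum gap between bursts, seconds (must exceed
#'   `intraBurstISI`).
#' @param nNoiseSpikes isolated spikes outside bursts (>= 0).
#' @param duration recording duration, seconds.
#' @param seed RNG seed.
#' @return a validated list of class `"SpikeTrainSpec"`.
#' @export
spikeTrainSpec <- function(nBursts = 10, spikesPerBurst = 8,
                           intraBurstISI = 0.03, interBurstGap = 2,
                           nNoiseSpikes = 0, duration = 60, seed = 1) {
  if (intraBurstISI <= 0) stopf("intraBurstISI must be > 0")
  if (interBurstGap <= intraBurstISI) {
    stopf("interBurstGap must exceed intraBurstISI")
  }
  if (spikesPerBurst < 1) stopf("spikesPerBurst must be >= 1")
  need <- nBursts * (spikesPerBurst - 1) * intraBurstISI +
    nBursts * interBurstGap
  if (duration < need) {
    stopf("duration %g s cannot fit %d bursts (need >= %g s)",
          duration, nBursts, need)
  }
  structure(list(nBursts = as.integer(nBursts),
                 spikesPerBurst = as.integer(spikesPerBurst),
                 intraBurstISI = intraBurstISI,
                 interBurstGap = interBurstGap,
                 nNoiseSpikes = as.integer(nNoiseSpikes),
                 duration = duration, seed = as.integer(seed)),
            class = "SpikeTrainSpec")
}

#' Generate a burst-structured spike train with ground truth
#'
#' Bursts are laid out left to right with seeded jitter while preserving at
#' least `interBurstGap` between consecutive burst windows. Noise spikes
#' are placed at least 0.3 s away from every burst window and from each
#' other (comfortably beyond the 0.25 s continuation limit), so with the
#' default burst rule the detector's burst set equals the constructed one.
#'
#' @param spec a [spikeTrainSpec()].
#' @return a list: `train` (a [SpikeTrain-class]) and `truth` — a list with
#'   `trueSpikeTimes`, `trueBurstWindows` (data.frame `tStart`, `tEnd`),
#'   `spikesPerBurst`, `nNoiseSpikes`.
#' @examples
#' sim <- genSpikeTrain(spikeTrainSpec(nBursts = 3, spikesPerBurst = 5,
#'                                     duration = 30))
#' nSpikes(sim$train)  # 15
#' @export
genSpikeTrain <- function(spec) {
  stopifnot(inherits(spec, "SpikeTrainSpec"))
  withSeed(spec$seed, function() {
    L <- (spec$spikesPerBurst - 1) * spec$intraBurstISI
    nb <- spec$nBursts
    times <- numeric(0)
    windows <- data.frame(tStart = numeric(0), tEnd = numeric(0))
    if (nb > 0) {
      slot_len <- L + spec$interBurstGap
      slack <- spec$duration - nb * slot_len
      jit <- sort(stats::runif(nb, 0, max(0, slack)))
      starts <- (seq_len(nb) - 1) * slot_len + jit
      for (s in starts) {
        times <- c(times, s + (0:(spec$spikesPerBurst - 1)) *
                     spec$intraBurstISI)
      }
      windows <- data.frame(tStart = starts, tEnd = starts + L)
    }
    margin <- 0.3
    noise <- numeric(0)
    if (spec$nNoiseSpikes > 0) {
      tries <- 0L
      while (length(noise) < spec$nNoiseSpikes) {
        tries <- tries + 1L
        if (tries > 10000L) {
          stopf("cannot place %d noise spikes clear of bursts",
                spec$nNoiseSpikes)
        }
        cand <- stats::runif(1, 0, spec$duration - 1e-9)
        ok <- TRUE
        if (nrow(windows)) {
          ok <- all(cand < windows$tStart - margin |
                      cand > windows$tEnd + margin)
        }
        if (ok && length(noise)) ok <- all(abs(cand - noise) > margin)
        if (ok) noise <- c(noise, cand)
      }
    }
    all_t <- sort(c(times, noise))
    train <- SpikeTrain(all_t, spec$duration)
    list(train = train,
         truth = list(trueSpikeTimes = all_t,
                      trueBurstWindows = windows,
                      spikesPerBurst = spec$spikesPerBurst,
                      nNoiseSpikes = spec$nNoiseSpikes))
  })
}

#' Benchmark spike times for detector evaluation
#'
#' A jittered regular grid of `n` spike times over `duration` seconds with
#' a guaranteed minimum separation, for recall/precision benchmarks of
#' [detectSpikes()] (burst structure is irrelevant there, only coverage
#' and separation).
#'
#' @param n number of spikes.
#' @param duration recording length, seconds.
#' @param minGap guaranteed minimum separation, seconds (default 5 ms).
#' @param seed RNG seed.
#' @return sorted numeric vector of `n` spike times.
#' @export
genBenchmarkTimes <- function(n = 100, duration = 10, minGap = 0.005,
                              seed = 1) {
  pitch <- (duration - 0.1) / n
  if (pitch <= minGap) stopf("cannot fit %d spikes %g s apart", n, minGap)
  withSeed(seed, function() {
    jit <- stats::runif(n, 0, pitch - minGap)
    0.05 + (seq_len(n) - 1) * pitch + jit
  })
}

#' Specification of a synthetic extracellular voltage trace
#'
#' @param samplingRate sampling rate, Hz (default 12500).
#' @param duration trace duration, seconds (default 600, a 10-minute
#'   recording).
#' @param noiseSigma SD of the additive Gaussian noise, microvolts.
#' @param spikeAmplitude signed peak amplitude of the rendered spike
#'   waveform, microvolts (default -60: negative-going extracellular
#'   spikes).
#' @param spikeWidth waveform width, seconds (default 1.2 ms); must span at
#'   least 4 samples.
#' @param seed RNG seed.
#' @return a validated list of class `"VoltageSpec"`.
#' @export
voltageSpec <- function(samplingRate = 12500, duration = 600,
                        noiseSigma = 5, spikeAmplitude = -60,
                        spikeWidth = 1.2e-3, seed = 1) {
  if (noiseSigma < 0) stopf("noiseSigma must be >= 0")
  if (spikeWidth * samplingRate < 4) {
    stopf("spikeWidth must span at least 4 samples")
  }
  if (samplingRate <= 2 * 3000) {
    stopf("samplingRate must exceed twice the upper filter band (6 kHz)")
  }
  structure(list(samplingRate = samplingRate, duration = duration,
                 noiseSigma = noiseSigma, spikeAmplitude = spikeAmplitude,
                 spikeWidth = spikeWidth, seed = as.integer(seed)),
            class = "VoltageSpec")
}

## biphasic waveform: dominant first lobe then an opposite lobe at half the
## amplitude, scaled so the extremum equals `amplitude` (signed)
spikeTemplate <- function(amplitude, width, fs) {
  tt <- seq(0, width, by = 1 / fs)
  s <- width / 8
  shape <- -exp(-0.5 * ((tt - 0.35 * width) / s)^2) +
    0.5 * exp(-0.5 * ((tt - 0.75 * width) / s)^2)
  shape <- shape / max(abs(shape))
  (-amplitude) * shape
}

#' Render spike times into a noisy voltage trace
#'
#' Each spike time receives a biphasic waveform whose extremum has the
#' requested signed peak amplitude and lands on the sample nearest the
#' spike time; i.i.d. Gaussian noise is added on top. The ground truth
#' carries the sample-snapped spike times actually rendered.
#'
#' @param spikeTimes spike times in seconds, all within `[0, duration)`.
#' @param spec a [voltageSpec()].
#' @return a list: `trace` (a [VoltageTrace-class]) and `truth` (a list
#'   with `trueSpikeTimes`).
#' @export
genVoltageTrace <- function(spikeTimes, spec) {
  stopifnot(inherits(spec, "VoltageSpec"))
  if (length(spikeTimes) &&
      (min(spikeTimes) < 0 || max(spikeTimes) >= spec$duration)) {
    stopf("spike times must lie in [0, duration)")
  }
  if (length(spikeTimes) && spec$spikeAmplitude == 0) {
    stopf("spikeAmplitude 0 with spikes present leaves no detectable truth")
  }
  withSeed(spec$seed, function() {
    fs <- spec$samplingRate
    n <- round(spec$duration * fs)
    x <- stats::rnorm(n, 0, spec$noiseSigma)
    snapped <- numeric(0)
    if (length(spikeTimes)) {
      tpl <- spikeTemplate(spec$spikeAmplitude, spec$spikeWidth, fs)
      i_ext <- which.max(abs(tpl))
      for (t in spikeTimes) {
        centre <- round(t * fs) + 1L
        lo <- centre - i_ext + 1L
        hi <- lo + length(tpl) - 1L
        src <- max(1L, lo):min(n, hi)
        if (!length(src)) next
        x[src] <- x[src] + tpl[src - lo + 1L]
        snapped <- c(snapped, (centre - 1L) / fs)
      }
    }
    list(trace = VoltageTrace(x, fs),
         truth = list(trueSpikeTimes = snapped))
  })
}

#' Specification of a synthetic two-channel image pair
#'
#' Foreground pixels are placed by seeded sampling without replacement, so
#' the number of pixels carrying both signals is an exact integer and the
#' Mander's coefficients of the noiseless pair are exact ratios.
#'
#' @param shape image dimensions, `c(rows, cols)` pixels.
#' @param nSignalA,nSignalB signal pixel counts per channel.
#' @param overlapFraction fraction of channel-A signal pixels that also
#'   carry channel-B signal; `nSignalA * overlapFraction` must be a whole
#'   number.
#' @param fgIntensity,bgIntensity foreground and background intensities
#'   (foreground must be brighter).
#' @param noiseSigma SD of additive Gaussian noise (clamped at 0 below).
#' @param seed RNG seed.
#' @return a validated list of class `"ImagePairSpec"`.
#' @export
imagePairSpec <- function(shape = c(64, 64), nSignalA = 100, nSignalB = 100,
                          overlapFraction = 0.5, fgIntensity = 200,
                          bgIntensity = 10, noiseSigma = 0, seed = 1) {
  N <- prod(shape)
  k <- nSignalA * overlapFraction
  if (abs(k - round(k)) > 1e-9) {
    stopf("nSignalA * overlapFraction must be an integer (got %g)", k)
  }
  k <- round(k)
  if (k > min(nSignalA, nSignalB)) {
    stopf("required overlap (%d) exceeds the smaller signal count", k)
  }
  if (nSignalA + nSignalB - k > N) stopf("signal counts exceed total pixels")
  if (fgIntensity <= bgIntensity) {
    stopf("fgIntensity must exceed bgIntensity")
  }
  if (overlapFraction < 0 || overlapFraction > 1) {
    stopf("overlapFraction must be in [0, 1]")
  }
  structure(list(shape = as.integer(shape), nSignalA = as.integer(nSignalA),
                 nSignalB = as.integer(nSignalB),
                 overlapFraction = overlapFraction, nOverlap = as.integer(k),
                 fgIntensity = fgIntensity, bgIntensity = bgIntensity,
                 noiseSigma = noiseSigma, seed = as.integer(seed)),
            class = "ImagePairSpec")
}

#' Generate a two-channel image pair with exact overlap ground truth
#'
#' @param spec an [imagePairSpec()].
#' @return a list: `pair` (an [ImagePair-class]), `maskA`, `maskB` (the
#'   true signal masks), and `truth` (a list with `trueM1`, `trueM2`,
#'   `nOverlap`).
#' @examples
#' sim <- genImagePair(imagePairSpec(nSignalA = 100, nSignalB = 200,
#'                                   overlapFraction = 0.25))
#' sim$truth  # M1 = 0.25, M2 = 0.125
#' @export
genImagePair <- function(spec) {
  stopifnot(inherits(spec, "ImagePairSpec"))
  withSeed(spec$seed, function() {
    N <- prod(spec$shape)
    k <- spec$nOverlap
    picked <- sample.int(N, spec$nSignalA + spec$nSignalB - k)
    both <- picked[seq_len(k)]
    onlyA <- picked[k + seq_len(spec$nSignalA - k)]
    onlyB <- picked[spec$nSignalA + seq_len(spec$nSignalB - k)]
    mk <- function(idx) {
      m <- matrix(FALSE, spec$shape[1], spec$shape[2])
      m[idx] <- TRUE
      m
    }
    maskA <- mk(c(both, onlyA))
    maskB <- mk(c(both, onlyB))
    render <- function(mask) {
      img <- matrix(spec$bgIntensity, spec$shape[1], spec$shape[2])
      img[mask] <- spec$fgIntensity
      if (spec$noiseSigma > 0) {
        img <- img + matrix(stats::rnorm(N, 0, spec$noiseSigma),
                            spec$shape[1], spec$shape[2])
        img[img < 0] <- 0
      }
      img
    }
    list(pair = ImagePair(render(maskA), render(maskB)),
         maskA = maskA, maskB = maskB,
         truth = list(trueM1 = k / spec$nSignalA,
                      trueM2 = k / spec$nSignalB,
                      nOverlap = k))
  })
}

#' Specification of a synthetic branching arbor
#'
#' Describes an arbor with `nMainBranches` trunks radiating from the soma,
#' each trunk made of `junctionsPerBranch + 1` segments of
#' `segmentLength` micrometres with one side branch (also
#' `segmentLength` long) at each internal trunk node. Segment directions
#' are jittered by up to `branchAngleSpread` degrees; path lengths are
#' unaffected, so the morphometric ground truth is constructive.
#' `stubLengths` optionally adds short side projections (attached at extra
#' mid-segment nodes of the first trunk) to exercise the 5 um junction
#' filter; stubs at least 5 um long count as junctions in the truth.
#'
#' @param nMainBranches number of trunks from the soma (>= 1).
#' @param junctionsPerBranch side branches per trunk (>= 0).
#' @param segmentLength segment length, micrometres (> 0; keep >= 5 so the
#'   junction filter is inert for the regular side branches).
#' @param branchAngleSpread direction jitter, degrees.
#' @param stubLengths optional extra side-projection lengths (um), each
#'   shorter than `segmentLength / 2`, at most one per trunk segment of
#'   the first branch.
#' @param seed RNG seed.
#' @return a validated list of class `"ArborSpec"`.
#' @export
arborSpec <- function(nMainBranches = 5, junctionsPerBranch = 2,
                      segmentLength = 20, branchAngleSpread = 15,
                      stubLengths = numeric(0), seed = 1) {
  if (nMainBranches < 1) stopf("nMainBranches must be >= 1")
  if (junctionsPerBranch < 0) stopf("junctionsPerBranch must be >= 0")
  if (segmentLength <= 0) stopf("segmentLength must be > 0")
  if (length(stubLengths)) {
    if (any(stubLengths <= 0) || any(stubLengths >= segmentLength / 2)) {
      stopf("stubLengths must be in (0, segmentLength / 2)")
    }
    if (length(stubLengths) > junctionsPerBranch + 1) {
      stopf("at most one stub per trunk segment of the first branch")
    }
  }
  structure(list(nMainBranches = as.integer(nMainBranches),
                 junctionsPerBranch = as.integer(junctionsPerBranch),
                 segmentLength = segmentLength,
                 branchAngleSpread = branchAngleSpread,
                 stubLengths = as.numeric(stubLengths),
                 seed = as.integer(seed)),
            class = "ArborSpec")
}

#' Generate a branching arbor with constructive morphometric ground truth
#'
#' The tree is planar (z = 0), rooted at a soma node at the origin. Ground
#' truth is computed during construction — never by the analysis code —
#' under the default 5 um junction filter and 10 um main-branch floor.
#'
#' @param spec an [arborSpec()].
#' @return a list: `arbor` (an [Arbor-class]) and `truth` (a list with
#'   `nMainBranches`, `longestMainBranch`, `totalProcessLength`,
#'   `nJunctions`).
#' @examples
#' sim <- genArbor(arborSpec(nMainBranches = 3, junctionsPerBranch = 2))
#' sim$truth$nJunctions  # 6
#' @export
genArbor <- function(spec) {
  stopifnot(inherits(spec, "ArborSpec"))
  withSeed(spec$seed, function() {
    sl <- spec$segmentLength
    nseg <- spec$junctionsPerBranch + 1L
    spread <- spec$branchAngleSpread * pi / 180
    nodes <- data.frame(id = 1, type = 1, x = 0, y = 0, z = 0,
                        radius = 2, parent = -1)
    nid <- 1L
    addNode <- function(x, y, parent, type = 5) {
      nid <<- nid + 1L
      nodes[nrow(nodes) + 1L, ] <<- list(nid, type, x, y, 0, 1, parent)
      nid
    }
    for (m in seq_len(spec$nMainBranches)) {
      theta0 <- 2 * pi * (m - 1) / spec$nMainBranches
      prev <- 1L
      px <- 0; py <- 0
      for (s in seq_len(nseg)) {
        th <- theta0 + stats::runif(1, -spread, spread)
        nx <- px + sl * cos(th); ny <- py + sl * sin(th)
        if (m == 1L && s <= length(spec$stubLengths)) {
          # split the segment to host a sub/super-threshold stub mid-way
          mx <- px + (nx - px) / 2; my <- py + (ny - py) / 2
          mid <- addNode(mx, my, prev)
          stl <- spec$stubLengths[s]
          sth <- th + pi / 2
          addNode(mx + stl * cos(sth), my + stl * sin(sth), mid)
          prev <- mid
        }
        cur <- addNode(nx, ny, prev)
        if (s < nseg) {
          # side branch at this internal trunk node
          sideth <- th + sample(c(-1, 1), 1) *
            (pi / 3 + stats::runif(1, -spread, spread))
          addNode(nx + sl * cos(sideth), ny + sl * sin(sideth), cur)
        }
        prev <- cur
        px <- nx; py <- ny
      }
    }
    # constructive truth under the default filters (5 um junction floor,
    # 10 um junction-free main-branch floor)
    side_q <- sl >= 5
    nj_first <- spec$junctionsPerBranch * side_q + sum(spec$stubLengths >= 5)
    nj_other <- spec$junctionsPerBranch * side_q
    q_first <- nj_first > 0 || nseg * sl >= 10
    q_other <- nj_other > 0 || nseg * sl >= 10
    n_main <- q_first + (spec$nMainBranches - 1L) * q_other
    truth <- list(
      nMainBranches = as.integer(n_main),
      longestMainBranch = if (n_main > 0) nseg * sl else 0,
      totalProcessLength = spec$nMainBranches *
        (nseg + spec$junctionsPerBranch) * sl + sum(spec$stubLengths),
      nJunctions = as.integer(nj_first +
                                (spec$nMainBranches - 1L) * nj_other)
    )
    list(arbor = Arbor(nodes), truth = truth)
  })
}
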