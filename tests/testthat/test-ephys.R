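fsine <- function(f, fs, dur = 1) {
  VoltageTrace(sin(2 * pi * f * (0:(dur * fs - 1)) / fs), fs)
}

# amplitude of a tone in a filtered trace, measured by FFT (edges trimmed)
toneAmplitude <- function(trace, f) {
  x <- voltageSamples(trace)
  n <- length(x)
  core <- x[floor(n / 4):floor(3 * n / 4)]
  sp <- abs(stats::fft(core)) / length(core) * 2
  freqs <- (seq_along(core) - 1) * samplingRate(trace) / length(core)
  max(sp[abs(freqs - f) < 2])
}

test_that("bandpass filter passes the band and rejects outside it", {
  fs <- 12500
  # DC is annihilated
  dc <- VoltageTrace(rep(3, fs), fs)
  out <- voltageSamples(bandpassFilter(dc))
  expect_lt(max(abs(out[1000:11000])), 1e-6 * 3)

  # 1 kHz inside the 200-3000 Hz band: gain within [0.9, 1]
  g <- toneAmplitude(bandpassFilter(fsine(1000, fs)), 1000)
  expect_gte(g, 0.9)
  expect_lte(g, 1.0)

  # 10 Hz well below the band: strongly attenuated
  g10 <- toneAmplitude(bandpassFilter(fsine(10, fs, dur = 2)), 10)
  expect_lt(g10, 0.05)

  # filter output preserves length and sampling rate
  f <- bandpassFilter(fsine(1000, fs))
  expect_length(voltageSamples(f), fs)
  expect_equal(samplingRate(f), fs)

  expect_error(bandpassFilter(fsine(100, 5000)), "Nyquist")
})

test_that("spike detection recovers ground truth and rejects noise", {
  # all-zero trace: threshold zero, strict crossing, no spikes
  z <- detectSpikes(VoltageTrace(rep(0, 12500), 12500))
  expect_equal(nSpikes(z), 0)

  expect_error(detectSpikes(VoltageTrace(c(0, NA, 0), 12500)),
               "(finite|NA)")

  # benchmark: 50 spikes at -60 uV over 5 uV noise
  tt <- genBenchmarkTimes(50, 10, seed = 21)
  v <- genVoltageTrace(tt, voltageSpec(duration = 10, noiseSigma = 5,
                                       spikeAmplitude = -60, seed = 21))
  st <- detectSpikes(v$trace)
  truth <- v$truth$trueSpikeTimes
  hits <- vapply(truth, function(t) min(abs(spikeTimes(st) - t)), 0)
  expect_gte(sum(hits <= 4e-4), 49)                       # recall
  fp <- vapply(spikeTimes(st), function(t) min(abs(truth - t)), 0)
  expect_equal(sum(fp > 4e-4), 0)                         # precision
})

test_that("sub-threshold signal adds no systematic detections", {
  fs <- 12500; dur <- 5
  set.seed(31)
  noise <- rnorm(dur * fs, 0, 5)
  sine <- 15 * sin(2 * pi * 1000 * (0:(dur * fs - 1)) / fs)  # 3 x sd
  n_noise <- nSpikes(detectSpikes(VoltageTrace(noise, fs)))
  n_with <- nSpikes(detectSpikes(VoltageTrace(noise + sine, fs)))
  expect_lte(n_with, n_noise + 2)
})

test_that("detection is scale-equivariant and phase-preserving", {
  tt <- genBenchmarkTimes(20, 5, seed = 22)
  v <- genVoltageTrace(tt, voltageSpec(duration = 5, noiseSigma = 5,
                                       spikeAmplitude = -60, seed = 22))
  st1 <- detectSpikes(v$trace)
  st2 <- detectSpikes(VoltageTrace(7.3 * voltageSamples(v$trace),
                                   samplingRate(v$trace)))
  expect_identical(spikeTimes(st1), spikeTimes(st2))

  # zero-phase: spike times on a filtered noiseless trace shift < 1 sample
  clean <- genVoltageTrace(tt, voltageSpec(duration = 5, noiseSigma = 0,
                                           spikeAmplitude = -60, seed = 1))
  raw <- detectSpikes(clean$trace, filter = FALSE)
  filt <- detectSpikes(clean$trace, filter = TRUE)
  expect_equal(nSpikes(raw), nSpikes(filt))
  expect_lt(max(abs(spikeTimes(raw) - spikeTimes(filt))),
            1 / samplingRate(clean$trace))
})

test_that("rate metrics follow the 100 ms ISI-exclusion rule", {
  st <- SpikeTrain(c(0, 0.05, 0.10, 0.30, 0.35), duration = 60)
  m <- rateMetrics(st)
  expect_equal(m$meanISI, 0.05)           # 200 ms ISI excluded
  expect_equal(m$meanFiringRate, 20)
  expect_equal(m$spikesPerMinute, 5)
  expect_true(m$isActive)

  # a single spike over the whole recording is not an active electrode
  lone <- rateMetrics(SpikeTrain(5, duration = 600))
  expect_false(lone$isActive)
  expect_equal(lone$spikesPerMinute, 0.1)

  # all ISIs above the exclusion: mean ISI undefined, count still reported
  sparse <- rateMetrics(SpikeTrain(c(0, 1, 2.5), duration = 60))
  expect_true(is.na(sparse$meanISI))
  expect_true(is.na(sparse$meanFiringRate))
  expect_equal(sparse$spikesPerMinute, 3)
})

test_that("spectrogram localizes tones and tracks epoch changes", {
  fs <- 1000
  t10 <- fsine(10, fs, dur = 10)
  sg <- spectrogram(t10, window = 1, overlapFraction = 0.5, fMax = 100)
  expect_true(all(sg$power >= 0))
  dom <- sg$freq[apply(sg$power, 2, which.max)]
  expect_true(all(abs(dom - 10) < 1))

  # 5 Hz epoch then 15 Hz epoch: the dominant bin switches
  x <- c(sin(2 * pi * 5 * (0:(5 * fs - 1)) / fs),
         sin(2 * pi * 15 * (0:(5 * fs - 1)) / fs))
  sg2 <- spectrogram(VoltageTrace(x, fs), window = 1, fMax = 50)
  dom2 <- sg2$freq[apply(sg2$power, 2, which.max)]
  expect_true(all(abs(dom2[sg2$time < 4] - 5) < 1))
  expect_true(all(abs(dom2[sg2$time > 6] - 15) < 1))

  # zero trace: all power zero
  sg0 <- spectrogram(VoltageTrace(rep(0, 5000), fs), window = 1)
  expect_true(all(sg0$power == 0))

  expect_error(spectrogram(t10, window = 1, fMax = 600), "Nyquist")
})

test_that("a super-burst train shifts the dominant rate-rhythm band", {
  # short sparse bursts (ISI 0.2 s -> 5 Hz rhythm) then one long dense
  # burst (ISI 0.07 s -> ~14 Hz rhythm)
  sparse <- genSpikeTrain(spikeTrainSpec(nBursts = 1, spikesPerBurst = 100,
                                         intraBurstISI = 0.2,
                                         interBurstGap = 1, duration = 22,
                                         seed = 1))
  dense_t <- seq(25, 35, by = 0.07)
  tr <- SpikeTrain(sort(c(spikeTimes(sparse$train), dense_t)),
                   duration = 40)
  sg <- spectrogram(rateSignal(tr), window = 2, overlapFraction = 0.5,
                    fMax = 50)
  keep <- sg$freq >= 2
  dom <- sg$freq[keep][apply(sg$power[keep, ], 2, which.max)]
  early <- dom[sg$time > 2 & sg$time < 18]
  late <- dom[sg$time > 26 & sg$time < 34]
  expect_true(all(early >= 2 & early <= 10))
  expect_true(all(late >= 10 & late <= 20))
})
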