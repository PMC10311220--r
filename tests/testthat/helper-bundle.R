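# Builds a small on-disk synthetic dataset plus its pipeline manifest.
makeBundle <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- genSpikeTrain(spikeTrainSpec(nBursts = 4, spikesPerBurst = 6,
                                      intraBurstISI = 0.04,
                                      interBurstGap = 2, nNoiseSpikes = 3,
                                      duration = 60, seed = 1))
  writeSpikeCSV(sim$train, file.path(dir, "spikes.csv"))
  tt <- genBenchmarkTimes(30, 5, seed = 2)
  v <- genVoltageTrace(tt, voltageSpec(duration = 5, noiseSigma = 5,
                                       spikeAmplitude = -60, seed = 2))
  writeVoltageRaw(v$trace, file.path(dir, "trace.f32"))
  ip <- genImagePair(imagePairSpec(shape = c(48, 48), nSignalA = 80,
                                   nSignalB = 80, overlapFraction = 0.5,
                                   seed = 3))
  writeImagePairTIFF(ip$pair, file.path(dir, "a.tif"),
                     file.path(dir, "b.tif"))
  arb <- genArbor(arborSpec(nMainBranches = 4, junctionsPerBranch = 2,
                            seed = 4))
  writeSWC(arb$arbor, file.path(dir, "cell1.swc"))
  set.seed(5)
  ang <- runif(40, 0, 2 * pi); d <- runif(40, 300, 800)
  writePointsCSV(cbind(d * cos(ang), d * sin(ang)),
                 file.path(dir, "points.csv"))
  data.frame(
    culture_id = "cult1",
    kind = c("spikes", "voltage", "image_pair", "arbor", "points"),
    path = file.path(dir, c("spikes.csv", "trace.f32", "a.tif",
                            "cell1.swc", "points.csv")),
    path_b = c(NA, NA, file.path(dir, "b.tif"), NA, NA),
    duration_s = c(60, NA, NA, NA, NA))
}
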