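## On-disk contracts: spike times as CSV (electrode_id, time_s[,
## amplitude_uV]); voltage as raw little-endian float32 plus a JSON sidecar
## carrying {sampling_rate, units, n_samples, electrode_id, duration_s};
## images as 16-bit single-channel TIFF (integer intensities 0..65535);
## arbors as SWC; ground truth and run summaries as JSON.

#' Write spike trains to CSV
#'
#' @param trains a [SpikeTrain-class] or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeSpikeCSV <- function(trains, path) {
  if (is(trains, "SpikeTrain")) trains <- list(trains)
  rows <- lapply(trains, function(tr) {
    n <- nSpikes(tr)
    data.frame(electrode_id = rep(electrodeId(tr), n),
               time_s = spikeTimes(tr),
               amplitude_uV = if (length(tr@amplitudes)) tr@amplitudes
                              else rep(NA_real_, n))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read spike trains from CSV
#'
#' @param path CSV with columns `electrode_id`, `time_s` and optionally
#'   `amplitude_uV`.
#' @param duration recording duration in seconds (the CSV carries times
#'   only).
#' @return a list of [SpikeTrain-class], one per electrode, named by
#'   electrode.
#' @export
readSpikeCSV <- function(path, duration) {
  df <- utils::read.csv(path)
  by_el <- split(df, df$electrode_id)
  out <- lapply(by_el, function(d) {
    o <- order(d$time_s)
    amp <- if ("amplitude_uV" %in% names(d) && !all(is.na(d$amplitude_uV))) {
      d$amplitude_uV[o]
    } else numeric(0)
    SpikeTrain(d$time_s[o], duration, d$electrode_id[1], amp)
  })
  out[order(names(out))]
}

#' Write a voltage trace as raw float32 + JSON sidecar
#'
#' @param trace a [VoltageTrace-class].
#' @param path output path for the binary samples; the sidecar is written
#'   to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
writeVoltageRaw <- function(trace, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(voltageSamples(trace), con, size = 4, endian = "little")
  jsonlite::write_json(
    list(sampling_rate = samplingRate(trace), units = "uV",
         n_samples = length(voltageSamples(trace)),
         electrode_id = electrodeId(trace),
         duration_s = duration(trace)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a voltage trace written by [writeVoltageRaw()]
#'
#' @param path path to the raw float32 file (its `.json` sidecar must sit
#'   next to it).
#' @return a [VoltageTrace-class].
#' @export
readVoltageRaw <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, numeric(), n = meta$n_samples, size = 4,
               endian = "little")
  VoltageTrace(x, meta$sampling_rate, meta$electrode_id)
}

#' Write an image pair as two 16-bit single-channel TIFFs
#'
#' Intensities must lie in `[0, 65535]`; they are rounded to integers.
#'
#' @param pair an [ImagePair-class].
#' @param pathA,pathB output TIFF paths for the two channels.
#' @return `c(pathA, pathB)`, invisibly.
#' @export
writeImagePairTIFF <- function(pair, pathA, pathB) {
  wr <- function(img, path) {
    if (max(img) > 65535) stopf("intensities exceed the 16-bit range")
    tiff::writeTIFF(round(img) / 65535, path, bits.per.sample = 16)
  }
  wr(channelA(pair), pathA)
  wr(channelB(pair), pathB)
  invisible(c(pathA, pathB))
}

#' Read an image pair from two single-channel TIFFs
#'
#' @param pathA,pathB TIFF paths (as written by [writeImagePairTIFF()]).
#' @param pixelSize micrometres per pixel (optional).
#' @return an [ImagePair-class] with intensities on the original 0..65535
#'   scale.
#' @export
readImagePairTIFF <- function(pathA, pathB, pixelSize = NA_real_) {
  rd <- function(path) {
    img <- tiff::readTIFF(path)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    round(img * 65535)
  }
  ImagePair(rd(pathA), rd(pathB), pixelSize)
}

#' Read cell positions from CSV
#'
#' @param path CSV with columns `x_um`, `y_um`.
#' @return a two-column numeric matrix (micrometres).
#' @export
readPointsCSV <- function(path) {
  df <- utils::read.csv(path)
  as.matrix(df[, c("x_um", "y_um")])
}

#' Write cell positions to CSV
#'
#' @param points two-column matrix/data.frame of (x, y) micrometres.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writePointsCSV <- function(points, path) {
  pts <- as.matrix(points)
  utils::write.csv(data.frame(x_um = pts[, 1], y_um = pts[, 2]), path,
                   row.names = FALSE)
  invisible(path)
}

#' Write a ground-truth record as JSON
#'
#' @param truth a generator's `truth` list.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeGroundTruthJSON <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
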