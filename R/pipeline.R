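#' Pipeline configuration
#'
#' Bundles every stage's parameter block. The defaults are the study
#' settings (200-3000 Hz band, 6 x RMS threshold, 100 ms ISI exclusion,
#' 5-spike / 100 ms / 250 ms burst rule, 25-pixel rolling ball, top 10%
#' TOS, 5 um junction filter, 50-200/200-400/400-600 um zones), so an
#' empty configuration reproduces them.
#'
#' @param seed RNG seed recorded in the run summary.
#' @param outputDir directory for the report bundle.
#' @param spikeDetection,rate,burst,coloc,sholl,morphometry parameter
#'   blocks (see the respective constructors).
#' @param zones a [zoneSpec()] or NULL when no point fields are analyzed.
#' @return a list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(seed = 1, outputDir = ".",
                           spikeDetection = spikeDetectionParams(),
                           rate = rateParams(), burst = burstParams(),
                           coloc = colocParams(), sholl = shollParams(),
                           morphometry = morphometryParams(),
                           zones = NULL) {
  structure(list(seed = as.integer(seed), outputDir = outputDir,
                 spikeDetection = spikeDetection, rate = rate,
                 burst = burst, coloc = coloc, sholl = sholl,
                 morphometry = morphometry, zones = zones),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Every block is optional; omitted fields take the defaults of the
#' corresponding constructor, so an empty file yields the standard
#' settings.
#'
#' @param path YAML file; top-level keys `seed`, `output_dir`,
#'   `spike_detection`, `rate`, `burst`, `coloc`, `sholl`, `morphometry`,
#'   `zones`, each holding that constructor's arguments.
#' @return a [pipelineConfig()] object.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  blk <- function(key, ctor) do.call(ctor, if (is.null(y[[key]])) list()
                                           else y[[key]])
  pipelineConfig(
    seed = if (is.null(y$seed)) 1L else y$seed,
    outputDir = if (is.null(y$output_dir)) "." else y$output_dir,
    spikeDetection = blk("spike_detection", spikeDetectionParams),
    rate = blk("rate", rateParams),
    burst = blk("burst", burstParams),
    coloc = blk("coloc", colocParams),
    sholl = blk("sholl", shollParams),
    morphometry = blk("morphometry", morphometryParams),
    zones = if (is.null(y$zones)) NULL else do.call(zoneSpec, y$zones)
  )
}

emptyTables <- function() {
  list(
    per_electrode = data.frame(
      culture_id = character(0), electrode_id = character(0),
      n_spikes = numeric(0), spikes_per_minute = numeric(0),
      mean_isi_s = numeric(0), mean_firing_rate_hz = numeric(0),
      is_active = logical(0), n_bursts = numeric(0),
      bursts_per_minute = numeric(0), mean_spikes_per_burst = numeric(0),
      mean_burst_duration_s = numeric(0), mean_ibi_s = numeric(0),
      burstiness = numeric(0)),
    per_burst = data.frame(
      culture_id = character(0), electrode_id = character(0),
      t_start_s = numeric(0), t_end_s = numeric(0), n_spikes = numeric(0)),
    per_cell = data.frame(
      culture_id = character(0), cell = character(0),
      n_main_branches = numeric(0), longest_main_branch_um = numeric(0),
      total_process_length_um = numeric(0), n_junctions = numeric(0)),
    per_culture_coloc = data.frame(
      culture_id = character(0), M1 = numeric(0), M2 = numeric(0),
      PCC = numeric(0), TOS = numeric(0)),
    zones = data.frame(
      culture_id = character(0), inner_um = numeric(0), outer_um = numeric(0),
      count = numeric(0), area_mm2 = numeric(0),
      density_per_mm2 = numeric(0)),
    sholl = data.frame(
      culture_id = character(0), cell = character(0),
      radius_um = numeric(0), crossings = numeric(0))
  )
}

electrodeRow <- function(culture, train, cfg) {
  rm_ <- rateMetrics(train, cfg$rate)
  bursts <- detectBursts(train, cfg$burst)
  bm <- if (nSpikes(train) > 0) burstMetrics(train, bursts) else NULL
  list(
    electrode = data.frame(
      culture_id = culture, electrode_id = electrodeId(train),
      n_spikes = nSpikes(train),
      spikes_per_minute = rm_$spikesPerMinute,
      mean_isi_s = rm_$meanISI, mean_firing_rate_hz = rm_$meanFiringRate,
      is_active = rm_$isActive,
      n_bursts = if (is.null(bm)) 0 else bm$nBursts,
      bursts_per_minute = if (is.null(bm)) 0 else bm$burstsPerMinute,
      mean_spikes_per_burst = if (is.null(bm)) NA_real_
                              else bm$meanSpikesPerBurst,
      mean_burst_duration_s = if (is.null(bm)) NA_real_
                              else bm$meanBurstDuration,
      mean_ibi_s = if (is.null(bm)) NA_real_ else bm$meanInterburstInterval,
      burstiness = if (is.null(bm)) NA_real_ else bm$burstiness),
    bursts = if (nrow(bursts)) {
      data.frame(culture_id = culture, electrode_id = electrodeId(train),
                 t_start_s = bursts$tStart, t_end_s = bursts$tEnd,
                 n_spikes = bursts$nSpikes)
    } else NULL
  )
}

#' Run the full analysis pipeline over a manifest
#'
#' Executes the stage appropriate to each manifest entry and writes the
#' report bundle: `per_electrode.csv`, `per_burst.csv`, `per_cell.csv`,
#' `per_culture_coloc.csv`, `zones.csv`, `sholl.csv` and a
#' `run_summary.json` carrying the seed, a configuration hash and the
#' package version. Output is deterministic: the same configuration and
#' manifest produce byte-identical files. Stage errors are collected with
#' file context; independent entries still run, and the pipeline fails at
#' the end if any entry errored.
#'
#' @param config a [pipelineConfig()].
#' @param manifest data.frame with columns `culture_id`, `kind` (one of
#'   `spikes`, `voltage`, `image_pair`, `arbor`, `points`), `path`, and
#'   optionally `path_b` (image pairs) and `duration_s` (spike CSVs).
#' @return invisibly, a list with the tables, the summary and any errors.
#' @export
runPipeline <- function(config, manifest) {
  dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
  tabs <- emptyTables()
  errors <- character(0)
  addRow <- function(name, row) {
    if (!is.null(row)) tabs[[name]] <<- rbind(tabs[[name]], row)
  }
  for (i in seq_len(nrow(manifest))) {
    e <- manifest[i, ]
    res <- tryCatch({
      switch(as.character(e$kind),
        spikes = {
          trains <- readSpikeCSV(e$path, e$duration_s)
          for (tr in trains) {
            r <- electrodeRow(e$culture_id, tr, config)
            addRow("per_electrode", r$electrode)
            addRow("per_burst", r$bursts)
          }
        },
        voltage = {
          tr <- readVoltageRaw(e$path)
          st <- detectSpikes(tr, config$spikeDetection)
          r <- electrodeRow(e$culture_id, st, config)
          addRow("per_electrode", r$electrode)
          addRow("per_burst", r$bursts)
        },
        image_pair = {
          pair <- readImagePairTIFF(e$path, e$path_b)
          cr <- colocalize(pair, config$coloc)
          addRow("per_culture_coloc",
                 data.frame(culture_id = e$culture_id, M1 = cr$M1,
                            M2 = cr$M2, PCC = cr$PCC, TOS = cr$TOS))
        },
        arbor = {
          arb <- readSWC(e$path)
          mm <- branchMorphometrics(arb, config$morphometry)
          cell <- basename(e$path)
          addRow("per_cell",
                 data.frame(culture_id = e$culture_id, cell = cell,
                            n_main_branches = mm$nMainBranches,
                            longest_main_branch_um = mm$longestMainBranch,
                            total_process_length_um = mm$totalProcessLength,
                            n_junctions = mm$nJunctions))
          sp <- shollProfile(arb, config$sholl)
          if (nrow(sp)) {
            addRow("sholl",
                   data.frame(culture_id = e$culture_id, cell = cell,
                              radius_um = sp$radius,
                              crossings = sp$crossings))
          }
        },
        points = {
          if (is.null(config$zones)) stopf("no zone spec configured")
          zd <- zoneDensity(readPointsCSV(e$path), config$zones)
          addRow("zones",
                 data.frame(culture_id = e$culture_id, inner_um = zd$inner,
                            outer_um = zd$outer, count = zd$count,
                            area_mm2 = zd$areaMm2,
                            density_per_mm2 = zd$densityPerMm2))
        },
        stopf("unknown manifest kind '%s'", e$kind))
      NULL
    }, error = function(err) conditionMessage(err))
    if (!is.null(res)) {
      errors <- c(errors, sprintf("%s [%s]: %s", e$path, e$kind, res))
    }
  }

  for (nm in names(tabs)) {
    utils::write.csv(tabs[[nm]], file.path(config$outputDir,
                                           paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  # hash the analysis settings (not the output location) via canonical JSON
  cfg_file <- tempfile()
  on.exit(unlink(cfg_file))
  hashed <- config[setdiff(sort(names(config)), "outputDir")]
  writeLines(jsonlite::serializeJSON(hashed, digits = 15), cfg_file)
  summary <- list(
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_file)),
    package_version = as.character(utils::packageVersion("neuroculture")),
    n_manifest = nrow(manifest),
    n_errors = length(errors),
    errors = errors,
    tables = lapply(tabs, nrow)
  )
  jsonlite::write_json(summary, file.path(config$outputDir,
                                          "run_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  if (length(errors)) {
    stopf("pipeline finished with %d error(s):\n%s", length(errors),
          paste(errors, collapse = "\n"))
  }
  invisible(list(tables = tabs, summary = summary, errors = errors))
}
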