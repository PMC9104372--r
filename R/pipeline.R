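## Pipeline orchestration behind the command-line entry point: each stage is
## an exported function taking a flat configuration list, writing its
## products and a provenance manifest to the output directory, and returning
## its results invisibly. All randomness funnels through one named seed per
## stage; identical config + seed reproduce byte-identical outputs.

#' Read a flat pipeline configuration file
#'
#' Debian-control-style `key: value` text (one record). Unknown keys are
#' kept; numeric-looking values are converted. Defaults (depth threshold
#' 40 m, clip depth 20 m, calibration window 1-5 m, training fraction 0.4,
#' classifiers mlc+rtc+svm) are filled for missing keys.
#'
#' @param path config file, or `NULL` for pure defaults.
#' @param overrides named list applied on top of the file.
#' @return named list.
#' @export
readPipelineConfig <- function(path = NULL, overrides = list()) {
  cfg <- list(
    out_dir = "seagrass_run", seed = 1,
    n_rows = 120, n_cols = 160, pixel_size = 10, noise_sd = 0.002,
    n_samples = 600,
    depth_threshold = 40, clip_depth = 20,
    calib_depth_min = 1, calib_depth_max = 5, transform = "log_contrast",
    train_fraction = 0.4, classifiers = "mlc,rtc,svm",
    loss_fraction = 0.15, gain_fraction = 0.15)
  if (!is.null(path)) {
    if (!file.exists(path)) stopValidation("config file not found: ", path)
    dcf <- read.dcf(path)
    fromFile <- setNames(as.list(dcf[1, ]), colnames(dcf))
    cfg <- utils::modifyList(cfg, fromFile)
  }
  cfg <- utils::modifyList(cfg, overrides)
  for (k in names(cfg)) {
    v <- suppressWarnings(as.numeric(cfg[[k]]))
    if (length(v) == 1 && !is.na(v) && !k %in% c("classifiers", "transform"))
      cfg[[k]] <- v
  }
  badNum <- vapply(c("train_fraction", "clip_depth", "depth_threshold"),
                   function(k) !is.numeric(cfg[[k]]), logical(1))
  if (any(badNum))
    stopValidation("non-numeric value for ",
                   paste(names(badNum)[badNum], collapse = ", "))
  if (cfg$train_fraction <= 0 || cfg$train_fraction >= 1)
    stopValidation("train_fraction must lie in (0, 1)")
  cfg
}

writeManifest <- function(outDir, stage, cfg, extra = list()) {
  cfgFile <- file.path(outDir, paste0(stage, "_config.dcf"))
  flat <- vapply(cfg, function(v) paste(format(v), collapse = ","),
                 character(1))
  write.dcf(as.data.frame(t(flat)), cfgFile)
  manifest <- c(list(stage = stage, seed = cfg$seed,
                     config_md5 = unname(tools::md5sum(cfgFile)),
                     package_version =
                       as.character(utils::packageVersion("SeagrassDyn")),
                     timestamped = FALSE), extra)
  jsonlite::write_json(manifest, file.path(outDir,
                                           paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Simulate a synthetic scene and epoch pair to disk
#'
#' Writes the reflectance bands, bathymetry, truth class maps for both
#' epochs, the calibration-zone polygon and the labelled samples (GeoJSON
#' points) under `cfg$out_dir`, plus a manifest with the seed and config
#' hash.
#'
#' @param cfg configuration list from [readPipelineConfig()].
#' @return invisibly, the `generateScene`/`generateEpochPair` results.
#' @export
cmdSimulate <- function(cfg) {
  outDir <- cfg$out_dir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  config <- ScenarioConfig(nRows = cfg$n_rows, nCols = cfg$n_cols,
                           pixelSize = cfg$pixel_size,
                           noiseSd = cfg$noise_sd, seed = cfg$seed)
  gen <- generateScene(config, nSamples = cfg$n_samples)
  pair <- generateEpochPair(config, cfg$loss_fraction, cfg$gain_fraction)
  ## image the SECOND epoch: classification estimates epoch-2 seagrass,
  ## which the change stage compares against the epoch-1 baseline truth
  epoch2 <- sceneFromTruth(pair$t2, nSamples = cfg$n_samples)
  writeScene(epoch2$scene, outDir)
  writeRasterGrid(pair$t1@classMap, file.path(outDir, "truth_epoch1.asc"))
  writeRasterGrid(pair$t2@classMap, file.path(outDir, "truth_epoch2.asc"))
  writeVectorFeatures(gen$calibrationZone,
                      file.path(outDir, "calibration_zone.geojson"))
  g <- georef(epoch2$scene)
  pts <- lapply(seq_along(epoch2$samples@labels), function(i) {
    rc <- epoch2$samples@location[i, ]
    list(type = "Point",
         coords = c(g@originX + (rc[2] - 0.5) * g@pixelSize,
                    g@originY - (rc[1] - 0.5) * g@pixelSize),
         class = as.character(epoch2$samples@labels[i]))
  })
  writeVectorFeatures(pts, file.path(outDir, "samples.geojson"))
  writeManifest(outDir, "simulate", cfg,
                list(planted = as.list(pair$planted)))
  invisible(list(gen = gen, pair = pair, epoch2 = epoch2))
}

#' Water-column correction stage
#'
#' Reads the scene from `cfg$out_dir`, clips to `clip_depth`, estimates
#' deep-water reflectance (refusing when no deep zone exists), fits the
#' attenuation coefficients over the calibration polygon and writes the
#' bottom-reflectance composite (`Rb_*.asc`) plus a per-band fit report.
#'
#' @param cfg configuration list.
#' @return invisibly, list with `rInf`, `fit`, `rb`.
#' @export
cmdCorrect <- function(cfg) {
  outDir <- cfg$out_dir
  scene <- readScene(file.path(outDir, "B2_490.asc"),
                     file.path(outDir, "B3_560.asc"),
                     file.path(outDir, "B4_665.asc"),
                     file.path(outDir, "DEPTH.asc"))
  rInf <- estimateDeepWaterReflectance(scene, cfg$depth_threshold)
  zone <- readVectorFeatures(file.path(outDir, "calibration_zone.geojson"))
  fit <- fitAttenuation(scene, zone, rInf, cfg$calib_depth_min,
                        cfg$calib_depth_max, transform = cfg$transform)
  rb <- correctWaterColumn(scene, rInf, fit, maxDepth = cfg$clip_depth)
  for (lab in names(rb))
    writeRasterGrid(rb[[lab]], file.path(outDir, paste0("Rb_", lab, ".asc")))
  writeFitReport(fit, file.path(outDir, "attenuation_fit.csv"))
  writeManifest(outDir, "correct", cfg,
                list(r_inf = as.list(setNames(rInf@rInf, names(rb))),
                     kd = as.list(setNames(fit@kd, names(rb)))))
  invisible(list(rInf = rInf, fit = fit, rb = rb))
}

CLASSIFIER_ORDER <- c("mlc", "rtc", "svm")

#' Classification + accuracy-assessment stage
#'
#' Reads the bottom-reflectance composite and labelled samples, splits them
#' into training/assessment sets, fits each requested classifier, writes one
#' classified raster and one confusion report per method, and selects the
#' best method by overall accuracy, then kappa, then the fixed order
#' mlc < rtc < svm on exact ties.
#'
#' @param cfg configuration list (`classifiers` comma-list among mlc, rtc,
#'   svm).
#' @return invisibly, list with per-method `rasters` and `confusions`, and
#'   `best`.
#' @export
cmdClassify <- function(cfg) {
  outDir <- cfg$out_dir
  rb <- list(readRasterGrid(file.path(outDir, "Rb_B2_490.asc"), "B2_490"),
             readRasterGrid(file.path(outDir, "Rb_B3_560.asc"), "B3_560"),
             readRasterGrid(file.path(outDir, "Rb_B4_665.asc"), "B4_665"))
  feats <- readVectorFeatures(file.path(outDir, "samples.geojson"))
  samples <- extractSamples(feats, rb)
  split <- splitSamples(samples, cfg$train_fraction,
                        seed = childSeed(cfg$seed, 11L))
  methods <- trimws(strsplit(cfg$classifiers, ",")[[1]])
  bad <- setdiff(methods, CLASSIFIER_ORDER)
  if (length(bad))
    stopValidation("unknown classifier(s): ", paste(bad, collapse = ", "))
  rasters <- list(); confusions <- list()
  for (m in methods) {
    raster <- switch(m,
      mlc = predictMLC(trainMLC(split@train), rb),
      rtc = trainPredictAlt(split@train, rb, "random_trees",
                            seed = childSeed(cfg$seed, 22L)),
      svm = trainPredictAlt(split@train, rb, "svm",
                            seed = childSeed(cfg$seed, 33L)))
    rasters[[m]] <- raster
    confusions[[m]] <- buildConfusion(raster, split@test)
    writeRasterGrid(raster, file.path(outDir, paste0("class_", m, ".asc")))
    writeConfusionReport(confusions[[m]],
                         file.path(outDir, paste0("confusion_", m, ".csv")))
  }
  ## best by overall accuracy, then kappa, then fixed order on exact ties
  ord <- order(-vapply(confusions, overallAccuracy, numeric(1)),
               -vapply(confusions, kappaIndex, numeric(1)),
               match(names(confusions), CLASSIFIER_ORDER))
  best <- names(confusions)[ord[1]]
  writeLines(best, file.path(outDir, "best_classifier.txt"))
  writeManifest(outDir, "classify", cfg, list(best = best))
  invisible(list(rasters = rasters, confusions = confusions, best = best))
}

#' Change-analysis stage
#'
#' Overlays the epoch-1 truth (baseline) with the best epoch-2
#' classification, writes the change raster and the stable/loss/gain/other
#' area summary.
#'
#' @param cfg configuration list.
#' @param baselinePath,currentPath optional explicit raster paths (defaults:
#'   `truth_epoch1.asc` and the best classifier's map in `cfg$out_dir`).
#' @return invisibly, list with `change` raster and `summary`.
#' @export
cmdChange <- function(cfg, baselinePath = NULL, currentPath = NULL) {
  outDir <- cfg$out_dir
  if (is.null(baselinePath))
    baselinePath <- file.path(outDir, "truth_epoch1.asc")
  if (is.null(currentPath)) {
    bestFile <- file.path(outDir, "best_classifier.txt")
    best <- if (file.exists(bestFile)) readLines(bestFile)[1] else "mlc"
    currentPath <- file.path(outDir, paste0("class_", best, ".asc"))
  }
  baseline <- readRasterGrid(baselinePath, "CLASS")
  current <- readRasterGrid(currentPath, "CLASS")
  change <- overlayChange(baseline, current)
  summary <- summarizeChange(change)
  writeRasterGrid(change, file.path(outDir, "change.asc"))
  writeChangeReport(summary, file.path(outDir, "change_summary.csv"))
  writeManifest(outDir, "change", cfg,
                list(area_ha = as.list(setNames(summary@areaHa,
                                                names(summary@pixelCounts)))))
  invisible(list(change = change, summary = summary))
}

#' Run the full pipeline
#'
#' simulate -> correct -> classify (+ assessment) -> change, all under one
#' configuration.
#'
#' @param cfg configuration list from [readPipelineConfig()].
#' @return invisibly, list of the stage results.
#' @export
runAll <- function(cfg) {
  sim <- cmdSimulate(cfg)
  cor <- cmdCorrect(cfg)
  cls <- cmdClassify(cfg)
  chg <- cmdChange(cfg)
  invisible(list(simulate = sim, correct = cor, classify = cls,
                 change = chg))
}
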