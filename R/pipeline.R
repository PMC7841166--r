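## File-based pipeline orchestration: every stage reads and writes plain
## CSV/TIFF/PNG artefacts so intermediate results stay inspectable, and the
## effective configuration is echoed to the output directory of every run.

#' Default pipeline configuration
#'
#' All tunables of the measurement with their standard values: 40 nm pixel
#' pitch, band-pass sigmas 1/5 px, region area 50-5000 px, 30-percent
#' 3x3-box termination, window-5 median filter, 40-percent positivity,
#' 4-px gap tolerance, 80-nm histogram bins, alpha 0.05, and the
#' edge-motility defaults (200 nm motion threshold, 2000 nm near-edge
#' distance, 15-px smoothing window).
#'
#' @return named list of configuration values.
#' @export
defaultPipelineConfig <- function() {
  list(pixelPitchNm = 40, zStepNm = 110, zIndices = NULL,
       sigmaLow = 1, sigmaHigh = 5, minArea = 50, maxArea = 5000,
       segmentationSource = "mean", terminationFrac = 0.30,
       maxExtendPx = 50, minPathPx = 3, medianWindow = 5,
       thresholdFrac = 0.40, maxGap = 4, binNm = 80, alpha = 0.05,
       motionThresholdNm = 200, nearEdgeThresholdNm = 2000,
       smoothingWindowPx = 15, seed = 1)
}

#' Read a pipeline configuration file (YAML)
#'
#' Values present in the file override the defaults; unknown keys are
#' rejected.
#'
#' @param path YAML file; NULL returns the defaults.
#' @return named configuration list.
#' @export
readPipelineConfig <- function(path = NULL) {
  cfg <- defaultPipelineConfig()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  modifyList(cfg, user)
}

#' @rdname readPipelineConfig
#' @param config configuration list.
#' @export
writePipelineConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

.cfgMeasureParams <- function(cfg) {
  list(thresholdFrac = cfg$thresholdFrac, maxGap = cfg$maxGap,
       terminationFrac = cfg$terminationFrac,
       medianWindow = cfg$medianWindow, maxExtendPx = cfg$maxExtendPx,
       minPathPx = cfg$minPathPx)
}

.log <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
  writeLines(msg, con)
}

#' Run a pipeline stage
#'
#' Subcommands: \code{simulate} (write a synthetic scene, masks and ground
#' truth), \code{segment} (scene TIFF to label image and region table),
#' \code{measure} (scene TIFF to per-adhesion measurement CSV),
#' \code{stats} (measurement CSV + reference CSV to histograms,
#' comparisons, 2D difference and PNG renders), \code{motility} (masks +
#' measurement CSV to edge classes), and \code{all} (chain simulate
#' through stats on a synthetic scene). The effective configuration is
#' echoed to \code{outputDir/config_used.yaml} and a log of parameters and
#' fallbacks to \code{outputDir/run.log}.
#'
#' @param subcommand one of simulate, segment, measure, stats, motility,
#'   all.
#' @param config configuration list, see
#'   \code{\link{defaultPipelineConfig}}.
#' @param inputDir directory holding the stage inputs (scene.tif,
#'   measurements.csv, masks, ...); defaults to \code{outputDir}.
#' @param referenceCsv measurement CSV of the reference population (for
#'   \code{stats}); when NULL a profile-level simulated null reference of
#'   500 adhesions is used.
#' @param outputDir output directory (created).
#' @param roiEdits optional ROI edits CSV for segmentation.
#' @return invisibly, a list of the stage's main results.
#' @export
runPipeline <- function(subcommand = c("simulate", "segment", "measure",
                                       "stats", "motility", "all"),
                        config = defaultPipelineConfig(),
                        inputDir = NULL, referenceCsv = NULL,
                        outputDir, roiEdits = NULL) {
  subcommand <- match.arg(subcommand)
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(inputDir)) inputDir <- outputDir
  writePipelineConfig(config, file.path(outputDir, "config_used.yaml"))
  logCon <- file(file.path(outputDir, "run.log"), open = "a")
  on.exit(close(logCon))
  .log(logCon, "subcommand=", subcommand, " seed=", config$seed,
       " R=", as.character(getRversion()))
  res <- list()

  doSimulate <- function() {
    spec <- randomSceneSpec(seed = config$seed)
    sc <- renderScene(spec)
    noisy <- addNoise(sc$images, spec@noise, seed = spec@seed)
    writeImagePair(noisy, file.path(outputDir, "scene.tif"))
    # simple edge program: alternate static and protruding segments
    prog <- rep(c(0, 500), length.out = nrow(spec@cellPolygon))
    tl <- renderTimelapseMasks(spec, prog,
                               nearEdgeThresholdNm =
                                 config$nearEdgeThresholdNm)
    writeMask(tl$maskT0, file.path(outputDir, "mask_t0.tif"))
    writeMask(tl$maskT1, file.path(outputDir, "mask_t1.tif"))
    truth <- sc$truth
    truth$edgeClass <- tl$faClasses$class[match(truth$id,
                                                tl$faClasses$id)]
    writeGroundTruth(truth, file.path(outputDir, "ground_truth.csv"))
    .log(logCon, "simulated ", nrow(truth), " adhesions")
    list(spec = spec, images = noisy, truth = truth)
  }

  loadScene <- function() {
    st <- loadStack(file.path(inputDir, "scene.tif"),
                    pixelPitchNm = config$pixelPitchNm,
                    zStepNm = config$zStepNm)
    projectZ(st, config$zIndices)
  }

  segParams <- function() SegmentationParams(
    sigmaLow = config$sigmaLow, sigmaHigh = config$sigmaHigh,
    minArea = config$minArea, maxArea = config$maxArea,
    source = config$segmentationSource)

  doSegment <- function(images) {
    regions <- segmentFAs(images, segParams(), roiEdits)
    writeLabelImage(regions, dim(images@red),
                    file.path(outputDir, "labels.tif"))
    info <- do.call(rbind, lapply(regions, function(r)
      data.frame(id = r@id, area = r@area, centroidRow = r@centroid[1],
                 centroidCol = r@centroid[2])))
    write.csv(info, file.path(outputDir, "regions.csv"),
              row.names = FALSE)
    .log(logCon, "segmented ", length(regions), " regions")
    regions
  }

  doMeasure <- function(images, regions) {
    meas <- measureScene(images, regions, params = .cfgMeasureParams(config))
    write.csv(meas, file.path(outputDir, "measurements.csv"),
              row.names = FALSE)
    .log(logCon, "measured ", nrow(meas), " adhesions (",
         sum(meas$discarded), " discarded)")
    meas
  }

  doStats <- function(meas) {
    expSet <- toSigned(meas, "experimental")
    refSet <- if (!is.null(referenceCsv)) {
      toSigned(read.csv(referenceCsv, stringsAsFactors = FALSE),
               "reference")
    } else {
      .log(logCon, "no reference supplied; simulating 500-adhesion null")
      simulateNullSet(500, seed = config$seed)
    }
    bias <- referenceBias(refSet)
    .log(logCon, sprintf("reference bias: head %+.1f, tail %+.1f nm",
                         bias[["head"]], bias[["tail"]]))
    expC <- applyBias(expSet, bias)
    refC <- applyBias(refSet, bias)
    out <- list(bias = bias)
    summ <- list()
    for (end in c("head", "tail")) {
      hc <- compareHistograms(expC, refC, end, binNm = config$binNm,
                              alpha = config$alpha)
      writeHistogramCsv(hc, file.path(outputDir,
                                      paste0("histogram_", end, ".csv")))
      plotComparison(hc, file.path(outputDir,
                                   paste0("histogram_", end, ".png")))
      summ[[end]] <- data.frame(end = end, n = hc@nExp, U = hc@U,
                                p = hc@pValue, median = hc@medianExp,
                                significant = hc@significant)
      out[[end]] <- hc
    }
    write.csv(do.call(rbind, summ),
              file.path(outputDir, "comparison_summary.csv"),
              row.names = FALSE)
    d2 <- diff2DHistogram(expC, refC, binNm = config$binNm)
    writeDiff2DCsv(d2, file.path(outputDir, "diff2d.csv"))
    plotDiff2D(d2, file.path(outputDir, "diff2d.png"))
    out$diff2d <- d2
    out
  }

  doMotility <- function(meas) {
    m0 <- readMask(file.path(inputDir, "mask_t0.tif"))
    m1 <- readMask(file.path(inputDir, "mask_t1.tif"))
    mp <- MotilityParams(config$motionThresholdNm,
                         config$nearEdgeThresholdNm,
                         config$smoothingWindowPx)
    map <- edgeDisplacement(m0, m1, mp, config$pixelPitchNm)
    meas <- classifyMeasurements(meas, map, mp)
    write.csv(meas, file.path(outputDir, "measurements.csv"),
              row.names = FALSE)
    .log(logCon, "edge classes: ",
         paste(names(table(meas$edgeClass)), table(meas$edgeClass),
               collapse = ", ", sep = "="))
    meas
  }

  if (subcommand == "simulate") {
    res <- doSimulate()
  } else if (subcommand == "segment") {
    res$regions <- doSegment(loadScene())
  } else if (subcommand == "measure") {
    images <- loadScene()
    res$measurements <- doMeasure(images, doSegment(images))
  } else if (subcommand == "stats") {
    meas <- read.csv(file.path(inputDir, "measurements.csv"),
                     stringsAsFactors = FALSE)
    res <- doStats(meas)
  } else if (subcommand == "motility") {
    meas <- read.csv(file.path(inputDir, "measurements.csv"),
                     stringsAsFactors = FALSE)
    res$measurements <- doMotility(meas)
  } else if (subcommand == "all") {
    sim <- doSimulate()
    inputDir <- outputDir
    images <- loadScene()
    regions <- doSegment(images)
    meas <- doMeasure(images, regions)
    meas <- doMotility(meas)
    res <- doStats(meas)
    res$measurements <- meas
    res$truth <- sim$truth
  }
  invisible(res)
}
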