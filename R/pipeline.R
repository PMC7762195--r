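# End-to-end orchestration: detect -> register -> propagate -> perfuse ->
# segment -> summarize, plus the validation harness comparing algorithm
# summaries against manual ones.

#' Simulate a complete stress-test scenario
#'
#' Builds one synthetic "patient recording" with the full clinical
#' protocol: a baseline segment, an occlusion with release, a reactive
#' hyperemia overshoot, a recording break while the foot is repositioned,
#' and a Buerger's-test segment in a distinct pose with its own ROI set.
#' Returns everything [runAnalysis()] needs plus the ground truth.
#'
#' Default problem size (desk scale): a 0.75-scale phantom (150 x 112 px)
#' and a 20-frame protocol — baseline frames 1-4, occlusion 5-7 with
#' release at 7, hyperemia peaking at frame 10, a break after frame 15,
#' Buerger frames 16-20.
#'
#' @param seed RNG seed (drives motion and speckle).
#' @param scale phantom scale factor.
#' @param nFrames total frames (>= 20 recommended at the default layout).
#' @param calibration instrument constants.
#' @param maxRotationDeg,maxTranslation motion bounds.
#' @param artifacts include static artifact boxes?
#' @return list: recording, initialRois, buergerRois, region (artifact-free
#'   box), calibration, protocol, groundTruth (poses, true ROI sets, true
#'   per-frame region perfusions, true peak frame).
#' @export
simulateScenario <- function(seed = 1, scale = 0.75, nFrames = 20L,
                             calibration = Calibration(1.25, 250),
                             maxRotationDeg = 8, maxTranslation = 10,
                             artifacts = TRUE) {
  stopifnot(nFrames >= 12L)
  phantom <- makeFootPhantom(scale = scale, artifacts = artifacts)
  prot <- Protocol(baselineWindow = c(1L, 4L), releaseFrame = 7L,
                   buergerWindow = c(nFrames - 4L, nFrames),
                   frameRate = 1,
                   breakFrames = nFrames - 5L)
  peakFrame <- 10L
  prof <- hyperemiaProfile(prot, nFrames, peakFrame)

  pivot <- c(75, 115) * scale
  base <- makeMotionTrajectory(nFrames, pivot,
                               maxRotationDeg = maxRotationDeg,
                               maxTranslation = maxTranslation,
                               seed = seed)
  # Buerger reset: repositioned foot -> a distinct base pose composed on
  # top of the within-segment motion
  gStart <- prot@buergerWindow[1]
  resetPose <- pivotTransform(25 * pi / 180, c(6, -8) * scale, pivot)
  traj <- base
  for (f in gStart:nFrames)
    traj[[f]] <- composeTransforms(resetPose, base[[f]])

  sim <- simulateRecording(phantom, traj, calibration,
                           perfusionScale = prof, protocol = prot,
                           seed = seed + 1000L)
  # the operator draws the Buerger ROI set on the segment's first frame
  buergerRois <- sim$groundTruth$roiSets[[gStart]]
  sim$groundTruth$peakFrame <- peakFrame
  list(recording = sim$recording,
       initialRois = phantom@rois,
       buergerRois = buergerRois,
       region = if (artifacts) artifactFreeRegion(phantom) else NULL,
       calibration = calibration,
       protocol = prot,
       phantom = phantom,
       groundTruth = sim$groundTruth)
}

#' Run the full semi-automatic analysis of one recording
#'
#' Executes the whole pipeline: foot detection and ICP tracking of the
#' manually drawn frame-1 ROIs (with the Buerger reset when the protocol
#' has a Buerger segment), per-frame perfusion conversion, PORH peak
#' detection on the whole-foot ROI, TOI segmentation and per-TOI means.
#' With \code{outputDir} set, writes the trace CSV, TOI summary CSV,
#' tracking diagnostics CSV, per-frame ROI JSON and a run log listing
#' every effective parameter and the config MD5 — identical inputs give
#' byte-identical outputs.
#'
#' @param recording a [Recording-class] with a protocol.
#' @param initialRois frame-1 ROI set.
#' @param calibration a [Calibration-class].
#' @param buergerRois Buerger first-frame ROI set (required iff the
#'   protocol has a Buerger segment).
#' @param region optional artifact-free pixel box.
#' @param peakRoi label of the ROI whose trace drives PORH peak detection
#'   (default "foot", the whole-foot region).
#' @param icpControl,cannyControl,peakHalfwidth,smoothingWindow,
#'   plateauEpsilon,plateauRun parameter overrides.
#' @param minPixels minimum valid pixels per ROI per frame.
#' @param outputDir optional output directory.
#' @return list (class \code{lsciAnalysis}): \code{tracking}
#'   ([TrackingResult-class]), \code{trace} ([PerfusionTrace-class]),
#'   \code{windows}, \code{peakFrame}, \code{toiSummary} (data.frame),
#'   \code{warnings} (character).
#' @export
runAnalysis <- function(recording, initialRois, calibration,
                        buergerRois = NULL, region = NULL,
                        peakRoi = "foot",
                        icpControl = icpParams(),
                        cannyControl = cannyParams(),
                        peakHalfwidth = 2L, smoothingWindow = 5L,
                        plateauEpsilon = 1, plateauRun = 5L,
                        minPixels = MIN_ROI_PIXELS,
                        outputDir = NULL) {
  prot <- protocol(recording)
  if (is.null(prot)) stopf("recording carries no protocol annotations")
  warnings <- character(0)
  wh <- withCallingHandlers

  track <- wh(trackRois(recording, initialRois, buergerRois, region,
                        icpControl, cannyControl),
              warning = function(w) {
                warnings <<- c(warnings, conditionMessage(w))
                invokeRestart("muffleWarning")
              })
  trace <- wh(perfusionTrace(recording, roiSets(track), calibration,
                             minPixels = minPixels),
              warning = function(w) {
                warnings <<- c(warnings, conditionMessage(w))
                invokeRestart("muffleWarning")
              })

  labels <- roiLabels(trace)
  if (!peakRoi %in% labels)
    stopf("peak ROI '%s' not among trace ROIs (%s)", peakRoi,
          paste(labels, collapse = ", "))
  searchEnd <- ncol(trace)
  if (hasBuerger(prot)) searchEnd <- prot@buergerWindow[1] - 1L
  if (length(prot@breakFrames)) {
    after <- prot@breakFrames[prot@breakFrames > prot@releaseFrame]
    if (length(after)) searchEnd <- min(searchEnd, min(after))
  }
  peakFrame <- findPorhPeak(perfusion(trace)[peakRoi, ],
                            prot@releaseFrame, searchEnd,
                            smoothingWindow, plateauEpsilon, plateauRun)
  windows <- segmentTois(prot, peakFrame, peakHalfwidth)
  trace <- assignTois(trace, windows)
  toiSummary <- wh(summarizeToi(trace, windows),
                   warning = function(w) {
                     warnings <<- c(warnings, conditionMessage(w))
                     invokeRestart("muffleWarning")
                   })

  result <- list(tracking = track, trace = trace, windows = windows,
                 peakFrame = peakFrame, toiSummary = toiSummary,
                 warnings = warnings)
  class(result) <- "lsciAnalysis"

  if (!is.null(outputDir)) {
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    writeTraceCsv(trace, file.path(outputDir, "trace.csv"))
    write.csv(toiSummary, file.path(outputDir, "toi_summary.csv"),
              row.names = FALSE)
    exportTracking(track, outputDir)
    writeRunLog(file.path(outputDir, "run_log.txt"),
                recording, calibration, prot, region,
                icpControl, cannyControl,
                list(peak_roi = peakRoi, peak_halfwidth = peakHalfwidth,
                     smoothing_window = smoothingWindow,
                     plateau_epsilon = plateauEpsilon,
                     plateau_run = plateauRun, min_pixels = minPixels),
                peakFrame, warnings)
  }
  result
}

#' @export
print.lsciAnalysis <- function(x, ...) {
  cat("LSCI analysis\n")
  show(x$tracking)
  show(x$trace)
  cat(sprintf("  PORH peak at frame %d; TOIs: %s\n", x$peakFrame,
              paste(vapply(names(x$windows), function(nm)
                sprintf("%s [%d, %d]", nm, x$windows[[nm]][1],
                        x$windows[[nm]][2]), character(1)), collapse = ", ")))
  cat(sprintf("  %d (ROI, TOI) summary mean(s); %d warning(s)\n",
              nrow(x$toiSummary), length(x$warnings)))
  invisible(x)
}

writeRunLog <- function(path, recording, calibration, prot, region,
                        icpControl, cannyControl, timelinePars,
                        peakFrame, warnings) {
  cfg <- list(
    frames = dim(recording@frames),
    calibration = list(beta = calibration@beta, gain = calibration@gain,
                       reference_pu = calibration@referencePerfusion,
                       sigma_convention = calibration@sigmaConvention),
    protocol = list(baseline = prot@baselineWindow,
                    release_frame = prot@releaseFrame,
                    buerger = prot@buergerWindow,
                    breaks = prot@breakFrames),
    artifact_free_region = region,
    icp = icpControl[c("maxIterations", "convergenceTol", "trimFraction")],
    canny = cannyControl,
    timeline = timelinePars)
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA, null = "null")
  hash <- unname(tools::md5sum(tmp))
  lines <- c(
    sprintf("lscitrack %s", as.character(utils::packageVersion("lscitrack"))),
    sprintf("config_md5: %s", hash),
    sprintf("porh_peak_frame: %d", peakFrame),
    "effective parameters:",
    paste0("  ", strsplit(jsonlite::toJSON(cfg, auto_unbox = TRUE,
                                           pretty = TRUE, digits = NA,
                                           null = "null"), "\n")[[1]]),
    if (length(warnings)) c("warnings:", paste0("  ", warnings)) else "warnings: none")
  writeLines(lines, path)
  unlink(tmp)
  invisible(path)
}

#' Validate algorithm summaries against manual summaries
#'
#' Compares per-(subject, ROI, TOI) mean perfusions from two analysis
#' routes. Per (ROI, TOI) cell it computes the single-measures absolute-
#' agreement ICC across subjects (algorithm and manual as the two raters)
#' with its confidence interval and reliability band, plus the
#' suboptimal-placement flags: a placement is suboptimal when the
#' algorithm perfusion deviates more than 10 % from the manual value.
#' Unmatched keys are listed and excluded with a warning; cells with
#' fewer than 2 complete subjects are skipped.
#'
#' @param algorithmSummaries,manualSummaries data.frames with columns
#'   \code{subject}, \code{roi}, \code{toi}, \code{mean_pu}.
#' @param confLevel confidence level for the ICC intervals.
#' @return list (class \code{lsciValidation}): \code{icc} data.frame (roi,
#'   toi, n_subjects, icc, ci_low, ci_high, p, band), \code{flags}
#'   data.frame per pair, \code{suboptimalRate}, \code{nPlacements}.
#' @export
validateAgainstManual <- function(algorithmSummaries, manualSummaries,
                                  confLevel = 0.95) {
  need <- c("subject", "roi", "toi", "mean_pu")
  for (nm in need) {
    if (!nm %in% names(algorithmSummaries) || !nm %in% names(manualSummaries))
      stopf("summaries need columns %s", paste(need, collapse = ", "))
  }
  key <- function(d) paste(d$subject, d$roi, d$toi, sep = "\r")
  ka <- key(algorithmSummaries); km <- key(manualSummaries)
  unmatched <- c(setdiff(ka, km), setdiff(km, ka))
  if (length(unmatched))
    warnf("%d unmatched (subject, roi, toi) key(s) excluded from validation",
          length(unmatched))
  common <- intersect(ka, km)
  alg <- algorithmSummaries[match(common, ka), ]
  man <- manualSummaries[match(common, km), ]

  pairs <- data.frame(subject = alg$subject, roi = alg$roi, toi = alg$toi,
                      algorithm_pu = alg$mean_pu, manual_pu = man$mean_pu)
  fl <- flagSuboptimal(pairs$algorithm_pu, pairs$manual_pu)
  pairs$suboptimal <- fl$flags

  cells <- unique(pairs[, c("roi", "toi")])
  iccRows <- list()
  for (i in seq_len(nrow(cells))) {
    sel <- pairs$roi == cells$roi[i] & pairs$toi == cells$toi[i]
    sub <- pairs[sel & !is.na(pairs$algorithm_pu) & !is.na(pairs$manual_pu), ]
    if (nrow(sub) < 2L) {
      warnf("cell (%s, %s): fewer than 2 complete subjects, skipped",
            cells$roi[i], cells$toi[i])
      next
    }
    res <- iccAbsoluteAgreement(cbind(algorithm = sub$algorithm_pu,
                                      manual = sub$manual_pu), confLevel)
    iccRows[[length(iccRows) + 1L]] <- data.frame(
      roi = cells$roi[i], toi = cells$toi[i], n_subjects = nrow(sub),
      icc = res@icc, ci_low = res@ciLow, ci_high = res@ciHigh,
      p = res@pValue, band = classifyReliability(res@icc))
  }
  out <- list(icc = do.call(rbind, iccRows), flags = pairs,
              suboptimalRate = fl$rate,
              nPlacements = nrow(pairs))
  class(out) <- "lsciValidation"
  out
}

#' @export
print.lsciValidation <- function(x, ...) {
  cat(sprintf("LSCI validation: %d placement(s), %.1f%% suboptimal (> 10%% off manual)\n",
              x$nPlacements, 100 * x$suboptimalRate))
  if (!is.null(x$icc)) {
    cat(sprintf("  ICC range [%.3f, %.3f]; bands: %s\n",
                min(x$icc$icc), max(x$icc$icc),
                paste(sprintf("%s=%d", names(table(x$icc$band)),
                              as.integer(table(x$icc$band))), collapse = ", ")))
  }
  invisible(x)
}

#' Write the validation report as CSV
#' @param validation result of [validateAgainstManual()].
#' @param dir output directory.
#' @export
writeValidationCsv <- function(validation, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(validation$icc, file.path(dir, "icc_report.csv"), row.names = FALSE)
  write.csv(validation$flags, file.path(dir, "suboptimal_flags.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' Simulate and analyze a cohort of recordings
#'
#' Generates \code{n} seeded scenario recordings, runs [runAnalysis()] on
#' each, and stacks the per-recording TOI summaries with a subject id —
#' the bookkeeping surface: n recordings x 4 ROIs x 3 TOIs placements.
#'
#' @param n number of recordings.
#' @param seed base seed; recording i uses seed + i.
#' @param ... passed to [simulateScenario()].
#' @return data.frame with columns subject, roi, toi, mean_pu, n_valid.
#' @export
simulateCohortSummaries <- function(n, seed = 1, ...) {
  out <- vector("list", n)
  for (i in seq_len(n)) {
    sc <- simulateScenario(seed = seed + i, ...)
    res <- suppressWarnings(
      runAnalysis(sc$recording, sc$initialRois, sc$calibration,
                  buergerRois = sc$buergerRois, region = sc$region))
    s <- res$toiSummary
    s$subject <- i
    out[[i]] <- s[, c("subject", "roi", "toi", "mean_pu", "n_valid")]
  }
  do.call(rbind, out)
}
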