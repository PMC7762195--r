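#' Per-frame, per-ROI perfusion trace
#'
#' A \code{SummarizedExperiment} with ROIs as rows and frames as columns.
#' Assays: \code{perfusion} (PU), \code{contrast} (dimensionless K) and
#' \code{valid_pixels} (count entering each statistic). \code{colData}
#' holds the frame index, the timestamp and (after [segmentTois()] /
#' [assignTois()]) the TOI label of each frame. \code{metadata} carries
#' the calibration constants, the sigma convention, the protocol and the
#' count of K > 1 observations (negative perfusions, flagged but not
#' clipped).
#'
#' @export
setClass("PerfusionTrace", contains = "SummarizedExperiment")

newPerfusionTrace <- function(perfusion, contrast, validPixels, times,
                              protocol = NULL, calibration = NULL) {
  cd <- S4Vectors::DataFrame(frame = seq_len(ncol(perfusion)),
                             time_s = times,
                             toi = NA_character_)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(perfusion = perfusion, contrast = contrast,
                  valid_pixels = validPixels),
    rowData = S4Vectors::DataFrame(label = rownames(perfusion)),
    colData = cd)
  S4Vectors::metadata(se) <- list(
    calibration = calibration,
    protocol = protocol,
    sigma_convention = if (!is.null(calibration)) calibration@sigmaConvention
                       else "population",
    n_contrast_above_one = sum(contrast > 1, na.rm = TRUE))
  as(se, "PerfusionTrace")
}

#' @rdname PerfusionTrace-class
#' @param object a \code{PerfusionTrace}.
#' @return \code{perfusion()}: the ROI x frame perfusion matrix (PU).
#' @export
perfusion <- function(object) SummarizedExperiment::assay(object, "perfusion")

#' @rdname PerfusionTrace-class
#' @export
speckleContrast <- function(object) SummarizedExperiment::assay(object, "contrast")

#' @rdname PerfusionTrace-class
#' @export
roiLabels <- function(object) SummarizedExperiment::rowData(object)$label

setMethod("show", "PerfusionTrace", function(object) {
  P <- perfusion(object)
  cat(sprintf("PerfusionTrace: %d ROI(s) x %d frame(s); %.1f%% missing; %d frame(s) with K > 1\n",
              nrow(P), ncol(P), 100 * mean(is.na(P)),
              S4Vectors::metadata(object)$n_contrast_above_one))
  rng <- range(P, na.rm = TRUE)
  cat(sprintf("  perfusion range [%.1f, %.1f] PU; ROIs: %s\n",
              rng[1], rng[2], paste(roiLabels(object), collapse = ", ")))
})

#' Write a perfusion trace as tidy CSV
#'
#' Long format: frame, time_s, roi_label, perfusion_pu, contrast,
#' valid_pixels, toi. UTF-8, header row, '.' decimal.
#'
#' @param trace a [PerfusionTrace-class].
#' @param path output CSV path.
#' @export
writeTraceCsv <- function(trace, path) {
  P <- perfusion(trace)
  K <- speckleContrast(trace)
  npx <- SummarizedExperiment::assay(trace, "valid_pixels")
  cd <- SummarizedExperiment::colData(trace)
  out <- data.frame(
    frame = rep(cd$frame, each = nrow(P)),
    time_s = rep(cd$time_s, each = nrow(P)),
    roi_label = rep(roiLabels(trace), times = ncol(P)),
    perfusion_pu = as.vector(P),
    contrast = as.vector(K),
    valid_pixels = as.vector(npx),
    toi = rep(cd$toi, each = nrow(P)))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
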