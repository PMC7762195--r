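# Speckle contrast -> perfusion conversion and two-point calibration.
# Coordinate convention: see utils.R.

#' ROI intensity statistics
#'
#' Mean intensity, population standard deviation and pixel count over the
#' valid pixels of a region. These are the sufficient statistics of the
#' contrast computation.
#'
#' @param values numeric vector of pixel intensities (NAs dropped).
#' @return list with \code{mean_intensity}, \code{std_intensity},
#'   \code{pixel_count}.
#' @export
roiStats <- function(values) {
  values <- values[!is.na(values)]
  list(mean_intensity = if (length(values)) mean(values) else NA_real_,
       std_intensity = if (length(values)) popSd(values) else NA_real_,
       pixel_count = length(values))
}

#' Speckle contrast of a region
#'
#' The (beta-corrected) speckle contrast \eqn{K = \beta \, \sigma / \langle
#' I \rangle}: the ratio of the intensity standard deviation to the mean
#' intensity over a region, scaled by the instrument's coherence factor so
#' that a static object yields K = 1. Lower K means more motion (more
#' blood flow) within the camera exposure.
#'
#' @param stats ROI statistics as returned by [roiStats()].
#' @param beta coherence factor (> 0), see [Calibration-class].
#' @param label optional ROI label used in error messages.
#' @return dimensionless contrast K >= 0.
#' @examples
#' roiContrast(roiStats(c(2, 4, 6)), beta = 1)
#' @export
roiContrast <- function(stats, beta, label = "ROI") {
  if (!is.finite(beta) || beta <= 0) stopf("beta must be positive")
  if (!is.finite(stats$mean_intensity) || stats$mean_intensity <= 0)
    stopf("invalid mean intensity in %s: must be positive", label)
  if (stats$std_intensity < 0) stopf("negative intensity sd in %s", label)
  beta * stats$std_intensity / stats$mean_intensity
}

#' Perfusion from speckle contrast
#'
#' The Perimed-style contrast-to-perfusion mapping \eqn{P = k (1/K - 1)}
#' with k the instrument's signal gain. K = 1 (static object) maps to
#' 0 PU and P is strictly decreasing in K. Noisy regions can measure
#' K > 1, which yields a negative perfusion; such values are deliberately
#' not clipped (clipping would bias TOI means upward) and are counted in
#' the trace diagnostics instead.
#'
#' @param K speckle contrast, > 0 (vectorized).
#' @param gain signal gain in PU.
#' @return perfusion in PU.
#' @examples
#' contrastToPerfusion(0.5, gain = 10) # 10 PU
#' @export
contrastToPerfusion <- function(K, gain) {
  if (!is.finite(gain) || gain <= 0) stopf("gain must be positive")
  bad <- !is.na(K) & K <= 0
  if (any(bad)) stopf("invalid contrast: K must be positive (got %g)", K[bad][1])
  gain * (1 / K - 1)
}

#' Contrast from perfusion (analytic inverse)
#'
#' Inverts the perfusion mapping: \eqn{K = k / (P + k)}. Used by the
#' speckle simulator to derive the contrast target for a pixel of known
#' perfusion; round-trips with [contrastToPerfusion()] to floating
#' precision.
#'
#' @param P perfusion in PU, >= 0 (vectorized).
#' @param gain signal gain in PU.
#' @return contrast K in (0, 1].
#' @export
perfusionToContrast <- function(P, gain) {
  if (!is.finite(gain) || gain <= 0) stopf("gain must be positive")
  bad <- !is.na(P) & P < 0
  if (any(bad)) stopf("negative perfusion %g has no contrast", P[bad][1])
  gain / (P + gain)
}

#' Two-point instrument calibration
#'
#' Fits the coherence factor and signal gain from measurements of a
#' zero-perfusion (static) target and a motility standard. The coherence
#' factor is \eqn{\beta = \langle I \rangle / \sigma} of the static target,
#' which forces its contrast to exactly 1 (hence 0 PU); the gain then
#' solves \eqn{P = k (1/K - 1)} so that the standard measures exactly
#' \code{referencePerfusion} PU.
#'
#' @param staticStats [roiStats()] of the zero-perfusion target.
#' @param standardStats [roiStats()] of the motility standard.
#' @param referencePerfusion PU assigned to the standard (default 250).
#' @return a [Calibration-class] object.
#' @examples
#' cal <- calibrate(list(mean_intensity = 1,  std_intensity = 0.8, pixel_count = 4096),
#'                  list(mean_intensity = 1,  std_intensity = 0.4, pixel_count = 4096))
#' coherenceFactor(cal)  # 1.25
#' signalGain(cal)       # 250
#' @export
calibrate <- function(staticStats, standardStats, referencePerfusion = 250) {
  if (!is.finite(staticStats$mean_intensity) || staticStats$mean_intensity <= 0 ||
      !is.finite(staticStats$std_intensity) || staticStats$std_intensity <= 0)
    stopf("static target needs positive mean and sd intensity")
  beta <- staticStats$mean_intensity / staticStats$std_intensity
  Kstd <- roiContrast(standardStats, beta, "motility standard")
  if (Kstd >= 1)
    stopf(paste("calibration failure: motility standard contrast %.4f >= 1;",
                "the standard is not distinguishable from a static target"), Kstd)
  gain <- referencePerfusion / (1 / Kstd - 1)
  Calibration(beta = beta, gain = gain,
              referencePerfusion = referencePerfusion)
}

# Minimum valid pixels for a stable sigma estimate; below this the
# frame/ROI perfusion is reported as missing.
MIN_ROI_PIXELS <- 25L

#' Per-frame, per-ROI perfusion trace
#'
#' Applies the contrast and perfusion equations to every ROI of every
#' frame of a recording: for each frame, pixel statistics are computed over
#' the intersection of the (tracked) ellipse mask with the frame's validity
#' mask — background pixels never enter the statistics — and converted to
#' perfusion with the supplied calibration. An ROI whose valid-pixel count
#' falls below \code{minPixels} on some frame yields a missing value for
#' that frame (with one summary warning), never an error.
#'
#' @param recording a [Recording-class].
#' @param roiSequence either a single ROI list applied to every frame or a
#'   list of per-frame ROI lists (e.g. [roiSets()] of a tracking result);
#'   all frames must share the same labels in the same order.
#' @param calibration a [Calibration-class].
#' @param minPixels minimum valid pixels per ROI per frame (default 25).
#' @return a [PerfusionTrace-class] (a \code{SummarizedExperiment} with
#'   assays \code{perfusion}, \code{contrast} and \code{valid_pixels};
#'   ROIs as rows, frames as columns). \code{metadata()} carries the
#'   calibration, the sigma convention and a count of K > 1 frames.
#' @export
perfusionTrace <- function(recording, roiSequence, calibration,
                           minPixels = MIN_ROI_PIXELS) {
  n <- nFrames(recording)
  perFrame <- is.list(roiSequence) && length(roiSequence) &&
    is.list(roiSequence[[1]]) && !is(roiSequence[[1]], "EllipseROI")
  if (!perFrame) roiSequence <- rep(list(roiSequence), n)
  if (length(roiSequence) != n)
    stopf("roiSequence has %d ROI sets for %d frames", length(roiSequence), n)
  labels <- vapply(roiSequence[[1]], roiLabel, character(1))
  shape <- dim(recording@frames)[1:2]

  P <- K <- matrix(NA_real_, length(labels), n,
                   dimnames = list(labels, NULL))
  npx <- matrix(0L, length(labels), n, dimnames = list(labels, NULL))
  starved <- 0L
  for (f in seq_len(n)) {
    img <- getFrame(recording, f)
    valid <- getValidity(recording, f)
    rois <- roiSequence[[f]]
    for (r in seq_along(rois)) {
      mask <- rasterizeEllipse(rois[[r]], shape, valid)
      vals <- img[mask]
      st <- roiStats(vals)
      npx[r, f] <- st$pixel_count
      if (st$pixel_count < minPixels || !is.finite(st$mean_intensity) ||
          st$mean_intensity <= 0 || st$std_intensity <= 0) {
        starved <- starved + 1L
        next
      }
      K[r, f] <- roiContrast(st, coherenceFactor(calibration), labels[r])
      P[r, f] <- contrastToPerfusion(K[r, f], signalGain(calibration))
    }
  }
  if (starved > 0L)
    warnf("%d ROI-frame(s) below the %d valid-pixel threshold: reported as missing",
          starved, minPixels)
  newPerfusionTrace(perfusion = P, contrast = K, validPixels = npx,
                    times = frameTimes(recording),
                    protocol = protocol(recording),
                    calibration = calibration)
}
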