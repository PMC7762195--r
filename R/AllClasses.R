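#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom stats filter qf pf rgamma runif rnorm median setNames aggregate
#' @importFrom utils write.csv read.csv
NULL

# ---------------------------------------------------------------------------
# Rigid 2D transforms

#' Rigid 2D transform (rotation + translation)
#'
#' A rigid-body motion of the image plane: a counter-clockwise rotation
#' about the coordinate origin followed by a translation. This is the exact
#' class of motion the tracker estimates between the reference frame and
#' every later frame of a recording: no scaling, no reflection.
#'
#' @slot rotation rotation angle in radians, wrapped to (-pi, pi].
#' @slot translation numeric length-2 translation (tx, ty) in pixels.
#' @export
setClass("RigidTransform2D",
  representation(rotation = "numeric", translation = "numeric"),
  prototype(rotation = 0, translation = c(0, 0)))

setValidity("RigidTransform2D", function(object) {
  if (length(object@rotation) != 1L || !is.finite(object@rotation))
    return("rotation must be a single finite angle")
  if (object@rotation <= -pi || object@rotation > pi + 1e-12)
    return("rotation must lie in (-pi, pi]")
  if (length(object@translation) != 2L || !all(is.finite(object@translation)))
    return("translation must be two finite numbers (tx, ty)")
  TRUE
})

#' @rdname RigidTransform2D-class
#' @param rotation rotation angle in radians (wrapped into (-pi, pi]).
#' @param translation numeric length-2 (tx, ty), pixels.
#' @return a \code{RigidTransform2D}.
#' @examples
#' t1 <- RigidTransform2D(pi / 6, c(5, -3))
#' applyTransform(t1, cbind(10, 0))
#' @export
RigidTransform2D <- function(rotation = 0, translation = c(0, 0)) {
  new("RigidTransform2D", rotation = wrapAngle(rotation),
      translation = as.numeric(translation))
}

setMethod("show", "RigidTransform2D", function(object) {
  cat(sprintf("RigidTransform2D: rotation %.4f rad (%.2f deg), translation (%.3f, %.3f) px\n",
              object@rotation, object@rotation * 180 / pi,
              object@translation[1], object@translation[2]))
})

# ---------------------------------------------------------------------------
# Ellipse ROIs

#' Elliptical region of interest
#'
#' An ellipse in pixel coordinates, labelled by the anatomical region it
#' covers. Clinically the four standard regions are the ulcer, the ulcer
#' edge, the toe and the whole foot, but any non-empty label is accepted.
#'
#' @slot label region label, e.g. "ulcer", "ulcer_edge", "toe", "foot".
#' @slot center numeric (x, y), pixel coordinates of the ellipse center.
#' @slot semiAxes numeric (a, b), semi-axis lengths in pixels, both > 0.
#' @slot orientation angle of the first axis, radians counter-clockwise
#'   from the +x axis.
#' @export
setClass("EllipseROI",
  representation(label = "character", center = "numeric",
                 semiAxes = "numeric", orientation = "numeric"))

setValidity("EllipseROI", function(object) {
  if (length(object@label) != 1L || !nzchar(object@label))
    return("label must be a single non-empty string")
  if (length(object@center) != 2L || !all(is.finite(object@center)))
    return("center must be two finite pixel coordinates (x, y)")
  if (length(object@semiAxes) != 2L || !all(object@semiAxes > 0))
    return("semi-axes must be two positive lengths (a, b)")
  if (length(object@orientation) != 1L || !is.finite(object@orientation))
    return("orientation must be a single finite angle")
  TRUE
})

#' @rdname EllipseROI-class
#' @param label,center,semiAxes,orientation see slots.
#' @return an \code{EllipseROI}.
#' @export
EllipseROI <- function(label, center, semiAxes, orientation = 0) {
  new("EllipseROI", label = as.character(label), center = as.numeric(center),
      semiAxes = as.numeric(semiAxes), orientation = as.numeric(orientation))
}

setMethod("show", "EllipseROI", function(object) {
  cat(sprintf("EllipseROI '%s': center (%.2f, %.2f), semi-axes (%.2f, %.2f), orientation %.3f rad\n",
              object@label, object@center[1], object@center[2],
              object@semiAxes[1], object@semiAxes[2], object@orientation))
})

#' @rdname EllipseROI-class
#' @param object an \code{EllipseROI}.
#' @export
roiLabel <- function(object) object@label

# ---------------------------------------------------------------------------
# Calibration

#' Instrument calibration constants
#'
#' The two instrument constants of the contrast-to-perfusion conversion:
#' the coherence factor beta, which rescales raw speckle contrast so that a
#' static object measures K = 1, and the signal gain k, which maps contrast
#' to perfusion units via P = k (1/K - 1). Both are obtained by a two-point
#' calibration against a zero-perfusion target and a motility standard
#' (a colloidal suspension of polystyrene particles assigned
#' \code{referencePerfusion} PU, conventionally 250).
#'
#' @slot beta dimensionless coherence factor, > 0.
#' @slot gain signal gain in perfusion units, > 0.
#' @slot referencePerfusion PU value assigned to the motility standard.
#' @slot sigmaConvention standard-deviation convention used throughout
#'   ("population", i.e. divide by N).
#' @export
setClass("Calibration",
  representation(beta = "numeric", gain = "numeric",
                 referencePerfusion = "numeric", sigmaConvention = "character"),
  prototype(sigmaConvention = "population"))

setValidity("Calibration", function(object) {
  if (length(object@beta) != 1L || !is.finite(object@beta) || object@beta <= 0)
    return("beta (coherence factor) must be a single positive number")
  if (length(object@gain) != 1L || !is.finite(object@gain) || object@gain <= 0)
    return("gain (signal gain) must be a single positive number")
  if (object@referencePerfusion <= 0)
    return("referencePerfusion must be positive")
  TRUE
})

#' @rdname Calibration-class
#' @param beta,gain,referencePerfusion see slots.
#' @return a \code{Calibration}.
#' @export
Calibration <- function(beta, gain, referencePerfusion = 250) {
  new("Calibration", beta = as.numeric(beta), gain = as.numeric(gain),
      referencePerfusion = as.numeric(referencePerfusion))
}

setMethod("show", "Calibration", function(object) {
  cat(sprintf("Calibration: beta = %.5f, gain = %.3f PU, reference = %g PU (%s sigma)\n",
              object@beta, object@gain, object@referencePerfusion,
              object@sigmaConvention))
})

#' @rdname Calibration-class
#' @param object a \code{Calibration}.
#' @export
coherenceFactor <- function(object) object@beta

#' @rdname Calibration-class
#' @export
signalGain <- function(object) object@gain

#' @rdname Calibration-class
#' @export
referencePerfusion <- function(object) object@referencePerfusion

# ---------------------------------------------------------------------------
# Protocol

#' Recording protocol annotations
#'
#' Operator-supplied annotations that anchor the timespans of interest
#' (TOIs): the baseline window, the frame at which the arterial occlusion
#' cuff is released (the post-occlusive reactive hyperemia peak is searched
#' after this frame), and the Buerger's-test window. The cuff event is
#' external to the image and is therefore annotated, never auto-detected.
#' \code{breakFrames} marks frames where the recording pauses (e.g. while
#' the foot is repositioned for the Buerger's test); no TOI may span a
#' break.
#'
#' @slot baselineWindow integer (first, last) frame of the baseline TOI.
#' @slot releaseFrame frame index of the occlusion release.
#' @slot buergerWindow integer (first, last) frame of the Buerger TOI, or
#'   \code{c(NA, NA)} when the recording has no Buerger segment.
#' @slot frameRate frames per second.
#' @slot breakFrames integer frame indices at which the recording pauses.
#' @export
setClass("Protocol",
  representation(baselineWindow = "integer", releaseFrame = "integer",
                 buergerWindow = "integer", frameRate = "numeric",
                 breakFrames = "integer"),
  prototype(frameRate = 1, breakFrames = integer(0)))

setValidity("Protocol", function(object) {
  bw <- object@baselineWindow
  if (length(bw) != 2L || any(bw < 1L) || bw[2] < bw[1])
    return("baselineWindow must be an increasing pair of frame indices")
  if (length(object@releaseFrame) != 1L || is.na(object@releaseFrame))
    return("releaseFrame must be a single frame index")
  if (object@releaseFrame < bw[2])
    return("occlusion release must come after the baseline window")
  gw <- object@buergerWindow
  if (length(gw) != 2L)
    return("buergerWindow must have two elements (use c(NA, NA) for none)")
  if (!any(is.na(gw))) {
    if (gw[2] < gw[1]) return("buergerWindow must be increasing")
    if (gw[1] <= object@releaseFrame)
      return("Buerger window must follow the occlusion release")
  }
  if (object@frameRate <= 0) return("frameRate must be positive")
  TRUE
})

#' @rdname Protocol-class
#' @param baselineWindow,releaseFrame,buergerWindow,frameRate,breakFrames
#'   see slots.
#' @return a \code{Protocol}.
#' @export
Protocol <- function(baselineWindow, releaseFrame,
                     buergerWindow = c(NA, NA), frameRate = 1,
                     breakFrames = integer(0)) {
  new("Protocol", baselineWindow = as.integer(baselineWindow),
      releaseFrame = as.integer(releaseFrame),
      buergerWindow = as.integer(buergerWindow),
      frameRate = as.numeric(frameRate),
      breakFrames = as.integer(breakFrames))
}

setMethod("show", "Protocol", function(object) {
  gw <- if (any(is.na(object@buergerWindow))) "none"
        else sprintf("[%d, %d]", object@buergerWindow[1], object@buergerWindow[2])
  cat(sprintf("Protocol: baseline [%d, %d], release at %d, Buerger %s, %g fps\n",
              object@baselineWindow[1], object@baselineWindow[2],
              object@releaseFrame, gw, object@frameRate))
  if (length(object@breakFrames))
    cat("  breaks after frames:", paste(object@breakFrames, collapse = ", "), "\n")
})

hasBuerger <- function(protocol) !any(is.na(protocol@buergerWindow))

setClassUnion("ProtocolOrNULL", c("Protocol", "NULL"))

# ---------------------------------------------------------------------------
# Recording

#' An LSCI recording
#'
#' A time-ordered stack of single-channel intensity frames together with a
#' per-frame validity mask (background pixels are invalid and never enter
#' perfusion statistics), frame timestamps and optional protocol
#' annotations. Intensities are linear arbitrary units; no bit-depth
#' rescaling is applied beyond the cast to double.
#'
#' @slot frames numeric array H x W x n (rows = y, columns = x).
#' @slot validity logical array H x W x n; FALSE marks background.
#' @slot times numeric timestamps, seconds, one per frame.
#' @slot protocol a \code{Protocol} or NULL.
#' @export
setClass("Recording",
  representation(frames = "array", validity = "array", times = "numeric",
                 protocol = "ProtocolOrNULL"))

setValidity("Recording", function(object) {
  d <- dim(object@frames)
  if (length(d) != 3L) return("frames must be an H x W x n array")
  if (!identical(dim(object@validity), d))
    return("validity mask must match frame dimensions")
  if (!is.logical(object@validity)) return("validity must be logical")
  if (length(object@times) != d[3]) return("one timestamp per frame required")
  if (is.unsorted(object@times)) return("frame times must be non-decreasing")
  TRUE
})

#' @rdname Recording-class
#' @param frames H x W x n array (a matrix is promoted to one frame).
#' @param validity logical mask; a single H x W matrix is recycled across
#'   frames; default all-valid.
#' @param times frame timestamps in seconds (default 0, 1, 2, ...).
#' @param protocol optional \code{Protocol}.
#' @return a \code{Recording}.
#' @export
Recording <- function(frames, validity = NULL, times = NULL, protocol = NULL) {
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  d <- dim(frames)
  if (is.null(validity)) validity <- array(TRUE, d)
  if (is.matrix(validity)) validity <- array(rep(validity, d[3]), d)
  if (is.null(times)) times <- seq_len(d[3]) - 1
  new("Recording", frames = frames, validity = array(as.logical(validity), d),
      times = as.numeric(times), protocol = protocol)
}

#' @rdname Recording-class
#' @param object a \code{Recording}.
#' @export
nFrames <- function(object) dim(object@frames)[3]

#' @rdname Recording-class
#' @param i frame index.
#' @export
getFrame <- function(object, i) object@frames[, , i]

#' @rdname Recording-class
#' @export
getValidity <- function(object, i) object@validity[, , i]

#' @rdname Recording-class
#' @export
frameTimes <- function(object) object@times

#' @rdname Recording-class
#' @export
protocol <- function(object) object@protocol

setMethod("show", "Recording", function(object) {
  d <- dim(object@frames)
  cat(sprintf("Recording: %d frame(s) of %d x %d px, %.1f%% valid pixels\n",
              d[3], d[1], d[2], 100 * mean(object@validity)))
  if (!is.null(object@protocol)) show(object@protocol)
})

# ---------------------------------------------------------------------------
# Tracking result

#' Result of ROI tracking across a recording
#'
#' Per-frame rigid transforms (reference frame to frame n), the propagated
#' ROI sets, and registration diagnostics. The transform of each reference
#' frame (frame 1, and the first Buerger frame when the protocol includes a
#' Buerger segment) is the identity relative to that frame's own ROI set.
#'
#' @slot transforms list of \code{RigidTransform2D}, one per frame.
#' @slot roiSets list (one per frame) of lists of \code{EllipseROI}.
#' @slot diagnostics data.frame with one row per frame: frame,
#'   reference_frame, rotation_deg, tx, ty, rms, iterations, converged,
#'   carried_forward.
#' @export
setClass("TrackingResult",
  representation(transforms = "list", roiSets = "list",
                 diagnostics = "data.frame"))

setValidity("TrackingResult", function(object) {
  n <- length(object@transforms)
  if (length(object@roiSets) != n) return("one ROI set per frame required")
  if (nrow(object@diagnostics) != n) return("one diagnostics row per frame required")
  TRUE
})

#' @rdname TrackingResult-class
#' @param object a \code{TrackingResult}.
#' @export
transforms <- function(object) object@transforms

#' @rdname TrackingResult-class
#' @export
roiSets <- function(object) object@roiSets

#' @rdname TrackingResult-class
#' @export
trackingDiagnostics <- function(object) object@diagnostics

setMethod("show", "TrackingResult", function(object) {
  d <- object@diagnostics
  cat(sprintf("TrackingResult: %d frame(s), %d converged, %d carried forward\n",
              nrow(d), sum(d$converged), sum(d$carried_forward)))
  cat(sprintf("  max |rotation| %.2f deg, max |translation| %.2f px, max RMS %.3f px\n",
              max(abs(d$rotation_deg)), max(abs(c(d$tx, d$ty))),
              max(d$rms, na.rm = TRUE)))
})

# ---------------------------------------------------------------------------
# ICC result

#' Intraclass correlation result
#'
#' Single-measures ICC from the two-way random-effects, absolute-agreement
#' model (ICC(2,1) / ICC(A,1)), with the F test of the subject effect and
#' the F-based confidence interval.
#'
#' @slot icc point estimate, in (-1, 1].
#' @slot model model descriptor string.
#' @slot fstat,df1,df2,pValue F test of between-subject variance.
#' @slot ciLow,ciHigh confidence bounds.
#' @slot nSubjects,nRaters matrix dimensions.
#' @slot confLevel confidence level of the interval.
#' @export
setClass("IccResult",
  representation(icc = "numeric", model = "character", fstat = "numeric",
                 df1 = "numeric", df2 = "numeric", pValue = "numeric",
                 ciLow = "numeric", ciHigh = "numeric",
                 nSubjects = "integer", nRaters = "integer",
                 confLevel = "numeric"))

setValidity("IccResult", function(object) {
  if (object@icc > 1 + 1e-12) return("ICC cannot exceed 1")
  if (!is.na(object@ciLow) && !is.na(object@ciHigh) &&
      (object@icc < object@ciLow - 1e-9 || object@icc > object@ciHigh + 1e-9))
    return("confidence interval must contain the point estimate")
  TRUE
})

#' @rdname IccResult-class
#' @param object an \code{IccResult}.
#' @export
iccValue <- function(object) object@icc

setMethod("show", "IccResult", function(object) {
  cat(sprintf("ICC = %.4f (%s), %d subjects x %d raters\n",
              object@icc, object@model, object@nSubjects, object@nRaters))
  cat(sprintf("  F(%g, %g) = %.3f, p = %.4g, %d%% CI [%.4f, %.4f] -> %s reliability\n",
              object@df1, object@df2, object@fstat, object@pValue,
              round(100 * object@confLevel), object@ciLow, object@ciHigh,
              classifyReliability(object@icc)))
})

# ---------------------------------------------------------------------------
# Foot phantom (synthetic ground truth)

#' Synthetic foot phantom
#'
#' A foot-shaped silhouette with a known per-pixel perfusion map (plantar
#' base level, toe, ulcer hotspot and ulcer-edge ring), ground-truth ellipse
#' ROIs placed on homogeneous patches of each region, and optional static
#' bright artifact boxes outside the silhouette (emulating an examination
#' bench). Everything the tracker and the perfusion pipeline estimate on a
#' simulated recording can be compared against this object.
#'
#' @slot shapeMask logical H x W silhouette.
#' @slot perfusionMap numeric H x W perfusion in PU (0 outside the foot).
#' @slot rois list of ground-truth \code{EllipseROI} (ulcer, ulcer_edge,
#'   toe, foot).
#' @slot artifactBoxes list of half-open pixel boxes (x0, y0, x1, y1) with
#'   static bright content.
#' @slot regionLevels named numeric, configured PU per region.
#' @export
setClass("FootPhantom",
  representation(shapeMask = "matrix", perfusionMap = "matrix",
                 rois = "list", artifactBoxes = "list",
                 regionLevels = "numeric"))

setValidity("FootPhantom", function(object) {
  if (!identical(dim(object@shapeMask), dim(object@perfusionMap)))
    return("shape mask and perfusion map must have identical dimensions")
  if (any(object@perfusionMap < 0)) return("perfusion map must be non-negative")
  if (any(object@perfusionMap[!object@shapeMask] != 0))
    return("perfusion must be zero outside the silhouette")
  TRUE
})

setMethod("show", "FootPhantom", function(object) {
  d <- dim(object@shapeMask)
  cat(sprintf("FootPhantom: %d x %d px, %d ROI(s), %d artifact box(es)\n",
              d[1], d[2], length(object@rois), length(object@artifactBoxes)))
  cat("  region levels (PU):",
      paste(sprintf("%s=%g", names(object@regionLevels), object@regionLevels),
            collapse = ", "), "\n")
})
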