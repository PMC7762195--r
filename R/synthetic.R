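# Synthetic LSCI recordings with known ground truth: a foot-shaped
# phantom with per-region perfusion, a gamma speckle sampler reproducing
# any target contrast, rigid motion trajectories, and calibration-target
# recordings. Everything is seeded and bit-reproducible.
# Coordinate convention: see utils.R.

#' Build a synthetic foot phantom
#'
#' A superellipse sole with five attached toe discs, an ulcer disc with a
#' hyperemic edge ring on the plantar surface, and four ground-truth
#' ellipse ROIs (ulcer, ulcer_edge, toe, foot), each placed on a
#' homogeneous patch of its region so that the ROI's true mean perfusion
#' equals the configured level exactly. Optional static bright artifact
#' boxes outside the silhouette emulate an examination bench. Deterministic:
#' the geometry is parametric, with no random element.
#'
#' @param scale geometry scale factor; scale 1 gives a 200 x 150 px image.
#' @param perfusionLevels named PU levels for \code{foot}, \code{toe},
#'   \code{ulcer}, \code{ulcer_edge}.
#' @param artifacts add static artifact boxes outside the silhouette?
#' @return a [FootPhantom-class].
#' @examples
#' ph <- makeFootPhantom(scale = 0.75)
#' ph
#' @export
makeFootPhantom <- function(scale = 1,
                            perfusionLevels = c(foot = 80, toe = 100,
                                                ulcer = 40, ulcer_edge = 120),
                            artifacts = TRUE) {
  need <- c("foot", "toe", "ulcer", "ulcer_edge")
  if (!all(need %in% names(perfusionLevels)))
    stopf("perfusionLevels needs entries %s", paste(need, collapse = ", "))
  if (any(perfusionLevels < 0)) stopf("perfusion levels must be >= 0")
  H <- round(200 * scale); W <- round(165 * scale)
  if (H < 40 || W < 30) stopf("scale %.2f too small for the silhouette", scale)
  s <- scale
  xs <- matrix(rep(seq_len(W), each = H), H, W)
  ys <- matrix(rep(seq_len(H), times = W), H, W)

  # sole: superellipse, exponent 2.5
  soleC <- c(75, 115) * s; soleAx <- c(45, 70) * s
  sole <- (abs(xs - soleC[1]) / soleAx[1])^2.5 +
          (abs(ys - soleC[2]) / soleAx[2])^2.5 <= 1
  # toes: hallux + four lesser toes, overlapping the sole top
  toeSpec <- list(c(50, 50, 12), c(68, 42, 8), c(82, 42, 7),
                  c(94, 46, 6), c(104, 52, 5))
  toes <- matrix(FALSE, H, W)
  for (tc in toeSpec)
    toes <- toes | ((xs - tc[1] * s)^2 + (ys - tc[2] * s)^2 <= (tc[3] * s)^2)
  shape <- sole | toes

  # ulcer disc and edge ring on the plantar surface
  ulcC <- c(75, 140) * s
  dUlc <- sqrt((xs - ulcC[1])^2 + (ys - ulcC[2])^2)
  ulcer <- dUlc <= 9 * s
  ring <- dUlc > 9 * s & dUlc <= 16 * s

  pmap <- matrix(0, H, W)
  pmap[shape] <- perfusionLevels[["foot"]]
  pmap[toes & shape] <- perfusionLevels[["toe"]]
  pmap[ring] <- perfusionLevels[["ulcer_edge"]]
  pmap[ulcer] <- perfusionLevels[["ulcer"]]
  pmap[!shape] <- 0

  rois <- list(
    EllipseROI("ulcer", ulcC, c(8, 8) * s),
    EllipseROI("ulcer_edge", c(75, 152.5) * s, c(8, 2.8) * s, orientation = 0),
    EllipseROI("toe", c(50, 50) * s, c(7, 7) * s),
    EllipseROI("foot", c(95, 90) * s, c(12, 9) * s))

  boxes <- list()
  if (artifacts)
    boxes <- list(list(x0 = round(142 * s), y0 = round(20 * s),
                       x1 = round(160 * s), y1 = round(190 * s)))

  new("FootPhantom", shapeMask = shape, perfusionMap = pmap, rois = rois,
      artifactBoxes = boxes, regionLevels = perfusionLevels)
}

#' Artifact-free region of a phantom
#'
#' The half-open pixel box excluding the phantom's static artifact boxes
#' (everything left of the leftmost artifact), i.e. what an operator would
#' select once on frame 1.
#'
#' @param phantom a [FootPhantom-class].
#' @return a pixel box list (x0, y0, x1, y1).
#' @export
artifactFreeRegion <- function(phantom) {
  d <- dim(phantom@shapeMask)
  x1 <- d[2] + 1L
  if (length(phantom@artifactBoxes))
    x1 <- min(vapply(phantom@artifactBoxes, function(b) b$x0, numeric(1))) - 2L
  list(x0 = 1L, y0 = 1L, x1 = as.integer(x1), y1 = d[1] + 1L)
}

#' Smooth random rigid motion trajectory
#'
#' A seeded random walk of rigid poses: per-frame rotation and translation
#' steps are drawn from centered normals, accumulated, and clamped to the
#' stated bounds so the foot stays in frame. The rotation pivot is the
#' foot centroid; the returned transforms are in rotate-about-origin form
#' (the translation absorbs the pivot), exactly the form the tracker
#' estimates. Frame 1 is the identity.
#'
#' @param nFrames number of frames.
#' @param pivot rotation pivot (x, y), typically the phantom centroid.
#' @param maxRotationDeg bound on the absolute rotation, degrees.
#' @param maxTranslation bound on each translation component, pixels.
#' @param rotStepDeg,transStep random-walk step standard deviations.
#' @param seed RNG seed.
#' @return list of \code{nFrames} [RigidTransform2D-class] poses (frame-1
#'   coordinates to frame-n coordinates).
#' @export
makeMotionTrajectory <- function(nFrames, pivot, maxRotationDeg = 10,
                                 maxTranslation = 15, rotStepDeg = 1.5,
                                 transStep = 2, seed = 1) {
  stopifnot(nFrames >= 1)
  set.seed(seed)
  rot <- cumsum(c(0, rnorm(nFrames - 1, 0, rotStepDeg * pi / 180)))
  tx <- cumsum(c(0, rnorm(nFrames - 1, 0, transStep)))
  ty <- cumsum(c(0, rnorm(nFrames - 1, 0, transStep)))
  maxRot <- maxRotationDeg * pi / 180
  rot <- pmax(pmin(rot, maxRot), -maxRot)
  tx <- pmax(pmin(tx, maxTranslation), -maxTranslation)
  ty <- pmax(pmin(ty, maxTranslation), -maxTranslation)
  lapply(seq_len(nFrames), function(f)
    pivotTransform(rot[f], c(tx[f], ty[f]), pivot))
}

#' Rigid transform rotating about a pivot
#'
#' Convenience constructor: rotation by \code{rotation} about \code{pivot}
#' followed by \code{translation}, expressed in the package's
#' rotate-about-origin form.
#'
#' @param rotation angle, radians.
#' @param translation (tx, ty), pixels.
#' @param pivot rotation pivot (x, y).
#' @return a [RigidTransform2D-class].
#' @export
pivotTransform <- function(rotation, translation, pivot) {
  R <- rotationMatrix(rotation)
  RigidTransform2D(rotation = rotation,
                   translation = pivot - as.numeric(R %*% pivot) + translation)
}

#' Sample a speckle intensity image for a perfusion map
#'
#' Draws per-pixel intensities from a gamma distribution with shape
#' \eqn{m = 1/K_{raw}^2} and mean \code{meanIntensity}, where the raw
#' contrast target \eqn{K_{raw} = K_{cal} / \beta} comes from inverting
#' the perfusion equation at each pixel's perfusion. The gamma family
#' reproduces any target contrast in (0, 1] — the empirical sd/mean of a
#' uniform patch converges to the target at the usual 1/sqrt(N) rate —
#' and is physically motivated by speckle averaging without simulating
#' coherent optics. Fully developed speckle (static target, beta = 1)
#' corresponds to shape 1, the exponential-intensity limit.
#'
#' @param perfusionMap numeric matrix of PU values.
#' @param calibration the [Calibration-class] the virtual instrument is
#'   set to.
#' @param meanIntensity mean intensity, arbitrary units.
#' @return intensity matrix, same shape (no RNG seeding: seed at the
#'   caller).
#' @export
sampleSpeckle <- function(perfusionMap, calibration, meanIntensity = 1) {
  Kcal <- perfusionToContrast(perfusionMap, signalGain(calibration))
  Kraw <- Kcal / coherenceFactor(calibration)
  if (any(Kraw <= 0 | Kraw > 1))
    stopf("raw contrast target outside (0, 1]: beta %.3f cannot realize perfusion %.1f PU",
          coherenceFactor(calibration), perfusionMap[which(Kraw > 1)[1]])
  m <- 1 / Kraw^2
  matrix(rgamma(length(m), shape = m, scale = meanIntensity / m),
         nrow(perfusionMap), ncol(perfusionMap))
}

# Pixel-index map for nearest-neighbor resampling under a rigid pose:
# out[y, x] = img[T^{-1}(x, y)]. NN (not interpolation) preserves speckle
# statistics. Returns linear destination/source indices reusable across
# images of the same shape.
warpIndex <- function(shape, pose) {
  H <- shape[1]; W <- shape[2]
  inv <- invertTransform(pose)
  xs <- rep(seq_len(W), each = H)
  ys <- rep.int(seq_len(H), W)
  src <- applyTransform(inv, cbind(xs, ys))
  sx <- round(src[, 1]); sy <- round(src[, 2])
  ok <- sx >= 1 & sx <= W & sy >= 1 & sy <= H
  list(dst = which(ok), src = (sx[ok] - 1L) * H + sy[ok])
}

warpNearest <- function(img, pose, fill = 0) {
  idx <- warpIndex(dim(img), pose)
  out <- matrix(fill, nrow(img), ncol(img))
  out[idx$dst] <- img[idx$src]
  out
}

#' Simulate an LSCI recording of a moving phantom
#'
#' For every frame, the phantom's perfusion map is moved by the frame's
#' ground-truth pose (nearest-neighbor resampling), optionally scaled by a
#' per-frame perfusion multiplier (to emulate occlusion, hyperemia and leg
#' elevation), and converted to speckle intensities with [sampleSpeckle()].
#' Background pixels get zero intensity and are marked invalid; static
#' artifact boxes are painted at fixed image positions with a bright
#' constant intensity and are also invalid.
#'
#' @param phantom a [FootPhantom-class].
#' @param trajectory list of per-frame [RigidTransform2D-class] poses
#'   (e.g. from [makeMotionTrajectory()]).
#' @param calibration a [Calibration-class].
#' @param perfusionScale per-frame multiplier of the perfusion map
#'   (length 1 or \code{length(trajectory)}).
#' @param meanIntensity foot mean intensity, arbitrary units.
#' @param protocol optional [Protocol-class] attached to the recording.
#' @param seed RNG seed; the recording is bit-identical for identical
#'   inputs.
#' @return list with \code{recording} (a [Recording-class]) and
#'   \code{groundTruth}: the per-frame poses, per-frame true ROI sets,
#'   region levels and the perfusion-scale vector.
#' @export
simulateRecording <- function(phantom, trajectory, calibration,
                              perfusionScale = 1, meanIntensity = 1,
                              protocol = NULL, seed = 1) {
  n <- length(trajectory)
  perfusionScale <- rep_len(perfusionScale, n)
  d <- dim(phantom@shapeMask)
  frames <- array(0, c(d, n))
  valid <- array(FALSE, c(d, n))
  set.seed(seed)
  for (f in seq_len(n)) {
    idx <- warpIndex(d, trajectory[[f]])
    pmap <- matrix(0, d[1], d[2])
    pmap[idx$dst] <- phantom@perfusionMap[idx$src]
    smask <- matrix(FALSE, d[1], d[2])
    smask[idx$dst] <- phantom@shapeMask[idx$src]
    img <- matrix(0, d[1], d[2])
    img[smask] <- sampleSpeckle(
      matrix(pmap[smask] * perfusionScale[f], ncol = 1),
      calibration, meanIntensity)
    for (b in phantom@artifactBoxes) {
      ysb <- max(1, b$y0):min(d[1], b$y1 - 1)
      xsb <- max(1, b$x0):min(d[2], b$x1 - 1)
      img[ysb, xsb] <- 1.5 * meanIntensity
      smask[ysb, xsb] <- FALSE
    }
    frames[, , f] <- img
    valid[, , f] <- smask
  }
  rec <- Recording(frames, valid, protocol = protocol)
  gtRois <- lapply(trajectory, function(tr)
    lapply(phantom@rois, transformEllipse, t = tr))
  list(recording = rec,
       groundTruth = list(transforms = trajectory, roiSets = gtRois,
                          regionLevels = phantom@regionLevels,
                          perfusionScale = perfusionScale))
}

#' Simulate two-point calibration target recordings
#'
#' A zero-perfusion (static) target whose raw contrast is
#' \code{1 / betaTrue}, and a motility standard whose true perfusion
#' equals \code{referencePerfusion} under the true constants. Applying
#' [calibrate()] to pooled pixel statistics of these recordings recovers
#' (betaTrue, gainTrue) within speckle sampling error.
#'
#' @param betaTrue,gainTrue true instrument constants.
#' @param referencePerfusion PU assigned to the standard (default 250).
#' @param patch image size c(H, W) of each target frame (default 64 x 64).
#' @param frames number of frames per target recording.
#' @param meanIntensity mean intensity, arbitrary units.
#' @param seed RNG seed.
#' @return list with \code{static} and \code{standard}
#'   ([Recording-class]) plus the true constants.
#' @export
simulateCalibrationTargets <- function(betaTrue = 1.25, gainTrue = 250,
                                       referencePerfusion = 250,
                                       patch = c(64, 64), frames = 10,
                                       meanIntensity = 1, seed = 1) {
  stopifnot(betaTrue > 0, gainTrue > 0, referencePerfusion > 0, frames >= 1)
  cal <- Calibration(betaTrue, gainTrue, referencePerfusion)
  set.seed(seed)
  mk <- function(level) {
    arr <- array(0, c(patch, frames))
    for (f in seq_len(frames))
      arr[, , f] <- sampleSpeckle(matrix(level, patch[1], patch[2]),
                                  cal, meanIntensity)
    Recording(arr)
  }
  list(static = mk(0), standard = mk(referencePerfusion),
       betaTrue = betaTrue, gainTrue = gainTrue,
       referencePerfusion = referencePerfusion)
}

#' Pooled pixel statistics of a recording
#'
#' [roiStats()] over all valid pixels of all frames — the statistics used
#' when calibrating from target recordings.
#'
#' @param recording a [Recording-class].
#' @return list(mean_intensity, std_intensity, pixel_count).
#' @export
recordingStats <- function(recording) {
  roiStats(recording@frames[recording@validity])
}

#' Per-frame mean perfusion of a uniform target recording
#'
#' Measures each frame of a target recording with a given calibration:
#' pooled frame statistics -> contrast -> perfusion. Used to verify the
#' 0 +/- 5 PU and 250 +/- 5 PU calibration tolerances on held-out frames.
#'
#' @param recording a [Recording-class] of a uniform target.
#' @param calibration a [Calibration-class].
#' @return numeric vector of per-frame perfusions (PU).
#' @export
measureUniformTarget <- function(recording, calibration) {
  vapply(seq_len(nFrames(recording)), function(f) {
    st <- roiStats(getFrame(recording, f)[getValidity(recording, f)])
    contrastToPerfusion(roiContrast(st, coherenceFactor(calibration)),
                        signalGain(calibration))
  }, numeric(1))
}

#' Piecewise perfusion multiplier for a stress-test protocol
#'
#' Emulates the clinical time course: baseline at 1, occlusion suppressed
#' to \code{occlusionLevel}, a reactive-hyperemia overshoot after release
#' (Gaussian bump of height \code{peakMult} at \code{peakFrame} decaying
#' back toward baseline), and the Buerger leg-elevation segment at
#' \code{buergerLevel}.
#'
#' @param protocol a [Protocol-class].
#' @param nFrames total frames.
#' @param peakFrame frame of the true hyperemia peak.
#' @param peakMult multiplier at the peak.
#' @param occlusionLevel,buergerLevel multipliers in those segments.
#' @param peakWidth Gaussian sd of the overshoot, frames.
#' @return numeric multiplier vector of length \code{nFrames}.
#' @export
hyperemiaProfile <- function(protocol, nFrames, peakFrame,
                             peakMult = 2.5, occlusionLevel = 0.2,
                             buergerLevel = 0.4, peakWidth = 3) {
  f <- seq_len(nFrames)
  prof <- rep(1, nFrames)
  occ <- f > protocol@baselineWindow[2] & f <= protocol@releaseFrame
  prof[occ] <- occlusionLevel
  post <- f > protocol@releaseFrame
  if (hasBuerger(protocol)) post <- post & f < protocol@buergerWindow[1]
  prof[post] <- 1 + (peakMult - 1) *
    exp(-(f[post] - peakFrame)^2 / (2 * peakWidth^2))
  if (hasBuerger(protocol))
    prof[f >= protocol@buergerWindow[1]] <- buergerLevel
  prof
}
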