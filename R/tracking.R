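# Foot-silhouette tracking: edge detection, closed-form rigid fit, ICP,
# and ROI propagation with the Buerger's-test reset.
# Coordinate convention: see utils.R.

#' ICP parameters
#'
#' ICP converges slowly in the tangential direction on smooth closed
#' contours (nearest-neighbor correspondence barely penalizes sliding
#' along the curve), so the stopping tolerance is deliberately tight; and
#' correspondences are only discarded as outliers when their residual
#' also exceeds \code{trimFloor} — a pure worst-fraction trim would throw
#' away exactly the high-curvature points (toes) that pin down the
#' rotation.
#'
#' @param maxIterations iteration cap (>= 1).
#' @param convergenceTol stop when the RMS residual changes by less than
#'   this many pixels between iterations.
#' @param trimFraction fraction of the worst correspondences eligible for
#'   discarding before each rigid fit, in [0, 1); robustness against
#'   spurious edge points.
#' @param trimFloor residual (pixels) below which a correspondence is
#'   never discarded, whatever its rank.
#' @param init initial [RigidTransform2D-class] guess (e.g. a warm start
#'   from the previous frame), or NULL (the default) for an automatic
#'   centroid + principal-axis alignment with rotational multi-start.
#'   Nearest-neighbor ICP on dense contours has sliding local minima with
#'   a convergence basin of only a degree or two, so cold starts run one
#'   ICP per \code{rotationStarts} offset and keep the lowest-residual
#'   fit; the moment-based initialization itself is exact for same-shape
#'   point sets.
#' @param rotationStarts rotation offsets (degrees, about the destination
#'   centroid) tried around the automatic initialization when
#'   \code{init} is NULL.
#' @return parameter list for [icp()].
#' @export
icpParams <- function(maxIterations = 200L, convergenceTol = 1e-5,
                      trimFraction = 0.1, trimFloor = 3,
                      init = NULL,
                      rotationStarts = c(0, -2, 2, -4, 4, -6, 6, -8, 8,
                                         -10, 10, -12, 12, -14, 14)) {
  stopifnot(maxIterations >= 1L, convergenceTol > 0,
            trimFraction >= 0, trimFraction < 1, trimFloor >= 0)
  list(maxIterations = as.integer(maxIterations),
       convergenceTol = convergenceTol,
       trimFraction = trimFraction, trimFloor = trimFloor, init = init,
       rotationStarts = rotationStarts)
}

# Moment-based initial alignment: map the source centroid onto the
# destination centroid and the source principal axis onto the
# destination principal axis; the 180-degree axis ambiguity is resolved
# by one nearest-neighbor RMS evaluation per candidate.
principalAxisInit <- function(src, dst) {
  axisAngle <- function(p) {
    cc <- sweep(p, 2, colMeans(p))
    m <- crossprod(cc) / nrow(cc)
    0.5 * atan2(2 * m[1, 2], m[1, 1] - m[2, 2])
  }
  dTheta <- axisAngle(dst) - axisAngle(src)
  cs <- colMeans(src); cd <- colMeans(dst)
  best <- NULL; bestRms <- Inf
  for (theta in c(dTheta, dTheta + pi)) {
    R <- rotationMatrix(theta)
    cand <- RigidTransform2D(theta, cd - as.numeric(R %*% cs))
    moved <- applyTransform(cand, src)
    nn <- nearestNeighbor(moved, dst)
    rms <- sqrt(mean(rowSums((moved - dst[nn, , drop = FALSE])^2)))
    if (rms < bestRms) { bestRms <- rms; best <- cand }
  }
  best
}

#' Detect foot-silhouette edge points in a frame
#'
#' Runs Canny edge detection on the intensity image, optionally restricted
#' to the artifact-free region (a half-open pixel box selected once on
#' frame 1 to exclude static bright structures such as the examination
#' bench), and keeps the largest connected edge component — the foot
#' silhouette dominates the edge map, and small internal edges would
#' corrupt shape matching.
#'
#' @param frame numeric H x W intensity matrix.
#' @param artifactFreeRegion optional half-open pixel box
#'   \code{list(x0, y0, x1, y1)}; only pixels inside it are considered.
#' @param params a [cannyParams()] list.
#' @param frameLabel label used in error messages.
#' @return n x 2 matrix of (x, y) edge-pixel coordinates, n >= 3.
#' @export
detectFootPoints <- function(frame, artifactFreeRegion = NULL,
                             params = cannyParams(), frameLabel = "frame") {
  checkPixelBox(artifactFreeRegion)
  if (!is.null(artifactFreeRegion)) {
    b <- artifactFreeRegion
    H <- nrow(frame); W <- ncol(frame)
    sub <- frame[max(1, b$y0):min(H, b$y1 - 1),
                 max(1, b$x0):min(W, b$x1 - 1), drop = FALSE]
    edges <- cannyEdges(sub, params)
    pts <- largestComponentPoints(edges)
    if (nrow(pts)) {
      pts[, 1] <- pts[, 1] + max(1, b$x0) - 1
      pts[, 2] <- pts[, 2] + max(1, b$y0) - 1
    }
  } else {
    edges <- cannyEdges(frame, params)
    pts <- largestComponentPoints(edges)
  }
  if (nrow(pts) < 3L)
    stopf("edge detection failure on %s: %d edge point(s) found (need >= 3)",
          frameLabel, nrow(pts))
  pts
}

#' Closed-form least-squares rigid fit of corresponding point sets
#'
#' Given two point sets in 1:1 correspondence, finds the rotation and
#' translation minimizing the mean squared correspondence distance
#' (Kabsch/Umeyama in 2D): centroids are aligned and the rotation comes
#' from the SVD of the cross-covariance with the determinant constrained
#' to +1 — no reflection, no scaling.
#'
#' @param src,dst n x 2 matrices of (x, y) points, equal n >= 3.
#' @return a [RigidTransform2D-class] mapping \code{src} onto \code{dst}.
#' @export
estimateRigidTransform <- function(src, dst) {
  src <- rbind(src); dst <- rbind(dst)
  if (nrow(src) != nrow(dst)) stopf("point sets must correspond 1:1")
  if (nrow(src) < 3L) stopf("need at least 3 point pairs")
  cs <- colMeans(src); cd <- colMeans(dst)
  S <- sweep(src, 2, cs); D <- sweep(dst, 2, cd)
  H <- crossprod(S, D)
  if (!all(is.finite(H)) || sum(H^2) == 0)
    stopf("degenerate point configuration: rigid fit undefined")
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, d)) %*% t(sv$u)
  theta <- atan2(R[2, 1], R[1, 1])
  trans <- cd - as.numeric(R %*% cs)
  RigidTransform2D(rotation = theta, translation = trans)
}

# index of the nearest row of B for each row of A (brute force,
# vectorized; the |a|^2 term is constant per row and dropped)
nearestNeighbor <- function(A, B) {
  s <- 2 * tcrossprod(A, B) - rep(rowSums(B^2), each = nrow(A))
  max.col(s, ties.method = "first")
}

#' Iterative closest point rigid registration
#'
#' Point-to-point ICP: alternates nearest-neighbor correspondence (the
#' \code{dst} point closest to each transformed \code{src} point) with the
#' closed-form rigid fit of [estimateRigidTransform()], optionally trimming
#' the worst correspondences, until the RMS residual change drops below
#' \code{convergenceTol} or \code{maxIterations} is reached.
#' Deterministic given inputs and parameters. Non-convergence is reported
#' in the diagnostics (\code{converged = FALSE}), never silently.
#'
#' @param src,dst n x 2 / m x 2 point matrices, both >= 3 points.
#' @param params an [icpParams()] list.
#' @return list with \code{transform} ([RigidTransform2D-class]),
#'   \code{rms} (final trimmed RMS residual, px), \code{iterations},
#'   \code{converged}.
#' @export
icp <- function(src, dst, params = icpParams()) {
  src <- rbind(src); dst <- rbind(dst)
  if (nrow(src) < 3L || nrow(dst) < 3L) stopf("ICP needs >= 3 points per set")
  if (!is.null(params$init))
    return(icpCore(src, dst, params, params$init))
  init0 <- principalAxisInit(src, dst)
  cd <- colMeans(dst)
  scan <- function(offsets, best = NULL) {
    for (offsetDeg in offsets) {
      init <- composeTransforms(
        pivotTransform(offsetDeg * pi / 180, c(0, 0), cd), init0)
      fit <- icpCore(src, dst, params, init)
      if (is.null(best) || fit$rms < best$rms) best <- fit
      if (best$rms < 0.1) break   # essentially exact; no restart can help
    }
    best
  }
  best <- scan(params$rotationStarts)
  # a still-poor best fit can mean the principal-axis direction was
  # picked the wrong way round (partial silhouettes): try the flip
  if (best$rms > 1) best <- scan(180 + params$rotationStarts, best)
  best
}

icpCore <- function(src, dst, params, init) {
  trans <- init
  nKeep <- max(3L, ceiling(nrow(src) * (1 - params$trimFraction)))
  floor2 <- params$trimFloor^2
  lastRms <- Inf; converged <- FALSE; it <- 0L; rms <- NA_real_
  while (it < params$maxIterations) {
    it <- it + 1L
    moved <- applyTransform(trans, src)
    nn <- nearestNeighbor(moved, dst)
    res2 <- rowSums((moved - dst[nn, , drop = FALSE])^2)
    cutoff <- max(sort(res2, partial = nKeep)[nKeep], floor2)
    keep <- which(res2 <= cutoff)
    rms <- sqrt(mean(res2[keep]))
    if (abs(lastRms - rms) < params$convergenceTol) { converged <- TRUE; break }
    lastRms <- rms
    trans <- estimateRigidTransform(src[keep, , drop = FALSE],
                                    dst[nn[keep], , drop = FALSE])
  }
  list(transform = trans, rms = rms, iterations = it, converged = converged)
}

#' Track ellipse ROIs across a recording
#'
#' Propagates the manually drawn frame-1 ROI set to every frame of the
#' recording: for each frame the reference frame's foot-silhouette points
#' are registered directly onto that frame's points (reference-to-frame-n,
#' not chained frame-to-frame, which would accumulate drift) and the
#' resulting rigid transform is applied to the reference ROI set. Each
#' frame's ICP is warm-started from the previous frame's accepted
#' transform.
#'
#' When the protocol includes a Buerger's-test segment, the foot is
#' repositioned and its imaged shape changes, so tracking is reset there:
#' a second, manually drawn ROI set (\code{buergerRois}) anchors the first
#' Buerger frame, which becomes the reference for the rest of the segment.
#'
#' Edge-detection failure or ICP non-convergence on a non-reference frame
#' carries the previous frame's ROIs forward with a diagnostic flag (a
#' hard failure would make whole recordings unanalyzable); failure on a
#' reference frame is fatal.
#'
#' @param recording a [Recording-class]; its protocol (if any) defines the
#'   Buerger segment.
#' @param initialRois list of [EllipseROI-class] drawn on frame 1.
#' @param buergerRois ROI set drawn on the first Buerger frame; required
#'   iff the protocol has a Buerger segment.
#' @param artifactFreeRegion optional half-open pixel box restricting edge
#'   detection (see [detectFootPoints()]).
#' @param icpControl an [icpParams()] list.
#' @param cannyControl a [cannyParams()] list.
#' @param maxRms registration acceptance gate: a fitted transform whose
#'   trimmed RMS residual exceeds this many pixels is rejected (gross
#'   misregistration, e.g. after silhouette fragmentation) and the
#'   previous frame's ROIs are carried forward instead.
#' @return a [TrackingResult-class].
#' @export
trackRois <- function(recording, initialRois, buergerRois = NULL,
                      artifactFreeRegion = NULL,
                      icpControl = icpParams(), cannyControl = cannyParams(),
                      maxRms = 5) {
  n <- nFrames(recording)
  prot <- protocol(recording)
  buergerStart <- NA_integer_
  if (!is.null(prot) && hasBuerger(prot)) {
    buergerStart <- prot@buergerWindow[1]
    if (is.null(buergerRois))
      stopf(paste("the protocol includes a Buerger's-test segment (frames %d-%d):",
                  "a second ROI set drawn on its first frame is required"),
            prot@buergerWindow[1], prot@buergerWindow[2])
  }

  refPoints <- detectFootPoints(getFrame(recording, 1), artifactFreeRegion,
                                cannyControl, "reference frame 1")
  refRois <- initialRois
  refFrame <- 1L

  transformsL <- vector("list", n)
  roiSetsL <- vector("list", n)
  diag <- data.frame(frame = seq_len(n), reference_frame = NA_integer_,
                     rotation_deg = NA_real_, tx = NA_real_, ty = NA_real_,
                     rms = NA_real_, iterations = NA_integer_,
                     converged = FALSE, carried_forward = FALSE)
  warm <- identityTransform()

  for (f in seq_len(n)) {
    if (!is.na(buergerStart) && f == buergerStart) {
      # reset: the repositioned foot gets its own reference and ROI set
      refPoints <- detectFootPoints(getFrame(recording, f), artifactFreeRegion,
                                    cannyControl,
                                    sprintf("Buerger reference frame %d", f))
      refRois <- buergerRois
      refFrame <- f
      warm <- identityTransform()
    }
    diag$reference_frame[f] <- refFrame

    if (f == refFrame) {
      transformsL[[f]] <- identityTransform()
      roiSetsL[[f]] <- refRois
      diag$rotation_deg[f] <- 0; diag$tx[f] <- 0; diag$ty[f] <- 0
      diag$rms[f] <- 0; diag$iterations[f] <- 0L; diag$converged[f] <- TRUE
      next
    }

    pts <- tryCatch(
      detectFootPoints(getFrame(recording, f), artifactFreeRegion,
                       cannyControl, sprintf("frame %d", f)),
      error = function(e) NULL)
    if (is.null(pts)) {
      transformsL[[f]] <- transformsL[[f - 1L]]
      roiSetsL[[f]] <- roiSetsL[[f - 1L]]
      diag$carried_forward[f] <- TRUE
      tr <- transformsL[[f]]
      diag$rotation_deg[f] <- tr@rotation * 180 / pi
      diag$tx[f] <- tr@translation[1]; diag$ty[f] <- tr@translation[2]
      warnf("frame %d: edge detection failed; ROIs carried forward", f)
      next
    }

    ctrl <- icpControl; ctrl$init <- warm
    fit <- icp(refPoints, pts, ctrl)
    if (!fit$converged || fit$rms > maxRms) {
      # warm start led nowhere: retry cold (multi-start initialization)
      ctrl$init <- NULL
      fit2 <- icp(refPoints, pts, ctrl)
      if (fit2$rms < fit$rms) fit <- fit2
    }
    diag$rms[f] <- fit$rms
    diag$iterations[f] <- fit$iterations
    diag$converged[f] <- fit$converged
    if ((!fit$converged || fit$rms > maxRms) && f > 1L) {
      transformsL[[f]] <- transformsL[[f - 1L]]
      roiSetsL[[f]] <- roiSetsL[[f - 1L]]
      diag$carried_forward[f] <- TRUE
      warnf("frame %d: registration rejected (converged = %s, RMS %.2f px); ROIs carried forward",
            f, fit$converged, fit$rms)
    } else {
      transformsL[[f]] <- fit$transform
      roiSetsL[[f]] <- lapply(refRois, transformEllipse, t = fit$transform)
      warm <- fit$transform
    }
    tr <- transformsL[[f]]
    diag$rotation_deg[f] <- tr@rotation * 180 / pi
    diag$tx[f] <- tr@translation[1]; diag$ty[f] <- tr@translation[2]
  }

  new("TrackingResult", transforms = transformsL, roiSets = roiSetsL,
      diagnostics = diag)
}

#' Export tracking diagnostics and per-frame ROIs
#'
#' Writes the diagnostics table as CSV and the per-frame ROI sets as one
#' JSON file per frame (same dialect as [writeRois()]).
#'
#' @param result a [TrackingResult-class].
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return invisibly, the diagnostics CSV path.
#' @export
exportTracking <- function(result, dir, prefix = "tracking") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, paste0(prefix, "_diagnostics.csv"))
  write.csv(trackingDiagnostics(result), csv, row.names = FALSE)
  roiDir <- file.path(dir, paste0(prefix, "_rois"))
  dir.create(roiDir, showWarnings = FALSE)
  for (f in seq_along(roiSets(result)))
    writeRois(roiSets(result)[[f]],
              file.path(roiDir, sprintf("frame_%04d.json", f)))
  invisible(csv)
}
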