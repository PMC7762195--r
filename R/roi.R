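# Ellipse geometry, rasterization and rigid-motion transport.
# Coordinate convention: see utils.R (1-based pixel centers, x = column,
# y = row, rotation about the coordinate origin).

rotationMatrix <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

#' Apply a rigid transform to points
#'
#' Maps points by rotation about the coordinate origin followed by
#' translation: \code{p' = R p + t}.
#'
#' @param t a [RigidTransform2D-class].
#' @param points n x 2 matrix of (x, y) coordinates.
#' @return n x 2 matrix of mapped coordinates.
#' @export
applyTransform <- function(t, points) {
  if (!is.matrix(points)) points <- rbind(points)
  out <- points %*% t(rotationMatrix(t@rotation))
  out[, 1] <- out[, 1] + t@translation[1]
  out[, 2] <- out[, 2] + t@translation[2]
  out
}

#' Compose and invert rigid transforms
#'
#' \code{composeTransforms(t2, t1)} is the transform that applies
#' \code{t1} first and \code{t2} second (function composition order), so
#' \code{applyTransform(composeTransforms(t2, t1), p)} equals
#' \code{applyTransform(t2, applyTransform(t1, p))}. The transforms form a
#' group: composition is associative and every transform has an inverse
#' with the opposite rotation.
#'
#' @param t1,t2 [RigidTransform2D-class] objects.
#' @return a [RigidTransform2D-class].
#' @export
composeTransforms <- function(t2, t1) {
  R2 <- rotationMatrix(t2@rotation)
  RigidTransform2D(rotation = t2@rotation + t1@rotation,
                   translation = as.numeric(R2 %*% t1@translation) + t2@translation)
}

#' @rdname composeTransforms
#' @param t a [RigidTransform2D-class].
#' @export
invertTransform <- function(t) {
  Rinv <- rotationMatrix(-t@rotation)
  RigidTransform2D(rotation = -t@rotation,
                   translation = as.numeric(-Rinv %*% t@translation))
}

identityTransform <- function() RigidTransform2D(0, c(0, 0))

isIdentity <- function(t, tol = 1e-12) {
  abs(t@rotation) < tol && all(abs(t@translation) < tol)
}

#' Transform an ellipse ROI under rigid motion
#'
#' The center is mapped by the transform and the orientation is
#' incremented by its rotation angle (wrapped into (-pi, pi]); the
#' semi-axes are unchanged since rigid motion preserves shape.
#'
#' @param roi an [EllipseROI-class].
#' @param t a [RigidTransform2D-class].
#' @return the transformed [EllipseROI-class].
#' @export
transformEllipse <- function(roi, t) {
  EllipseROI(label = roi@label,
             center = as.numeric(applyTransform(t, rbind(roi@center))),
             semiAxes = roi@semiAxes,
             orientation = wrapAngle(roi@orientation + t@rotation))
}

#' Rasterize an ellipse to a pixel mask
#'
#' A pixel belongs to the mask iff its center lies inside or on the
#' ellipse boundary and the validity mask is TRUE there. Pixel centers are
#' used directly (no anti-aliased partial coverage), which keeps masks
#' deterministic; pixels outside the image are dropped and an empty mask
#' is legal output.
#'
#' @param roi an [EllipseROI-class].
#' @param shape image dimensions c(H, W) (rows, columns).
#' @param validity optional logical H x W matrix; FALSE excludes a pixel.
#' @return logical H x W matrix.
#' @export
rasterizeEllipse <- function(roi, shape, validity = NULL) {
  H <- shape[1]; W <- shape[2]
  mask <- matrix(FALSE, H, W)
  a <- roi@semiAxes[1]; b <- roi@semiAxes[2]
  r <- max(a, b)
  xr <- max(1L, floor(roi@center[1] - r)):min(W, ceiling(roi@center[1] + r))
  yr <- max(1L, floor(roi@center[2] - r)):min(H, ceiling(roi@center[2] + r))
  if (roi@center[1] + r < 1 || roi@center[1] - r > W ||
      roi@center[2] + r < 1 || roi@center[2] - r > H)
    return(mask)
  # rotate pixel centers into the ellipse frame
  xs <- rep(xr, each = length(yr)) - roi@center[1]
  ys <- rep(yr, times = length(xr)) - roi@center[2]
  co <- cos(roi@orientation); si <- sin(roi@orientation)
  u <- xs * co + ys * si
  v <- -xs * si + ys * co
  inside <- (u / a)^2 + (v / b)^2 <= 1
  mask[cbind(rep(yr, times = length(xr)), rep(xr, each = length(yr)))] <- inside
  if (!is.null(validity)) mask <- mask & validity
  mask
}

# ---------------------------------------------------------------------------
# JSON dialects

#' Read and write ellipse ROI sets as JSON
#'
#' ROI sets are stored as a JSON array of objects
#' \code{\{label, center: [x, y], semi_axes: [a, b], orientation_rad\}}.
#'
#' @param path file path.
#' @return \code{readRois}: list of [EllipseROI-class].
#' @export
readRois <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(raw, function(r)
    EllipseROI(label = r$label, center = unlist(r$center),
               semiAxes = unlist(r$semi_axes),
               orientation = r$orientation_rad %||% 0))
}

#' @rdname readRois
#' @param rois list of [EllipseROI-class].
#' @export
writeRois <- function(rois, path) {
  out <- lapply(rois, function(r)
    list(label = r@label, center = r@center, semi_axes = r@semiAxes,
         orientation_rad = r@orientation))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write a half-open pixel box as JSON
#'
#' The artifact-free region is stored as
#' \code{\{x0, y0, x1, y1\}}, keeping pixels with \code{x0 <= x < x1} and
#' \code{y0 <= y < y1}.
#'
#' @param path file path.
#' @return \code{readPixelBox}: named list (x0, y0, x1, y1).
#' @export
readPixelBox <- function(path) {
  box <- jsonlite::fromJSON(path)
  checkPixelBox(box)
  box
}

#' @rdname readPixelBox
#' @param box named list (x0, y0, x1, y1).
#' @export
writePixelBox <- function(box, path) {
  checkPixelBox(box)
  jsonlite::write_json(box[c("x0", "y0", "x1", "y1")], path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write calibration constants as JSON
#' @param path file path.
#' @return \code{readCalibration}: a [Calibration-class].
#' @export
readCalibration <- function(path) {
  j <- jsonlite::fromJSON(path)
  Calibration(beta = j$beta, gain = j$gain,
              referencePerfusion = j$reference_perfusion %||% 250)
}

#' @rdname readCalibration
#' @param calibration a [Calibration-class].
#' @export
writeCalibration <- function(calibration, path) {
  jsonlite::write_json(
    list(beta = calibration@beta, gain = calibration@gain,
         reference_perfusion = calibration@referencePerfusion,
         sigma_convention = calibration@sigmaConvention),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
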