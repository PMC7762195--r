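# Foot detection, rigid fitting, ICP and ROI propagation.

test_that("closed-form rigid fit recovers exact and noisy correspondences", {
  set.seed(3)
  src <- cbind(runif(200, 0, 100), runif(200, 0, 100))
  expect_equal(estimateRigidTransform(src, src)@rotation, 0, tolerance = 1e-12)

  truth <- RigidTransform2D(30 * pi / 180, c(5, -3))
  fit <- estimateRigidTransform(src, applyTransform(truth, src))
  expect_equal(fit@rotation, truth@rotation, tolerance = 1e-9)
  expect_equal(fit@translation, truth@translation, tolerance = 1e-9)

  # noisy correspondences: sigma 0.5 px on 200 points
  noisy <- applyTransform(truth, src) + matrix(rnorm(400, 0, 0.5), 200, 2)
  fitN <- estimateRigidTransform(src, noisy)
  expect_lt(abs(fitN@rotation - truth@rotation) * 180 / pi, 0.5)

  expect_error(estimateRigidTransform(src[1:2, ], src[1:2, ]), "3 point")
  same <- matrix(5, 4, 2)
  expect_error(estimateRigidTransform(same, same), "degenerate")
})

test_that("ICP recovers rigid motion, with and without outliers", {
  ph <- makeFootPhantom(scale = 0.5, artifacts = FALSE)
  src <- which(ph@shapeMask & !EBImage::erode(EBImage::Image(ph@shapeMask * 1)),
               arr.ind = TRUE)
  src <- cbind(src[, 2], src[, 1])

  self <- icp(src, src)
  expect_true(self$converged)
  expect_equal(self$rms, 0, tolerance = 1e-9)
  expect_equal(self$transform@rotation, 0, tolerance = 1e-9)

  truth <- RigidTransform2D(10 * pi / 180, c(3, -2))
  dst <- applyTransform(truth, src)
  fit <- icp(src, dst)
  expect_true(fit$converged)
  expect_lt(abs(fit$transform@rotation - truth@rotation), 1e-6)
  expect_lt(max(abs(fit$transform@translation - truth@translation)), 1e-6)

  # 10 % spurious points in the target, trimming enabled
  set.seed(17)
  junk <- cbind(runif(ceiling(nrow(src) * 0.1), 1, 100),
                runif(ceiling(nrow(src) * 0.1), 1, 80))
  fitO <- icp(src, rbind(dst, junk), icpParams(trimFraction = 0.2))
  expect_lt(abs(fitO$transform@rotation - truth@rotation) * 180 / pi, 1)
})

test_that("foot detection finds the silhouette and honors the artifact box", {
  expect_error(detectFootPoints(matrix(1, 60, 60)), "detection failure")

  ph <- makeFootPhantom(scale = 0.75)
  cal <- testCalibration()
  sim <- simulateRecording(ph, list(RigidTransform2D()), cal, seed = 3)
  frame <- getFrame(sim$recording, 1)
  pts <- detectFootPoints(frame, artifactFreeRegion(ph))

  # every detected point lies on the true silhouette boundary (within 2 px)
  m <- ph@shapeMask
  interior <- m & rbind(m[-1, ], FALSE) & rbind(FALSE, m[-nrow(m), ]) &
    cbind(m[, -1], FALSE) & cbind(FALSE, m[, -ncol(m)])
  bIdx <- which(m & !interior, arr.ind = TRUE)
  boundary <- cbind(bIdx[, 2], bIdx[, 1])
  d2 <- outer(rowSums(pts^2), rowSums(boundary^2), "+") -
    2 * tcrossprod(pts, boundary)
  expect_lt(sqrt(max(pmax(apply(d2, 1, min), 0))), 2)
  # and most of the boundary is covered by detected points
  expect_gt(mean(sqrt(pmax(apply(d2, 2, min), 0)) <= 2), 0.8)

  # convex hull of the points contains the silhouette centroid
  centroid <- c(mean(boundary[, 1]), mean(boundary[, 2]))
  hull <- grDevices::chull(pts)
  expect_true(all(range(pts[hull, 1]) %*% c(-1, 1) > 0))
  expect_true(centroid[1] > min(pts[, 1]) && centroid[1] < max(pts[, 1]))
  expect_true(centroid[2] > min(pts[, 2]) && centroid[2] < max(pts[, 2]))

  # a bright static bar outside the artifact-free box changes nothing
  phClean <- makeFootPhantom(scale = 0.75, artifacts = FALSE)
  simClean <- simulateRecording(phClean, list(RigidTransform2D()), cal, seed = 3)
  ptsClean <- detectFootPoints(getFrame(simClean$recording, 1),
                               artifactFreeRegion(ph))
  expect_identical(pts, ptsClean)
  # ... and the raw edge map really does contain the bar's edges, which
  # only the box keeps out of the point set
  edges <- cannyEdges(frame)
  b <- ph@artifactBoxes[[1]]
  pad <- 2
  expect_gt(sum(edges[(b$y0 - pad):(b$y1 + pad), (b$x0 - pad):(b$x1 + pad)]), 0)
})

test_that("ROI tracking follows known trajectories on noiseless phantoms", {
  ph <- makeFootPhantom(scale = 0.75, artifacts = FALSE)
  pivot <- c(75, 115) * 0.75

  # static recording: identity transforms, constant ROIs
  trajStatic <- rep(list(RigidTransform2D()), 4)
  recS <- noiselessRecording(ph, trajStatic)
  tkS <- trackRois(recS, ph@rois)
  for (f in 1:4) {
    expect_equal(transforms(tkS)[[f]]@rotation, 0, tolerance = 1e-6)
    expect_lt(max(abs(transforms(tkS)[[f]]@translation)), 1e-3)
  }

  # known rigid trajectory: ROI centers within 1 px per frame
  traj <- makeMotionTrajectory(8, pivot, maxRotationDeg = 10,
                               maxTranslation = 12, seed = 4)
  rec <- noiselessRecording(ph, traj)
  tk <- trackRois(rec, ph@rois)
  trueSets <- lapply(traj, function(t) lapply(ph@rois, transformEllipse, t = t))
  expect_lt(max(maxRoiCenterError(roiSets(tk), trueSets)), 1)
  expect_true(all(trackingDiagnostics(tk)$converged))

  # registration consistency: A->B and B->A are mutual inverses.
  # Exact-copy point sets: to 1e-3 px; contours re-discretized by the
  # renderer: to a tenth of a pixel.
  probe <- cbind(c(40, 60, 80), c(50, 90, 120))
  pA <- detectFootPoints(getFrame(rec, 1))
  exactB <- applyTransform(traj[[6]], pA)
  fwd <- icp(pA, exactB)$transform
  bwd <- icp(exactB, pA)$transform
  rtExact <- composeTransforms(bwd, fwd)
  expect_lt(max(abs(applyTransform(rtExact, probe) - probe)), 1e-3)

  pB <- detectFootPoints(getFrame(rec, 6))
  rt <- composeTransforms(icp(pB, pA)$transform, icp(pA, pB)$transform)
  expect_lt(max(abs(applyTransform(rt, probe) - probe)), 0.1)
})

test_that("the Buerger's-test segment restarts from its own ROI set", {
  ph <- makeFootPhantom(scale = 0.75, artifacts = FALSE)
  prot <- Protocol(baselineWindow = c(1, 3), releaseFrame = 4,
                   buergerWindow = c(7, 9))
  pivot <- c(75, 115) * 0.75
  resetPose <- pivotTransform(20 * pi / 180, c(4, -6), pivot)
  traj <- rep(list(RigidTransform2D()), 9)
  for (f in 7:9) traj[[f]] <- resetPose
  rec <- noiselessRecording(ph, traj, protocol = prot)

  buergerRois <- lapply(ph@rois, transformEllipse, t = resetPose)
  tk <- trackRois(rec, ph@rois, buergerRois)
  # within the Buerger segment the ROIs derive from the second ROI set
  for (f in 7:9) {
    est <- roiSets(tk)[[f]]
    for (r in seq_along(est))
      expect_lt(sqrt(sum((est[[r]]@center - buergerRois[[r]]@center)^2)), 1)
  }
  expect_equal(trackingDiagnostics(tk)$reference_frame, c(rep(1L, 6), rep(7L, 3)))
  # the first Buerger frame is its own reference: identity
  expect_equal(transforms(tk)[[7]]@rotation, 0)

  # a protocol with a Buerger segment demands the second ROI set
  expect_error(trackRois(rec, ph@rois), "second ROI set")
})

test_that("tracking exports diagnostics CSV and per-frame ROI JSON", {
  ph <- makeFootPhantom(scale = 0.75, artifacts = FALSE)
  rec <- noiselessRecording(ph, rep(list(RigidTransform2D()), 2))
  tk <- trackRois(rec, ph@rois)
  dir <- withr::local_tempdir()
  exportTracking(tk, dir)
  d <- read.csv(file.path(dir, "tracking_diagnostics.csv"))
  expect_equal(nrow(d), 2L)
  expect_true(all(c("rotation_deg", "rms", "converged") %in% names(d)))
  expect_length(list.files(file.path(dir, "tracking_rois")), 2L)
})
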