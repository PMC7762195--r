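# Phantom construction, speckle sampler statistics, trajectories and
# calibration-target recordings.

test_that("phantoms are deterministic with the configured region levels", {
  ph1 <- makeFootPhantom(scale = 0.75)
  ph2 <- makeFootPhantom(scale = 0.75)
  expect_identical(ph1@perfusionMap, ph2@perfusionMap)
  expect_identical(ph1@shapeMask, ph2@shapeMask)

  lv <- ph1@regionLevels
  expect_setequal(unique(as.vector(ph1@perfusionMap)), c(0, unname(lv)))
  expect_true(all(ph1@perfusionMap[!ph1@shapeMask] == 0))

  # each ground-truth ROI sits on a homogeneous patch of its region
  for (roi in ph1@rois) {
    mask <- rasterizeEllipse(roi, dim(ph1@shapeMask))
    vals <- ph1@perfusionMap[mask]
    expect_gte(sum(mask), 25)
    expect_equal(mean(vals), unname(lv[[roiLabel(roi)]]),
                 info = roiLabel(roi))
  }

  # artifact boxes live outside the silhouette
  for (b in ph1@artifactBoxes)
    expect_false(any(ph1@shapeMask[b$y0:(b$y1 - 1), b$x0:(b$x1 - 1)]))

  expect_error(makeFootPhantom(scale = 0.05), "too small")
  expect_error(makeFootPhantom(perfusionLevels = c(foot = 80)), "entries")
})

test_that("the gamma speckle sampler reproduces target contrasts at 1/sqrt(N)", {
  cal <- testCalibration()
  set.seed(41)
  # static target, beta 1: fully developed speckle, raw contrast 1
  calB1 <- Calibration(1, 250)
  x <- sampleSpeckle(matrix(0, 64, 64), calB1)
  expect_lt(abs(popSd(x) / mean(x) - 1), 4 / sqrt(2 * 4096))

  # generic perfusion level: raw contrast K_cal / beta at N = 4096
  for (P in c(0, 100, 250)) {
    target <- perfusionToContrast(P, signalGain(cal)) / coherenceFactor(cal)
    y <- sampleSpeckle(matrix(P, 64, 64), cal)
    expect_lt(abs(popSd(y) / mean(y) - target), 5 * target / sqrt(2 * 4096))
  }

  # a beta below 1 cannot realize low perfusion (raw contrast > 1)
  expect_error(sampleSpeckle(matrix(0, 8, 8), Calibration(0.8, 250)),
               "raw contrast")
})

test_that("recordings are bit-identical for identical seeds and carry truth", {
  ph <- makeFootPhantom(scale = 0.6, artifacts = FALSE)
  traj <- makeMotionTrajectory(3, pivot = c(75, 115) * 0.6, seed = 2)
  cal <- testCalibration()
  a <- simulateRecording(ph, traj, cal, seed = 7)
  b <- simulateRecording(ph, traj, cal, seed = 7)
  expect_identical(a$recording@frames, b$recording@frames)
  expect_identical(a$recording@validity, b$recording@validity)

  gt <- a$groundTruth
  expect_length(gt$transforms, 3L)
  expect_length(gt$roiSets, 3L)
  expect_equal(gt$transforms[[1]]@rotation, 0)  # frame 1 is the identity
  expect_equal(gt$roiSets[[1]][[1]]@center, ph@rois[[1]]@center)

  # trajectories stay within their stated bounds
  long <- makeMotionTrajectory(200, pivot = c(50, 60), maxRotationDeg = 10,
                               maxTranslation = 15, seed = 5)
  rots <- vapply(long, function(t) t@rotation, numeric(1))
  expect_lte(max(abs(rots)) * 180 / pi, 10 + 1e-9)
})

test_that("calibration targets recover the true instrument constants", {
  tg <- simulateCalibrationTargets(betaTrue = 1.25, gainTrue = 250, seed = 11)
  cal <- calibrate(recordingStats(tg$static), recordingStats(tg$standard))
  expect_lt(abs(coherenceFactor(cal) - 1.25) / 1.25, 0.03)
  expect_lt(abs(signalGain(cal) - 250) / 250, 0.05)

  # noiseless analytic statistics invert exactly
  exact <- calibrate(list(mean_intensity = 1, std_intensity = 1 / 1.25,
                          pixel_count = 1e6),
                     list(mean_intensity = 1,
                          std_intensity = perfusionToContrast(250, 250) / 1.25,
                          pixel_count = 1e6))
  expect_equal(coherenceFactor(exact), 1.25, tolerance = 1e-12)
  expect_equal(signalGain(exact), 250, tolerance = 1e-9)

  # the recovered calibration reads a fresh static recording near 0 PU
  fresh <- simulateCalibrationTargets(seed = 99)
  expect_lt(abs(mean(measureUniformTarget(fresh$static, cal))), 5)
})

test_that("recordings round-trip through TIFF + sidecar", {
  ph <- makeFootPhantom(scale = 0.6, artifacts = FALSE)
  prot <- Protocol(c(1, 2), 3, c(NA, NA))
  sim <- simulateRecording(ph, rep(list(RigidTransform2D()), 3),
                           testCalibration(), protocol = prot, seed = 13)
  prefix <- file.path(withr::local_tempdir(), "rec")
  writeRecording(sim$recording, prefix)
  back <- readRecording(prefix)
  expect_equal(nFrames(back), 3L)
  expect_identical(back@validity, sim$recording@validity)
  # float32 pages: relative error at single precision
  expect_lt(max(abs(back@frames - sim$recording@frames)) /
              max(sim$recording@frames), 1e-6)
  expect_equal(protocol(back)@baselineWindow, c(1L, 2L))
})
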