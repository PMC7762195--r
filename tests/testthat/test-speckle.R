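# Speckle contrast, perfusion conversion and two-point calibration.

test_that("contrast equation matches hand-computed statistics", {
  # sigma equal to the mean with beta 1: the static-object normalization
  expect_equal(roiContrast(list(mean_intensity = 3, std_intensity = 3,
                                pixel_count = 100), beta = 1), 1)
  # zero variance
  expect_equal(roiContrast(list(mean_intensity = 5, std_intensity = 0,
                                pixel_count = 100), beta = 2), 0)
  # brute-force oracle on {2, 4, 6}: mean 4, population sd sqrt(8/3)
  st <- roiStats(c(2, 4, 6))
  expect_equal(st$mean_intensity, 4)
  expect_equal(st$std_intensity, sqrt(8 / 3))
  expect_equal(roiContrast(st, 1), sqrt(8 / 3) / 4)
  expect_error(roiContrast(list(mean_intensity = 0, std_intensity = 1,
                                pixel_count = 10), 1, label = "toe"),
               "toe")
})

test_that("perfusion mapping and its analytic inverse round-trip", {
  expect_equal(contrastToPerfusion(1, 250), 0)       # static object
  expect_equal(contrastToPerfusion(0.5, 10), 10)
  expect_equal(perfusionToContrast(0, 77), 1)
  expect_equal(perfusionToContrast(130, 130), 0.5)
  expect_error(contrastToPerfusion(0, 250), "contrast")
  expect_error(contrastToPerfusion(-0.2, 250), "contrast")
  expect_error(perfusionToContrast(-1, 250), "perfusion")

  # round trip on a grid, 1e-9 relative
  for (gain in seq(50, 500, by = 50)) {
    P <- seq(0, 500, by = 20)
    back <- contrastToPerfusion(perfusionToContrast(P, gain), gain)
    expect_lt(max(abs(back - P) / pmax(P, 1)), 1e-9)
  }
  expect_lt(abs(contrastToPerfusion(perfusionToContrast(250, 250), 250) - 250),
            1e-12)

  # strict monotonicity: P decreasing in K, increasing in gain for K < 1
  K <- seq(0.1, 1.5, by = 0.05)
  expect_true(all(diff(contrastToPerfusion(K, 100)) < 0))
  gains <- seq(50, 500, by = 25)
  expect_true(all(diff(vapply(gains, function(g)
    contrastToPerfusion(0.6, g), numeric(1))) > 0))
})

test_that("two-point calibration pins the targets to 0 and 250 PU exactly", {
  static <- list(mean_intensity = 1, std_intensity = 0.8, pixel_count = 4096)
  standard <- list(mean_intensity = 1, std_intensity = 0.4, pixel_count = 4096)
  cal <- calibrate(static, standard)
  expect_equal(coherenceFactor(cal), 1.25)    # 1 / 0.8
  expect_equal(signalGain(cal), 250)          # 250 / (1/0.5 - 1)

  # idempotence on the calibration inputs themselves
  expect_equal(roiContrast(static, coherenceFactor(cal)), 1)
  expect_equal(contrastToPerfusion(roiContrast(static, coherenceFactor(cal)),
                                   signalGain(cal)), 0)
  expect_equal(contrastToPerfusion(roiContrast(standard, coherenceFactor(cal)),
                                   signalGain(cal)), 250)

  # a standard indistinguishable from a static target cannot calibrate
  expect_error(calibrate(static, list(mean_intensity = 1, std_intensity = 0.9,
                                      pixel_count = 4096)),
               "calibration failure")
})

test_that("ROI statistics equal a brute-force loop over masked pixels", {
  set.seed(31)
  for (rep in 1:5) {
    img <- matrix(rexp(40 * 50), 40, 50)
    roi <- EllipseROI("r", c(runif(1, 10, 40), runif(1, 10, 30)),
                      c(runif(1, 4, 12), runif(1, 4, 9)), runif(1, -pi, pi))
    valid <- matrix(runif(40 * 50) > 0.2, 40, 50)
    mask <- rasterizeEllipse(roi, c(40, 50), valid)
    st <- roiStats(img[mask])
    # explicit loop oracle
    s <- 0; s2 <- 0; n <- 0
    for (y in 1:40) for (x in 1:50) if (mask[y, x]) {
      s <- s + img[y, x]; s2 <- s2 + img[y, x]^2; n <- n + 1
    }
    expect_equal(st$pixel_count, n)
    expect_equal(st$mean_intensity, s / n)
    expect_equal(st$std_intensity, sqrt(s2 / n - (s / n)^2), tolerance = 1e-10)
  }
})

test_that("perfusion traces handle static, uniform and starved ROIs", {
  cal <- testCalibration()
  set.seed(77)

  # uniform P = 100 patch: trace mean within speckle sampling tolerance
  pm <- matrix(100, 80, 80)
  fr <- array(0, c(80, 80, 10))
  for (f in 1:10) fr[, , f] <- sampleSpeckle(pm, cal)
  rec <- Recording(fr)
  roi <- EllipseROI("patch", c(40.5, 40.5), c(30, 30))
  tr <- perfusionTrace(rec, list(roi), cal)
  expect_equal(dim(perfusion(tr)), c(1L, 10L))
  expect_lt(abs(mean(perfusion(tr)) - 100), 5)

  # static target after calibration: all frames near 0 PU
  fr0 <- array(0, c(80, 80, 6))
  for (f in 1:6) fr0[, , f] <- sampleSpeckle(matrix(0, 80, 80), cal)
  tr0 <- perfusionTrace(Recording(fr0), list(roi), cal)
  expect_lt(abs(mean(perfusion(tr0))), 5)

  # ROI fully outside the validity mask: missing on all frames, warning
  dead <- matrix(FALSE, 80, 80)
  recDead <- Recording(fr[, , 1:3], array(rep(dead, 3), c(80, 80, 3)))
  expect_warning(trD <- perfusionTrace(recDead, list(roi), cal),
                 "valid-pixel threshold")
  expect_true(all(is.na(perfusion(trD))))

  # K > 1 frames are flagged, not clipped
  expect_true(S4Vectors::metadata(tr0)$n_contrast_above_one >= 0)
})
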