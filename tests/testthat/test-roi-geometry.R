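# Ellipse rasterization and rigid-transform algebra.

test_that("rasterized masks match a brute-force point-in-ellipse scan", {
  roi <- EllipseROI("c", c(25.5, 25.5), c(20, 20))
  mask <- rasterizeEllipse(roi, c(51, 51))
  expect_identical(mask, bruteForceEllipseMask(roi, c(51, 51)))
  # circle of radius 20: pixel count within 2 % of pi r^2
  expect_lt(abs(sum(mask) - pi * 400) / (pi * 400), 0.02)

  set.seed(5)
  for (rep in 1:5) {
    roi <- EllipseROI("e", c(runif(1, 5, 45), runif(1, 5, 45)),
                      c(runif(1, 3, 15), runif(1, 3, 15)), runif(1, -pi, pi))
    expect_identical(rasterizeEllipse(roi, c(50, 50)),
                     bruteForceEllipseMask(roi, c(50, 50)))
  }
})

test_that("degenerate rasterizations yield empty masks, not errors", {
  off <- EllipseROI("off", c(500, 500), c(10, 5))
  expect_equal(sum(rasterizeEllipse(off, c(60, 60))), 0)
  roi <- EllipseROI("r", c(30, 30), c(8, 8))
  none <- matrix(FALSE, 60, 60)
  expect_equal(sum(rasterizeEllipse(roi, c(60, 60), none)), 0)
})

test_that("ellipses transport rigidly: center mapped, axes kept, angle added", {
  roi <- EllipseROI("u", c(10, 0), c(6, 3), orientation = 0.2)
  expect_equal(transformEllipse(roi, RigidTransform2D()), roi)

  quarter <- transformEllipse(roi, RigidTransform2D(pi / 2, c(0, 0)))
  expect_equal(quarter@center, c(0, 10), tolerance = 1e-12)
  expect_equal(quarter@orientation, 0.2 + pi / 2)
  expect_equal(quarter@semiAxes, roi@semiAxes)

  set.seed(11)
  for (rep in 1:25) {
    roi <- EllipseROI("x", runif(2, -20, 80), c(runif(1, 2, 9), runif(1, 2, 9)),
                      runif(1, -pi, pi))
    t <- RigidTransform2D(runif(1, -pi, pi), runif(2, -30, 30))
    back <- transformEllipse(transformEllipse(roi, t), invertTransform(t))
    expect_equal(back@center, roi@center, tolerance = 1e-9)
    expect_equal(wrapAngle(back@orientation - roi@orientation), 0,
                 tolerance = 1e-9)
  }
})

test_that("rigid transforms form a group under composition", {
  t <- RigidTransform2D(0.7, c(4, -2))
  expect_equal(composeTransforms(RigidTransform2D(), t), t)
  expect_equal(invertTransform(t)@rotation, -0.7)
  idc <- composeTransforms(t, invertTransform(t))
  expect_equal(idc@rotation, 0, tolerance = 1e-12)
  expect_equal(idc@translation, c(0, 0), tolerance = 1e-12)

  set.seed(13)
  p <- cbind(runif(20, -50, 50), runif(20, -50, 50))
  for (rep in 1:200) {
    t1 <- RigidTransform2D(runif(1, -pi, pi), runif(2, -20, 20))
    t2 <- RigidTransform2D(runif(1, -pi, pi), runif(2, -20, 20))
    # documented convention: composeTransforms(t2, t1) applies t1 first
    expect_equal(applyTransform(composeTransforms(t2, t1), p),
                 applyTransform(t2, applyTransform(t1, p)),
                 tolerance = 1e-9)
  }
  # associativity
  t3 <- RigidTransform2D(-1.1, c(3, 9))
  t1 <- RigidTransform2D(0.3, c(1, 2)); t2 <- RigidTransform2D(-0.4, c(-5, 0))
  a <- composeTransforms(composeTransforms(t3, t2), t1)
  b <- composeTransforms(t3, composeTransforms(t2, t1))
  expect_equal(a@rotation, b@rotation, tolerance = 1e-12)
  expect_equal(a@translation, b@translation, tolerance = 1e-9)
})

test_that("mask area is approximately invariant under rigid motion", {
  set.seed(9)
  for (rep in 1:20) {
    roi <- EllipseROI("a", c(40, 45) + runif(2, -3, 3), c(9, 6),
                      runif(1, -pi, pi))
    t <- RigidTransform2D(runif(1, -pi, pi), runif(2, -5, 5))
    moved <- transformEllipse(roi, t)
    moved@center <- roi@center   # keep inside the image; area is what matters
    a0 <- sum(rasterizeEllipse(roi, c(90, 90)))
    a1 <- sum(rasterizeEllipse(moved, c(90, 90)))
    # boundary discretization: jitter scales with the perimeter
    expect_lt(abs(a1 - a0), 0.02 * a0 + 2)
  }
})

test_that("ROI and pixel-box JSON dialects round-trip", {
  rois <- list(EllipseROI("ulcer", c(10.5, 20.25), c(4, 3), 0.3),
               EllipseROI("foot", c(50, 60), c(12, 9), -1.2))
  f <- withr::local_tempfile(fileext = ".json")
  writeRois(rois, f)
  back <- readRois(f)
  expect_equal(length(back), 2L)
  expect_equal(back[[1]]@center, rois[[1]]@center)
  expect_equal(back[[2]]@orientation, rois[[2]]@orientation)
  expect_equal(vapply(back, roiLabel, character(1)), c("ulcer", "foot"))

  b <- withr::local_tempfile(fileext = ".json")
  writePixelBox(list(x0 = 1, y0 = 2, x1 = 90, y1 = 120), b)
  expect_equal(readPixelBox(b)$x1, 90)
  expect_error(writePixelBox(list(x0 = 5, y0 = 2, x1 = 5, y1 = 120), b),
               "empty")
})
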