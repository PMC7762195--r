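# TOI segmentation, PORH peak detection and per-TOI summaries.

test_that("PORH peak detection finds peaks and applies the plateau fallback", {
  # well-defined peak: symmetric rise then fall -> argmax frame
  tr <- c(rep(10, 5), seq(10, 100, by = 5), seq(95, 15, by = -5))
  expect_equal(findPorhPeak(tr, releaseFrame = 5), which.max(tr))

  # rise onto a plateau: first frame where the increase stops
  trP <- c(rep(10, 5), seq(10, 100, length.out = 15), rep(100, 20))
  peak <- findPorhPeak(trP, releaseFrame = 5)
  expect_gte(peak, 19)   # near the plateau onset (smoothing shifts by ~2)
  expect_lte(peak, 23)

  # monotone nondecreasing: fallback path, frame after the release
  trM <- c(rep(5, 5), seq(5, 200, length.out = 30))
  expect_gte(findPorhPeak(trM, 5), 6)

  # seeded noisy hyperemia curve with true peak at frame 40
  set.seed(21)
  f <- 11:80
  trN <- c(rep(100, 10), 100 + 250 * exp(-(f - 40)^2 / 200) -
             80 * (f < 18)) + rnorm(80, 0, 5)
  expect_lt(abs(findPorhPeak(trN, releaseFrame = 12) - 40), 4)

  expect_error(findPorhPeak(c(1, 2, 3), releaseFrame = 3), "release")
  expect_error(findPorhPeak(rep(NA_real_, 30), releaseFrame = 5), "no perfusion")
  expect_error(findPorhPeak(tr, 5, smoothingWindow = 4), "odd")
})

test_that("peak detection is shift-equivariant", {
  set.seed(8)
  base <- c(rep(20, 10), 20 + 180 * exp(-((11:60) - 30)^2 / 60)) + rnorm(60, 0, 3)
  p0 <- findPorhPeak(base, releaseFrame = 10)
  for (shift in c(5, 12)) {
    shifted <- c(rep(20, shift), base)
    expect_equal(findPorhPeak(shifted, releaseFrame = 10 + shift), p0 + shift)
  }
})

test_that("TOI segmentation respects the protocol, clipping and breaks", {
  prot <- Protocol(baselineWindow = c(1, 10), releaseFrame = 20,
                   buergerWindow = c(60, 80))
  w <- segmentTois(prot, porhPeakFrame = 40, peakHalfwidth = 2)
  expect_equal(w$baseline, c(1L, 10L))
  expect_equal(w$porh_peak, c(38L, 42L))
  expect_equal(w$buerger, c(60L, 80L))

  # peak at the first post-release frame: clipped at the left edge
  wc <- segmentTois(prot, porhPeakFrame = 21, peakHalfwidth = 2)
  expect_equal(wc$porh_peak, c(21L, 23L))

  # a break before the Buerger segment bounds the peak window
  protB <- Protocol(c(1, 10), 20, c(60, 80), breakFrames = 45L)
  wb <- segmentTois(protB, porhPeakFrame = 44, peakHalfwidth = 4)
  expect_lte(wb$porh_peak[2], 45L)
  for (nm in names(wb))
    expect_false(any(45L >= wb[[nm]][1] & 45L < wb[[nm]][2]))

  # peak outside the post-release region is rejected
  expect_error(segmentTois(prot, porhPeakFrame = 5), "post-release")
  # overlap is an error: peak window running into the baseline cannot
  # happen (clipping), but a malformed protocol is caught on construction
  expect_error(Protocol(c(1, 30), 20, c(60, 80)), "release")
})

test_that("TOI means average the non-missing frames only", {
  P <- matrix(75, 2, 20, dimnames = list(c("a", "b"), NULL))
  tr <- lscitrack:::newPerfusionTrace(P, P * 0 + 0.5, P * 0 + 100L, 0:19)
  w <- list(baseline = c(1L, 5L), porh_peak = c(8L, 12L), buerger = c(15L, 20L))
  s <- summarizeToi(tr, w)
  expect_equal(nrow(s), 6L)
  expect_true(all(s$mean_pu == 75))

  # one missing frame: mean over the rest, count reported
  P2 <- P; P2[1, 2] <- NA; P2[1, 3] <- 60
  tr2 <- lscitrack:::newPerfusionTrace(P2, P2 * 0 + 0.5, P2 * 0 + 100L, 0:19)
  s2 <- summarizeToi(tr2, w)
  row <- s2[s2$roi == "a" & s2$toi == "baseline", ]
  expect_equal(row$n_valid, 4L)
  expect_equal(row$mean_pu, mean(c(75, 60, 75, 75)))

  # TOI means are invariant to frame order within the window
  P3 <- P2[, c(5:1, 6:20)]
  tr3 <- lscitrack:::newPerfusionTrace(P3, P3 * 0 + 0.5, P3 * 0 + 100L, 0:19)
  expect_equal(summarizeToi(tr3, w)$mean_pu, s2$mean_pu)

  # an all-missing cell yields NA plus a warning
  P4 <- P; P4[2, 15:20] <- NA
  tr4 <- lscitrack:::newPerfusionTrace(P4, P4 * 0 + 0.5, P4 * 0 + 100L, 0:19)
  expect_warning(s4 <- summarizeToi(tr4, w), "no valid frames")
  expect_true(is.na(s4[s4$roi == "b" & s4$toi == "buerger", "mean_pu"]))
})

test_that("TOI labels land on the trace frames", {
  P <- matrix(1, 1, 10, dimnames = list("a", NULL))
  tr <- lscitrack:::newPerfusionTrace(P, P, P * 0 + 30L, 0:9)
  tr <- assignTois(tr, list(baseline = c(1L, 3L), porh_peak = c(5L, 7L)))
  toi <- SummarizedExperiment::colData(tr)$toi
  expect_equal(toi[1:3], rep("baseline", 3))
  expect_equal(toi[5:7], rep("porh_peak", 3))
  expect_true(is.na(toi[4]))
})
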