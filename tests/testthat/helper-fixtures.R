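# Shared fixtures, all generated in code.

testCalibration <- function() Calibration(beta = 1.25, gain = 250)

# Noiseless rendering of a moving phantom: binary silhouette frames (foot
# intensity 1, background 0), per-frame validity from the moved mask.
noiselessRecording <- function(phantom, trajectory, protocol = NULL) {
  d <- dim(phantom@shapeMask)
  n <- length(trajectory)
  fr <- array(0, c(d, n))
  va <- array(FALSE, c(d, n))
  for (f in seq_len(n)) {
    sm <- lscitrack:::warpNearest(phantom@shapeMask * 1, trajectory[[f]]) > 0.5
    fr[, , f] <- sm * 1
    va[, , f] <- sm
  }
  Recording(fr, va, protocol = protocol)
}

# Independent brute-force ellipse rasterization (double loop, no shared
# code with rasterizeEllipse).
bruteForceEllipseMask <- function(roi, shape) {
  H <- shape[1]; W <- shape[2]
  mask <- matrix(FALSE, H, W)
  co <- cos(roi@orientation); si <- sin(roi@orientation)
  for (y in seq_len(H)) for (x in seq_len(W)) {
    dx <- x - roi@center[1]; dy <- y - roi@center[2]
    u <- dx * co + dy * si
    v <- -dx * si + dy * co
    mask[y, x] <- (u / roi@semiAxes[1])^2 + (v / roi@semiAxes[2])^2 <= 1
  }
  mask
}

maxRoiCenterError <- function(estimatedSets, trueSets) {
  vapply(seq_along(estimatedSets), function(f) {
    est <- estimatedSets[[f]]; tru <- trueSets[[f]]
    max(vapply(seq_along(est), function(r)
      sqrt(sum((est[[r]]@center - tru[[r]]@center)^2)), numeric(1)))
  }, numeric(1))
}

# Independent ICC oracle: mean squares from stats::aov on the long-format
# two-way layout (different route than the package's direct sums).
aovIccOracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  d <- data.frame(y = as.vector(m),
                  subject = factor(rep(seq_len(n), k)),
                  rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subject + rater, data = d))[[1]][["Mean Sq"]]
  MSR <- ms[1]; MSC <- ms[2]; MSE <- ms[3]
  (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
}

# 10 x 2 ratings fixture with reference ICC(A,1) values computed with an
# independent implementation (pingouin 0.6.1; matrix drawn from
# numpy default_rng(7), normal(100, 20)).
pingouinFixture <- function() {
  m <- matrix(c(
    100.02460306714966, 105.97491075016940,
     94.51724289275565,  82.18816322485452,
     90.90658429656555,  80.16706890007075,
    101.20287205194877, 126.80430491109067,
     90.15586962897340,  87.59050200360119,
    109.79684100370396, 107.13774016320122,
    102.10828497995797,  81.39063910583590,
     99.41496355073453, 113.90606388916575,
     73.11570905429836,  90.84768477919563,
     61.97554520398312,  74.20924520430049), ncol = 2, byrow = TRUE)
  list(ratings = m,
       icc = 0.581890625182063,
       f = 3.596287040468163,
       p = 0.03510156089595241,
       ci = c(-0.05, 0.88))   # reference rounds its CI to 2 decimals
}
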