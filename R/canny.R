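# Canny edge detection on intensity frames. EBImage supplies the
# primitives (separable Gaussian blur, 2D convolution, morphology and
# connected-component labeling); the Canny chain itself (gradient,
# non-maximum suppression, hysteresis) is implemented here.
# Coordinate convention: see utils.R.

#' Canny parameters
#'
#' Defaults suit smoothed speckle images of a foot silhouette: a 2 px
#' Gaussian averages out the speckle grain before differentiation, and the
#' hysteresis thresholds auto-adapt to the gradient-magnitude distribution
#' (high = 90th percentile of non-zero magnitudes, low = 0.4 * high).
#'
#' @param sigma Gaussian smoothing standard deviation, pixels.
#' @param highQuantile quantile of non-zero gradient magnitudes used as
#'   the strong-edge threshold.
#' @param lowFraction low threshold as a fraction of the high threshold.
#' @return list of parameters for [cannyEdges()].
#' @export
cannyParams <- function(sigma = 2, highQuantile = 0.9, lowFraction = 0.4) {
  stopifnot(sigma > 0, highQuantile > 0, highQuantile < 1,
            lowFraction > 0, lowFraction <= 1)
  list(sigma = sigma, highQuantile = highQuantile, lowFraction = lowFraction)
}

sobelKernels <- function() {
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3) / 8   # d/dx (columns)
  ky <- t(kx)                                               # d/dy (rows)
  list(kx = kx, ky = ky)
}

shiftMatrix <- function(m, dy, dx) {
  # shift content by (dy, dx), padding with 0 (used for neighbor lookups)
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  ys <- max(1, 1 + dy):min(H, H + dy)
  xs <- max(1, 1 + dx):min(W, W + dx)
  out[ys, xs] <- m[ys - dy, xs - dx]
  out
}

#' Canny edge detection
#'
#' Gaussian smoothing, Sobel gradients, non-maximum suppression along the
#' quantized gradient direction, and two-threshold hysteresis (weak edge
#' pixels survive only in a connected component that contains a strong
#' pixel; components are taken with 8-connectivity).
#'
#' @param img numeric H x W intensity matrix.
#' @param params a [cannyParams()] list.
#' @return logical H x W edge mask.
#' @export
cannyEdges <- function(img, params = cannyParams()) {
  if (!all(is.finite(img))) stopf("image contains non-finite intensities")
  H <- nrow(img); W <- ncol(img)
  sm <- EBImage::gblur(img, sigma = params$sigma)
  k <- sobelKernels()
  gx <- EBImage::filter2(sm, k$kx)
  gy <- EBImage::filter2(sm, k$ky)
  mag <- sqrt(gx^2 + gy^2)
  if (max(mag) <= 0) return(matrix(FALSE, H, W))

  # non-maximum suppression: quantize direction into 4 bins
  ang <- atan2(gy, gx)               # (-pi, pi]
  ang[ang < 0] <- ang[ang < 0] + pi  # fold to [0, pi)
  bin <- as.integer(floor((ang + pi / 8) / (pi / 4))) %% 4L
  # bin 0: horizontal gradient -> compare left/right neighbors (dx +/- 1)
  # bin 1: diagonal dx=+1, dy=+1; bin 2: vertical (dy +/- 1); bin 3: dx=+1, dy=-1
  offs <- list(c(0, 1), c(1, 1), c(1, 0), c(-1, 1))
  keep <- matrix(FALSE, H, W)
  for (b in 0:3) {
    o <- offs[[b + 1]]
    n1 <- shiftMatrix(mag, o[1], o[2])
    n2 <- shiftMatrix(mag, -o[1], -o[2])
    keep <- keep | (bin == b & mag >= n1 & mag >= n2)
  }
  keep <- keep & mag > 0

  high <- stats::quantile(mag[mag > 0], params$highQuantile, names = FALSE)
  low <- params$lowFraction * high
  strong <- keep & mag >= high
  weak <- keep & mag >= low
  if (!any(strong)) return(matrix(FALSE, H, W))

  lab <- labelEdgeComponents(weak)
  goodLabels <- unique(lab[strong])
  out <- weak & (lab %in% goodLabels)
  matrix(out, H, W)
}

# 8-connected component labels for an edge mask (EBImage::bwlabel is
# 4-connected, which fragments diagonal edge chains). Union-find over the
# edge pixels; edge masks are sparse so this is cheap.
labelEdgeComponents <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  idx <- which(mask)
  n <- length(idx)
  if (!n) return(lab)
  rr <- ((idx - 1L) %% H) + 1L
  cc <- ((idx - 1L) %/% H) + 1L
  id <- matrix(0L, H, W)
  id[idx] <- seq_len(n)
  parent <- seq_len(n)
  findRoot <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]  # path halving
      i <- parent[i]
    }
    i
  }
  for (o in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(-1L, 1L))) {
    nr <- rr + o[1]; nc <- cc + o[2]
    ok <- nr >= 1L & nr <= H & nc >= 1L & nc <= W
    nb <- integer(n); nb[ok] <- id[cbind(nr[ok], nc[ok])]
    pair <- which(nb > 0L)
    for (i in pair) {
      ra <- findRoot(i); rb <- findRoot(nb[i])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(n), findRoot, integer(1))
  lab[idx] <- match(roots, unique(roots))
  lab
}

# Largest 8-connected component of an edge mask, as an n x 2 (x, y)
# matrix. Only the single dominant chain is kept: including secondary
# chains makes the point sets of different frames inconsistent (a chain
# can pass the cut in one frame and fail it in the next), which is worse
# for registration than a partial but consistent silhouette.
largestComponentPoints <- function(mask) {
  lab <- labelEdgeComponents(mask)
  labs <- lab[lab > 0]
  if (!length(labs)) return(matrix(numeric(0), 0, 2))
  best <- as.integer(names(which.max(table(labs))))
  idx <- which(lab == best, arr.ind = TRUE)
  cbind(x = idx[, 2], y = idx[, 1])
}
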