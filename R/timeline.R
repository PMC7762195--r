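# Timespans of interest: PORH peak detection, TOI segmentation and
# per-TOI summary statistics.

#' Detect the post-occlusive reactive hyperemia peak
#'
#' After the occlusion cuff is released, perfusion overshoots; the moment
#' of peak perfusion defines the PORH timespan of interest. The
#' post-release trace is smoothed with a centered moving average. If the
#' smoothed trace has a strict local maximum (a value exceeding both of
#' its neighbors), the frame of the global maximum is returned. When no
#' well-defined peak exists (the perfusion rises onto a plateau), the
#' fallback takes the maximum measured value once the perfusion stops
#' increasing: the first frame at which the smoothed forward difference
#' stays below \code{plateauEpsilon} for \code{plateauRun} consecutive
#' frames. If the trace never stops increasing, the frame of the maximum
#' (the last rising frame) is returned.
#'
#' @param trace numeric per-frame perfusion for one ROI (full recording;
#'   missing frames are linearly interpolated inside the search window).
#' @param releaseFrame frame index of the occlusion release; the peak is
#'   searched in frames after this one.
#' @param searchEnd last frame of the search window (default: end of the
#'   trace, or the frame before the first break/Buerger frame if the
#'   protocol is supplied via \code{trace} attributes).
#' @param smoothingWindow odd moving-average width, frames (default 5).
#' @param plateauEpsilon plateau slope threshold, PU/frame (default 1).
#' @param plateauRun consecutive sub-threshold differences required
#'   (default 5).
#' @return frame index of the detected peak (in whole-trace coordinates).
#' @export
findPorhPeak <- function(trace, releaseFrame, searchEnd = length(trace),
                         smoothingWindow = 5L, plateauEpsilon = 1,
                         plateauRun = 5L) {
  if (smoothingWindow < 1L || smoothingWindow %% 2L == 0L)
    stopf("smoothingWindow must be odd and >= 1")
  if (releaseFrame >= searchEnd)
    stopf("no frames after the occlusion release to search")
  win <- (releaseFrame + 1L):searchEnd
  post <- trace[win]
  if (all(is.na(post))) stopf("PORH search window contains no perfusion values")
  if (length(post) < smoothingWindow)
    stopf("PORH search window (%d frames) shorter than the smoothing window (%d)",
          length(post), smoothingWindow)
  # fill interior missing values so smoothing stays defined
  if (anyNA(post)) {
    ok <- which(!is.na(post))
    post <- stats::approx(ok, post[ok], xout = seq_along(post), rule = 2)$y
  }
  sm <- movingAverage(post, smoothingWindow)

  m <- length(sm)
  if (m >= 3L) {
    interior <- 2:(m - 1L)
    localMax <- sm[interior] > sm[interior - 1L] & sm[interior] > sm[interior + 1L]
    if (any(localMax)) return(win[which.max(sm)])
  }
  # fallback: perfusion stopped increasing
  d <- diff(sm)
  below <- d < plateauEpsilon
  run <- rle(below)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1L
  hit <- which(run$values & run$lengths >= plateauRun)
  if (length(hit)) return(win[starts[hit[1]]])
  win[which.max(sm)]
}

# centered moving average with shrinking window at the edges
movingAverage <- function(x, w) {
  h <- (w - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i)
    mean(x[max(1L, i - h):min(n, i + h)]), numeric(1))
}

#' Segment a recording into timespans of interest
#'
#' TOI 1 (baseline) is the protocol's baseline window; TOI 2 (PORH peak)
#' is a symmetric window of \code{peakHalfwidth} frames around the
#' detected peak, clipped to the post-release region (after the release
#' frame, before the next break or the Buerger window); TOI 3 (Buerger)
#' is the protocol's Buerger window. No TOI may span a recording break,
#' and the three windows must be disjoint.
#'
#' @param protocol a [Protocol-class].
#' @param porhPeakFrame peak frame from [findPorhPeak()].
#' @param peakHalfwidth frames either side of the peak (default 2).
#' @return named list of integer \code{c(first, last)} windows:
#'   \code{baseline}, \code{porh_peak}, and \code{buerger} when present.
#' @export
segmentTois <- function(protocol, porhPeakFrame, peakHalfwidth = 2L) {
  lo <- protocol@releaseFrame + 1L
  hi <- Inf
  if (hasBuerger(protocol)) hi <- protocol@buergerWindow[1] - 1L
  brk <- protocol@breakFrames
  if (length(brk)) {
    # a break listed as frame b pauses the recording between b and b + 1
    after <- brk[brk > protocol@releaseFrame]
    if (length(after)) hi <- min(hi, min(after))
  }
  if (porhPeakFrame < lo || porhPeakFrame > hi)
    stopf("PORH peak frame %d lies outside the post-release region [%d, %s]",
          porhPeakFrame, lo, format(hi))
  toi2 <- c(max(lo, porhPeakFrame - peakHalfwidth),
            min(hi, porhPeakFrame + peakHalfwidth))
  windows <- list(baseline = protocol@baselineWindow, porh_peak = as.integer(toi2))
  if (hasBuerger(protocol)) windows$buerger <- protocol@buergerWindow

  # disjointness and break checks
  nm <- names(windows)
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    if (any(brk >= w[1] & brk < w[2]))
      stopf("TOI '%s' [%d, %d] spans a recording break", nm[i], w[1], w[2])
    for (j in seq_len(i - 1L)) {
      v <- windows[[j]]
      if (w[1] <= v[2] && v[1] <= w[2])
        stopf("TOI windows '%s' [%d, %d] and '%s' [%d, %d] overlap",
              nm[j], v[1], v[2], nm[i], w[1], w[2])
    }
  }
  windows
}

#' Assign TOI labels to the frames of a trace
#'
#' @param trace a [PerfusionTrace-class].
#' @param windows TOI windows from [segmentTois()].
#' @return the trace with \code{colData()$toi} filled in.
#' @export
assignTois <- function(trace, windows) {
  toi <- rep(NA_character_, ncol(trace))
  for (nm in names(windows)) {
    w <- windows[[nm]]
    toi[seq(w[1], w[2])] <- nm
  }
  SummarizedExperiment::colData(trace)$toi <- toi
  trace
}

#' Mean perfusion per ROI per TOI
#'
#' Arithmetic mean over the non-missing frames of each TOI window for each
#' ROI, with the number of contributing frames. A TOI with zero valid
#' frames for an ROI yields a missing summary and a warning.
#'
#' @param trace a [PerfusionTrace-class].
#' @param windows TOI windows from [segmentTois()].
#' @return data.frame with columns roi, toi, mean_pu, n_valid.
#' @export
summarizeToi <- function(trace, windows) {
  P <- perfusion(trace)
  labels <- roiLabels(trace)
  rows <- list()
  for (nm in names(windows)) {
    w <- windows[[nm]]
    if (w[2] > ncol(P)) stopf("TOI '%s' extends past the end of the trace", nm)
    sub <- P[, seq(w[1], w[2]), drop = FALSE]
    nValid <- rowSums(!is.na(sub))
    m <- rowMeans(sub, na.rm = TRUE)
    m[nValid == 0L] <- NA_real_
    rows[[nm]] <- data.frame(roi = labels, toi = nm, mean_pu = unname(m),
                             n_valid = unname(nValid))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (any(out$n_valid == 0L))
    warnf("%d (ROI, TOI) cell(s) have no valid frames: summary missing",
          sum(out$n_valid == 0L))
  out
}
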