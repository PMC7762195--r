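# Recording I/O: multi-page TIFF stacks with a JSON sidecar.
# TIFF pages are float32 in [0, 1]; raw intensities are arbitrary linear
# units, so the frame maximum is recorded in the sidecar
# (intensity_scale) and restored on read.

#' Read and write a protocol as JSON
#'
#' Dialect: \code{\{baseline: [f0, f1], release_frame, buerger: [f0, f1],
#' frame_rate_hz, breaks: [...]\}}; \code{buerger} may be null.
#'
#' @param path file path.
#' @return \code{readProtocol}: a [Protocol-class].
#' @export
readProtocol <- function(path) {
  j <- jsonlite::fromJSON(path)
  Protocol(baselineWindow = j$baseline,
           releaseFrame = j$release_frame,
           buergerWindow = if (is.null(j$buerger)) c(NA, NA) else j$buerger,
           frameRate = j$frame_rate_hz %||% 1,
           breakFrames = j$breaks %||% integer(0))
}

#' @rdname readProtocol
#' @param protocol a [Protocol-class].
#' @export
writeProtocol <- function(protocol, path) {
  jsonlite::write_json(
    list(baseline = protocol@baselineWindow,
         release_frame = protocol@releaseFrame,
         buerger = if (hasBuerger(protocol)) protocol@buergerWindow else NULL,
         frame_rate_hz = protocol@frameRate,
         breaks = protocol@breakFrames),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write a recording as multi-page TIFF + sidecar JSON
#'
#' Writes \code{<prefix>.tif} (intensity frames, float32),
#' \code{<prefix>_mask.tif} (per-frame validity) and
#' \code{<prefix>.json} (frame times, intensity scale, protocol).
#'
#' @param recording a [Recording-class].
#' @param prefix output path prefix.
#' @return invisibly, the sidecar path.
#' @export
writeRecording <- function(recording, prefix) {
  scale <- max(recording@frames, 1e-12)
  n <- nFrames(recording)
  tiff::writeTIFF(lapply(seq_len(n), function(f) getFrame(recording, f) / scale),
                  paste0(prefix, ".tif"), bits.per.sample = 32L,
                  compression = "none")
  tiff::writeTIFF(lapply(seq_len(n), function(f) getValidity(recording, f) * 1),
                  paste0(prefix, "_mask.tif"), bits.per.sample = 8L,
                  compression = "none")
  side <- list(intensity_scale = scale, times_s = recording@times,
               n_frames = n)
  sidecar <- paste0(prefix, ".json")
  jsonlite::write_json(side, sidecar, auto_unbox = TRUE, digits = NA)
  if (!is.null(protocol(recording)))
    writeProtocol(protocol(recording), paste0(prefix, "_protocol.json"))
  invisible(sidecar)
}

#' Read a recording written by [writeRecording()]
#'
#' @param prefix path prefix used at write time.
#' @return a [Recording-class].
#' @export
readRecording <- function(prefix) {
  pages <- tiff::readTIFF(paste0(prefix, ".tif"), all = TRUE)
  side <- jsonlite::fromJSON(paste0(prefix, ".json"))
  d <- dim(pages[[1]])
  frames <- array(unlist(pages), c(d, length(pages))) * side$intensity_scale
  maskPath <- paste0(prefix, "_mask.tif")
  valid <- if (file.exists(maskPath)) {
    mp <- tiff::readTIFF(maskPath, all = TRUE)
    array(unlist(mp), c(d, length(mp))) > 0.5
  } else array(TRUE, c(d, length(pages)))
  protPath <- paste0(prefix, "_protocol.json")
  prot <- if (file.exists(protPath)) readProtocol(protPath) else NULL
  Recording(frames, valid, times = side$times_s, protocol = prot)
}
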