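# Shared coordinate convention (used by every module):
# pixel-center coordinates, 1-based; x = column index (rightward),
# y = row index (downward); rotation angles are measured counter-clockwise
# in the (x, y) frame and rotations act about the coordinate origin, with
# the translation absorbing any pivot.

#' Population standard deviation
#'
#' Standard deviation with the 1/N convention (divide by the pixel count,
#' not N - 1). Speckle contrast uses population statistics so that small
#' worked examples are deterministic; for regions of hundreds of pixels the
#' difference from the sample convention is negligible.
#'
#' @param x numeric vector (NAs removed).
#' @return non-negative scalar.
#' @export
popSd <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Wrap an angle into (-pi, pi]
#' @param a angle(s) in radians.
#' @return wrapped angle(s).
#' @export
wrapAngle <- function(a) {
  w <- (a + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## Validate a half-open pixel box list(x0, y0, x1, y1); keep pixels with
## x0 <= x < x1 and y0 <= y < y1.
checkPixelBox <- function(box) {
  if (is.null(box)) return(invisible(NULL))
  need <- c("x0", "y0", "x1", "y1")
  if (!all(need %in% names(box)))
    stopf("pixel box needs fields %s", paste(need, collapse = ", "))
  if (box$x1 <= box$x0 || box$y1 <= box$y0)
    stopf("pixel box is empty: [%s, %s) x [%s, %s)",
          box$x0, box$x1, box$y0, box$y1)
  invisible(NULL)
}
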