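#' Decibel / linear intensity conversion
#'
#' The package stores OCT intensity in decibels with the convention
#' `dB = 10*log10(I_linear)` (equivalently `20*log10` of detected amplitude).
#' Attenuation, speckle and calibration operate on linear intensity;
#' co-occurrence texture consumes the log-transformed (dB) data directly.
#'
#' @param db,linear numeric values to convert.
#' @param factor decibel factor: 10 for intensity (default), 20 for amplitude.
#' @return converted numeric values; the two functions are exact inverses.
#' @examples
#' dbToLinear(0)            # 1
#' dbToLinear(6)            # ~3.981 with the intensity convention
#' dbToLinear(6, factor = 20)  # ~1.995
#' linearToDb(dbToLinear(-37.2))
#' @export
dbToLinear <- function(db, factor = 10) {
  stopifnot(all(is.finite(factor)), factor > 0)
  10^(db / factor)
}

#' @rdname dbToLinear
#' @export
linearToDb <- function(linear, factor = 10) {
  stopifnot(all(is.finite(factor)), factor > 0)
  factor * log10(linear)
}

## ---- shared coordinate helpers ----------------------------------------
## Arrays are [frame, azimuth, depth], 1-based, closed ranges. Depth grows
## away from the catheter core; azimuth wraps; frames run proximal->distal.

#' Wrap azimuthal indices onto 1..n
#'
#' Single shared helper enforcing the cylindrical azimuth convention
#' (index `n + 1` is index `1`). Every module that steps across the azimuth
#' seam goes through this function.
#'
#' @param i integer indices (any range).
#' @param n number of azimuthal samples.
#' @return indices wrapped into `1..n`.
#' @export
wrapAzimuth <- function(i, n) ((i - 1L) %% n) + 1L

#' Rotate a volume or en face map azimuthally
#'
#' Cyclic shift along the azimuth axis, used by the rotation-equivariance
#' property tests: rotating the input volume must rotate every en face
#' biomarker map identically.
#'
#' @param x an [OctVolume-class], a 3-D array, or an en face matrix.
#' @param by integer shift (positive = towards higher azimuth index).
#' @return object of the same type, rotated.
#' @export
rotateAzimuth <- function(x, by) {
  if (is(x, "OctVolume")) {
    out <- x
    out@intensity <- rotateAzimuth(x@intensity, by)
    return(out)
  }
  if (is.matrix(x)) {
    n <- ncol(x)
    return(x[, wrapAzimuth(seq_len(n) - by, n), drop = FALSE])
  }
  n <- dim(x)[2L]
  x[, wrapAzimuth(seq_len(n) - by, n), , drop = FALSE]
}

## Gaussian smoothing of a vector with half-sample symmetric padding.
## Symmetric padding reflects each boundary weight back onto a real sample
## bijectively, so the window mean is exactly preserved -- the property the
## noise-floor estimator relies on.
gaussSmooth1d <- function(x, width = 5L, sigma = 1) {
  if (length(x) == 0L || width <= 1L) return(x)
  half <- (width - 1L) %/% 2L
  k <- exp(-((-half:half)^2) / (2 * sigma^2))
  k <- k / sum(k)
  n <- length(x)
  pad <- c(x[pmin(half:1, n)], x, x[pmax(n - seq_len(half) + 1L, 1L)])
  out <- stats::filter(pad, k, sides = 2)
  as.numeric(out[(half + 1L):(half + n)])
}

## Circular running median along a vector (azimuth), NA-tolerant.
circularMedian <- function(x, width = 5L) {
  n <- length(x)
  half <- (width - 1L) %/% 2L
  idx <- outer(seq_len(n), -half:half, function(i, k) wrapAzimuth(i + k, n))
  apply(matrix(x[idx], nrow = n), 1L, stats::median, na.rm = TRUE)
}

## Morphological closing of a logical vector along the (wrapped) azimuth:
## dilation then erosion with a flat structuring element of given width.
circularClose <- function(v, width = 3L) {
  n <- length(v)
  half <- (width - 1L) %/% 2L
  idx <- outer(seq_len(n), -half:half, function(i, k) wrapAzimuth(i + k, n))
  dil <- apply(matrix(v[idx], nrow = n), 1L, any)
  apply(matrix(dil[idx], nrow = n), 1L, all)
}
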