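#' @include AllClasses.R
NULL

#' Accessors for OCT-AFI containers
#'
#' Small accessor generics shared by the data containers: `intensity()`
#' returns the stored pixel data (dB for [OctVolume-class], detector units or
#' uM fluorescein for [AfiMap-class]), `axialPitch()`, `azimuthalPitch()` and
#' `framePitch()` return physical pixel sizes in micrometres, and
#' `maBounds()` returns the per-volume depth bookkeeping for the fundamental
#' image and the multipath artifact band.
#'
#' @param x a container object.
#' @return `intensity()` an array or matrix; pitch accessors a scalar in
#'   micrometres; `maBounds()` a named integer vector with elements `fiEnd`
#'   (last depth index of the fundamental image, 1-based inclusive) and
#'   `maStart` (first depth index of the multipath band, `NA` if absent).
#' @name accessors
#' @aliases intensity axialPitch azimuthalPitch framePitch maBounds
#' @examples
#' cfg <- phantomConfig(nFrames = 4, nAzimuth = 32, nDepth = 80, seed = 1)
#' ph <- generatePhantom(cfg)
#' dim(intensity(oct(ph)))
#' axialPitch(oct(ph))
NULL

#' @rdname accessors
#' @export
setGeneric("intensity", function(x) standardGeneric("intensity"))

#' @rdname accessors
#' @export
setGeneric("axialPitch", function(x) standardGeneric("axialPitch"))

#' @rdname accessors
#' @export
setGeneric("azimuthalPitch", function(x) standardGeneric("azimuthalPitch"))

#' @rdname accessors
#' @export
setGeneric("framePitch", function(x) standardGeneric("framePitch"))

#' @rdname accessors
#' @export
setGeneric("maBounds", function(x) standardGeneric("maBounds"))

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname accessors
#' @export
setGeneric("nAzimuth", function(x) standardGeneric("nAzimuth"))

#' @rdname accessors
#' @export
setGeneric("nDepth", function(x) standardGeneric("nDepth"))

#' @rdname accessors
#' @export
setGeneric("afiUnits", function(x) standardGeneric("afiUnits"))

#' @rdname accessors
#' @export
setGeneric("isCalibrated", function(x) standardGeneric("isCalibrated"))

#' @rdname accessors
#' @export
setGeneric("oct", function(x) standardGeneric("oct"))

#' @rdname accessors
#' @export
setGeneric("afi", function(x) standardGeneric("afi"))
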