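#' @include AllClasses.R AllGenerics.R
NULL

#' @rdname accessors
#' @export
setMethod("intensity", "OctVolume", function(x) x@intensity)

#' @rdname accessors
#' @export
setMethod("intensity", "AfiMap", function(x) x@intensity)

#' @rdname accessors
#' @export
setMethod("axialPitch", "OctVolume", function(x) x@axialPitch)

#' @rdname accessors
#' @export
setMethod("azimuthalPitch", "OctVolume", function(x) x@azimuthalPitch)

#' @rdname accessors
#' @export
setMethod("framePitch", "OctVolume", function(x) x@framePitch)

#' @rdname accessors
#' @export
setMethod("maBounds", "OctVolume", function(x)
  c(fiEnd = x@fiEnd, maStart = x@maStart))

#' @rdname accessors
#' @export
setMethod("nFrames", "OctVolume", function(x) dim(x@intensity)[1L])

#' @rdname accessors
#' @export
setMethod("nAzimuth", "OctVolume", function(x) dim(x@intensity)[2L])

#' @rdname accessors
#' @export
setMethod("nDepth", "OctVolume", function(x) dim(x@intensity)[3L])

#' @rdname accessors
#' @export
setMethod("nFrames", "AfiMap", function(x) nrow(x@intensity))

#' @rdname accessors
#' @export
setMethod("nAzimuth", "AfiMap", function(x) ncol(x@intensity))

#' @rdname accessors
#' @export
setMethod("afiUnits", "AfiMap", function(x) x@units)

#' @rdname accessors
#' @export
setMethod("isCalibrated", "AfiMap", function(x) x@calibrated)

#' @rdname accessors
#' @export
setMethod("oct", "StandardVolume", function(x) x@oct)

#' @rdname accessors
#' @export
setMethod("afi", "StandardVolume", function(x) x@afi)

#' @rdname accessors
#' @export
setMethod("oct", "PhantomBundle", function(x) x@oct)

#' @rdname accessors
#' @export
setMethod("afi", "PhantomBundle", function(x) x@afi)

setMethod("show", "OctVolume", function(object) {
  d <- dim(object@intensity)
  cat("OctVolume:", d[1L], "frames x", d[2L], "azimuth x", d[3L], "depth\n")
  cat(sprintf("  pitch (um): axial %g, azimuthal %g, frame %g\n",
              object@axialPitch, object@azimuthalPitch, object@framePitch))
  cat(sprintf("  intensity range (dB): [%.1f, %.1f]\n",
              min(object@intensity), max(object@intensity)))
  cat(sprintf("  fundamental image ends at z = %d; multipath band: %s\n",
              object@fiEnd,
              if (is.na(object@maStart)) "none"
              else paste0("z >= ", object@maStart)))
})

setMethod("show", "AfiMap", function(object) {
  d <- dim(object@intensity)
  cat("AfiMap:", d[1L], "frames x", d[2L], "azimuth,",
      if (object@calibrated) "calibrated (uM fluorescein)\n"
      else "raw detector units\n")
  n <- sum(object@uncalculated)
  if (n) cat("  uncalculated pixels:", n, "\n")
})

setMethod("show", "StandardVolume", function(object) {
  cat(object@kind, "calibration standard\n")
  show(object@oct)
})

setMethod("show", "DepthIntensityModel", function(object) {
  p <- object@params
  cat(sprintf(
    "%s standard depth-intensity model: I(d) = %.4g * exp(-%.4g d) + %.4g\n",
    object@kind, p[["a"]], p[["b"]], p[["c"]]))
  cat(sprintf("  valid depth range: [%g, %g] um, fit RMSE %.3g\n",
              object@validRange[1L], object@validRange[2L], object@rmse))
})

setMethod("show", "AttenuationVolume", function(object) {
  cat("AttenuationVolume: delta =", object@delta, "mm\n")
  cat(sprintf("  %d columns evaluated, %d flagged\n",
              sum(!is.na(object@nLast)), sum(object@flagged, na.rm = TRUE)))
  mu <- object@mu[!is.na(object@mu)]
  if (length(mu))
    cat(sprintf("  mu range (mm^-1): [%.2f, %.2f]\n", min(mu), max(mu)))
})

setMethod("show", "PhantomConfig", function(object) {
  cat(sprintf("PhantomConfig: %d x %d x %d (frame x azimuth x depth), seed %d\n",
              object@nFrames, object@nAzimuth, object@nDepth, object@seed))
  cat(sprintf("  mu superficial/deep: %g / %g mm^-1, boundary %g um\n",
              object@muSuperficial, object@muDeep, object@layerBoundaryDepth))
  cat(sprintf("  concentration %g uM, speckle shape %g, noise floor %g dB\n",
              object@concentration, object@speckleShape, object@noiseFloorDb))
  if (length(object@lesionSpec))
    cat("  lesions:", length(object@lesionSpec), "\n")
})

setMethod("show", "PhantomBundle", function(object) {
  cat("PhantomBundle (synthetic OCT-AFI acquisition with ground truth)\n")
  show(object@oct)
  cat(sprintf("  specimen frames: %d..%d\n",
              object@metadata$specimenFrames[1L],
              object@metadata$specimenFrames[2L]))
})
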