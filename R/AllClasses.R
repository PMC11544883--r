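#' @import methods
NULL

## Coordinate convention (shared by every module, see coords.R):
## arrays are [frame, azimuth, depth]; indices are 1-based and ranges closed;
## depth index increases away from the catheter core; azimuth wraps
## (index nAzimuth + 1 == 1); frames are ordered proximal -> distal.
## En face maps are [frame, azimuth] matrices with NA marking invalid pixels.

#' OctVolume: helically scanned OCT backscatter volume
#'
#' Container for a 3-D OCT intensity volume in decibels, indexed
#' `[frame, azimuth, depth]`, together with the physical pixel sizes and the
#' per-volume depth bookkeeping of the fundamental image ('FI') and the
#' multipath artifact ('MA') band produced by higher-order fiber modes in a
#' double-clad-fiber catheter. Stored intensity is `10*log10` of linear
#' intensity (equivalently `20*log10` of detected amplitude).
#'
#' @slot intensity numeric 3-D array `[frame, azimuth, depth]`, dB.
#' @slot axialPitch depth pixel size, micrometres (water-index corrected).
#' @slot azimuthalPitch azimuthal pixel size at the window tube, micrometres.
#' @slot framePitch pullback distance between consecutive frames, micrometres.
#' @slot fiEnd last depth index (1-based, inclusive) of the fundamental image;
#'   pixels beyond it belong to artifact bands or padding.
#' @slot maStart first depth index of the multipath band at the end of the
#'   A-line, or `NA` when no multipath artifact is present there.
#' @export
setClass("OctVolume",
  representation(
    intensity = "array",
    axialPitch = "numeric",
    azimuthalPitch = "numeric",
    framePitch = "numeric",
    fiEnd = "integer",
    maStart = "integer"
  )
)

setValidity("OctVolume", function(object) {
  msg <- character()
  if (length(dim(object@intensity)) != 3L)
    msg <- c(msg, "intensity must be a 3-D array [frame, azimuth, depth]")
  if (!all(is.finite(object@intensity)))
    msg <- c(msg, "intensity must be finite (dB)")
  for (p in c("axialPitch", "azimuthalPitch", "framePitch"))
    if (length(slot(object, p)) != 1L || !is.finite(slot(object, p)) ||
        slot(object, p) <= 0)
      msg <- c(msg, paste(p, "must be a positive scalar (micrometres)"))
  nz <- dim(object@intensity)[3L]
  if (length(object@fiEnd) != 1L || is.na(object@fiEnd) ||
      object@fiEnd < 1L || object@fiEnd > nz)
    msg <- c(msg, "fiEnd must be a depth index within the volume")
  if (length(object@maStart) != 1L ||
      (!is.na(object@maStart) &&
       (object@maStart <= object@fiEnd || object@maStart > nz)))
    msg <- c(msg, "maStart must be NA or a depth index beyond fiEnd")
  if (length(msg)) msg else TRUE
})

#' Construct an OctVolume
#'
#' @param intensity 3-D dB array `[frame, azimuth, depth]`.
#' @param axialPitch,azimuthalPitch,framePitch pixel sizes in micrometres
#'   (defaults 10, the native resampled grid).
#' @param fiEnd last depth index of the fundamental image (default: the full
#'   depth extent).
#' @param maStart first depth index of the multipath band, `NA` if none.
#' @return an [OctVolume-class] object.
#' @export
OctVolume <- function(intensity, axialPitch = 10, azimuthalPitch = 10,
                      framePitch = 10, fiEnd = dim(intensity)[3L],
                      maStart = NA_integer_) {
  new("OctVolume", intensity = intensity, axialPitch = axialPitch,
      azimuthalPitch = azimuthalPitch, framePitch = framePitch,
      fiEnd = as.integer(fiEnd), maStart = as.integer(maStart))
}

#' AfiMap: en face autofluorescence map
#'
#' One fluorescence value per A-line, indexed `[frame, azimuth]`. Raw maps
#' hold non-negative detector units; calibrated maps hold uM fluorescein and
#' may contain negative values (intensity below the imaged background), which
#' are retained so that region medians stay unbiased. Pixels where
#' calibration was skipped (invalid depth, or depth beyond the calibration
#' range) are recorded in `uncalculated` and set to `NA`.
#'
#' @slot intensity numeric matrix `[frame, azimuth]`.
#' @slot units `"raw"` or `"uM"`.
#' @slot calibrated logical flag.
#' @slot uncalculated logical matrix marking skipped pixels.
#' @export
setClass("AfiMap",
  representation(
    intensity = "matrix",
    units = "character",
    calibrated = "logical",
    uncalculated = "matrix"
  )
)

setValidity("AfiMap", function(object) {
  msg <- character()
  if (!identical(dim(object@intensity), dim(object@uncalculated)))
    msg <- c(msg, "uncalculated mask must match intensity dimensions")
  if (!object@units %in% c("raw", "uM"))
    msg <- c(msg, "units must be 'raw' or 'uM'")
  if (!object@calibrated && any(object@intensity < 0, na.rm = TRUE))
    msg <- c(msg, "raw AFI values must be non-negative")
  ok <- !object@uncalculated
  if (any(!is.finite(object@intensity[ok])))
    msg <- c(msg, "AFI values must be finite where not masked")
  if (length(msg)) msg else TRUE
})

#' Construct an AfiMap
#'
#' @param intensity `[frame, azimuth]` matrix.
#' @param units `"raw"` (detector units) or `"uM"` (fluorescein).
#' @param calibrated logical.
#' @param uncalculated logical matrix of skipped pixels (default none).
#' @return an [AfiMap-class] object.
#' @export
AfiMap <- function(intensity, units = "raw", calibrated = units == "uM",
                   uncalculated = NULL) {
  if (is.null(uncalculated))
    uncalculated <- matrix(FALSE, nrow(intensity), ncol(intensity))
  new("AfiMap", intensity = intensity, units = units,
      calibrated = calibrated, uncalculated = uncalculated)
}

#' StandardVolume: calibration standard acquisition
#'
#' Joint OCT + AFI acquisition of a fluorescent calibration standard: the
#' bright standard is a test tube of 0.98 uM fluorescein, the dark standard a
#' water-filled tube covered in matte black foil. The OCT channel shows the
#' catheter sheath but negligible backscatter from the low-scattering fluid.
#'
#' @slot kind `"bright"` or `"dark"`.
#' @slot oct an [OctVolume-class].
#' @slot afi a raw [AfiMap-class].
#' @slot truthSheathZ integer matrix of true sheath-surface depth indices
#'   (filled by the phantom generator; empty for real acquisitions).
#' @export
setClass("StandardVolume",
  representation(kind = "character", oct = "OctVolume", afi = "AfiMap",
                 truthSheathZ = "matrix"),
  prototype(truthSheathZ = matrix(integer(0), 0L, 0L))
)

setValidity("StandardVolume", function(object) {
  if (!object@kind %in% c("bright", "dark"))
    return("kind must be 'bright' or 'dark'")
  TRUE
})

#' EnFaceMask: en face keep/remove/background segmentation
#'
#' Manual-style en face masks: `keep` marks tissue to retain, `remove` marks
#' artifacts to exclude (bubbles, sheath markers, birefringence bands), and
#' `background` marks the air region at the specimen exit used for the
#' background fluorescence value. `keep` and `remove` are disjoint.
#'
#' @slot keep,remove,background logical `[frame, azimuth]` matrices.
#' @export
setClass("EnFaceMask",
  representation(keep = "matrix", remove = "matrix", background = "matrix")
)

setValidity("EnFaceMask", function(object) {
  msg <- character()
  if (!identical(dim(object@keep), dim(object@remove)) ||
      !identical(dim(object@keep), dim(object@background)))
    msg <- c(msg, "keep/remove/background must share dimensions")
  if (any(object@keep & object@remove))
    msg <- c(msg, "keep and remove must be disjoint")
  if (length(msg)) msg else TRUE
})

#' Construct an EnFaceMask
#' @param keep,remove,background logical `[frame, azimuth]` matrices; missing
#'   ones default to all-FALSE (and `keep` to all-TRUE).
#' @return an [EnFaceMask-class] object.
#' @export
EnFaceMask <- function(keep, remove = NULL, background = NULL) {
  if (is.null(remove)) remove <- matrix(FALSE, nrow(keep), ncol(keep))
  if (is.null(background)) background <- matrix(FALSE, nrow(keep), ncol(keep))
  new("EnFaceMask", keep = keep, remove = remove, background = background)
}

#' DepthIntensityModel: fitted standard intensity vs depth
#'
#' Monotone non-increasing model of calibration-standard AFI intensity as a
#' function of the distance between the optical core and the sheath surface,
#' `I(d) = a*exp(-b*d) + c`, fitted by least squares.
#'
#' @slot kind `"bright"` or `"dark"`.
#' @slot params named numeric vector `(a, b, c)`; `b >= 0` so the curve never
#'   increases with depth.
#' @slot validRange depth range (micrometres) spanned by the fitted data.
#' @slot rmse residual root-mean-square error of the fit.
#' @export
setClass("DepthIntensityModel",
  representation(kind = "character", params = "numeric",
                 validRange = "numeric", rmse = "numeric")
)

setValidity("DepthIntensityModel", function(object) {
  msg <- character()
  if (!object@kind %in% c("bright", "dark"))
    msg <- c(msg, "kind must be 'bright' or 'dark'")
  if (!all(c("a", "b", "c") %in% names(object@params)))
    msg <- c(msg, "params must contain a, b, c")
  else if (object@params[["b"]] < 0)
    msg <- c(msg, "decay rate b must be non-negative (monotone model)")
  if (length(msg)) msg else TRUE
})

#' AttenuationVolume: depth-resolved attenuation estimates
#'
#' Per-voxel optical attenuation coefficient mu (mm^-1) over the tissue mask,
#' with per-column bookkeeping: `nLast` is the deepest retained depth index N
#' per A-line, `muTail` the tail estimate mu(N) obtained from a log-linear
#' fit, and `flagged` marks columns where the tail slope was non-physical and
#' mu(N) was floored.
#'
#' @slot mu numeric 3-D array, `NA` outside the evaluated tissue region.
#' @slot delta axial pixel pitch in millimetres.
#' @slot nLast integer matrix `[frame, azimuth]`, `NA` for skipped columns.
#' @slot muTail numeric matrix of mu(N) values.
#' @slot flagged logical matrix of columns with floored/capped values.
#' @export
setClass("AttenuationVolume",
  representation(mu = "array", delta = "numeric", nLast = "matrix",
                 muTail = "matrix", flagged = "matrix")
)

setValidity("AttenuationVolume", function(object) {
  msg <- character()
  if (length(dim(object@mu)) != 3L)
    msg <- c(msg, "mu must be a 3-D array")
  if (object@delta <= 0) msg <- c(msg, "delta must be positive (mm)")
  if (any(object@mu <= 0, na.rm = TRUE))
    msg <- c(msg, "mu must be positive where defined")
  if (length(msg)) msg else TRUE
})

#' PhantomConfig: synthetic OCT-AFI phantom description
#'
#' Full parametric description of a synthetic cylindrical OCT-AFI acquisition
#' with known ground truth. Defaults describe a small two-layer tube segment
#' imaged at the native 10 um grid (1792 A-lines per revolution on the real
#' system; tests and examples use far fewer). See [phantomConfig()].
#'
#' @slot nFrames,nAzimuth,nDepth volume extents.
#' @slot axialPitch,azimuthalPitch,framePitch pixel sizes, micrometres.
#' @slot zCore depth index of the PET core reflection.
#' @slot sheathRadius distance core -> window-tube outer surface, micrometres.
#' @slot surfaceProfile list: `base` radius (um), `azAmplitude`, `azCycles`,
#'   `frameAmplitude`, `framePhase` of the sinusoidal lumen radius.
#' @slot amplitude A-line model amplitude (linear a.u.).
#' @slot muSuperficial,muDeep layer attenuation coefficients, mm^-1.
#' @slot layerBoundaryDepth boundary depth below the surface, micrometres.
#' @slot concentration fluorophore concentration field value, uM.
#' @slot afiDecay list `(a, b, c)` of the AFI depth-decay model
#'   `a*exp(-b*d) + c` (b in 1/um).
#' @slot afiGain detector units per uM fluorescein at zero depth decay.
#' @slot afiBackground additive AFI background offset, detector units.
#' @slot afiNoiseSd multiplicative AFI noise sd (fraction of signal).
#' @slot speckleShape gamma speckle shape alpha (`Inf` = no speckle).
#' @slot noiseFloorDb additive OCT noise-floor level, dB (`-Inf` = none).
#' @slot noiseShape gamma shape of the additive noise-floor draws.
#' @slot lesionSpec list of lesions, each a list with `frames`, `azimuth`
#'   (index ranges), and optional `muSuperficial`, `muDeep`,
#'   `concentration` overrides.
#' @slot artifactSpec list with optional `multipath` (list `start`, `scale`),
#'   `birefringence` (list `depth`, `phase`), `bubbles` (list of
#'   `frame`, `azimuth`, `radius` in pixels).
#' @slot specimenFrames first and last frame containing tissue; frames beyond
#'   the distal end image air and serve as the AFI background region.
#' @slot seed integer RNG seed.
#' @export
setClass("PhantomConfig",
  representation(
    nFrames = "integer", nAzimuth = "integer", nDepth = "integer",
    axialPitch = "numeric", azimuthalPitch = "numeric", framePitch = "numeric",
    zCore = "integer", sheathRadius = "numeric", surfaceProfile = "list",
    amplitude = "numeric", muSuperficial = "numeric", muDeep = "numeric",
    layerBoundaryDepth = "numeric", concentration = "numeric",
    afiDecay = "list", afiGain = "numeric", afiBackground = "numeric",
    afiNoiseSd = "numeric", speckleShape = "numeric",
    noiseFloorDb = "numeric", noiseShape = "numeric",
    lesionSpec = "list", artifactSpec = "list",
    specimenFrames = "integer", seed = "integer"
  )
)

setValidity("PhantomConfig", function(object) {
  msg <- character()
  if (object@muSuperficial <= 0 || object@muDeep <= 0)
    msg <- c(msg, "attenuation coefficients must be positive")
  if (object@concentration < 0)
    msg <- c(msg, "concentration must be non-negative")
  if (object@layerBoundaryDepth <= 0 ||
      object@layerBoundaryDepth >= object@nDepth * object@axialPitch)
    msg <- c(msg, "layer boundary must lie within the depth range")
  if (object@zCore < 1L || object@zCore >= object@nDepth)
    msg <- c(msg, "zCore must be a valid depth index")
  for (les in object@lesionSpec) {
    if (any(les$frames < 1L) || any(les$frames > object@nFrames) ||
        any(les$azimuth < 1L) || any(les$azimuth > object@nAzimuth))
      msg <- c(msg, "lesion region outside volume bounds")
    mus <- c(les$muSuperficial, les$muDeep)
    if (length(mus) && any(mus <= 0))
      msg <- c(msg, "lesion attenuation overrides must be positive")
    if (!is.null(les$concentration) && les$concentration < 0)
      msg <- c(msg, "lesion concentration override must be non-negative")
  }
  if (length(object@specimenFrames) != 2L ||
      any(object@specimenFrames < 1L) ||
      any(object@specimenFrames > object@nFrames) ||
      diff(object@specimenFrames) < 0)
    msg <- c(msg, "specimenFrames must be an increasing pair within the volume")
  if (length(msg)) msg else TRUE
})

#' PhantomBundle: generated phantom with ground truth
#'
#' The output of [generatePhantom()]: the synthetic OCT volume and raw AFI
#' map, bright/dark calibration standards, en face artifact masks, and
#' ground-truth sidecars (true surface index, per-voxel attenuation field,
#' per-pixel fluorophore concentration, and pullback metadata).
#'
#' @slot config the generating [PhantomConfig-class].
#' @slot oct an [OctVolume-class].
#' @slot afi a raw [AfiMap-class].
#' @slot brightStandard,darkStandard [StandardVolume-class] objects.
#' @slot truthSurface integer matrix of true surface depth indices (`NA`
#'   where no tissue, i.e. beyond the specimen end).
#' @slot truthMu numeric 3-D array of true mu (mm^-1), `NA` outside tissue.
#' @slot truthConcentration numeric matrix of true uM per en face pixel.
#' @slot enfaceMask an [EnFaceMask-class]; `background` marks air frames.
#' @slot metadata list: `specimenFrames`, `pathology` (lengths in mm, per-2mm
#'   block diagnoses, fimbriae length), `lesionMask` logical matrix.
#' @export
setClass("PhantomBundle",
  representation(
    config = "PhantomConfig", oct = "OctVolume", afi = "AfiMap",
    brightStandard = "StandardVolume", darkStandard = "StandardVolume",
    truthSurface = "matrix", truthMu = "array",
    truthConcentration = "matrix", enfaceMask = "EnFaceMask",
    metadata = "list"
  )
)

setValidity("PhantomBundle", function(object) {
  msg <- character()
  nz <- dim(intensity(object@oct))[3L]
  s <- object@truthSurface
  if (any(s < 1 | s > nz, na.rm = TRUE))
    msg <- c(msg, "truth surface outside depth bounds")
  bg <- object@enfaceMask@background
  if (any(bg & !is.na(s)))
    msg <- c(msg, "background region must be disjoint from tissue contact")
  if (length(msg)) msg else TRUE
})
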