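#' @include AllClasses.R
NULL

#' Construct an en face depth map
#'
#' Distance from the optical core to the tissue (or sheath) surface per
#' A-line: `d = (surface_z - z_core) * axialPitch`, in micrometres. Pixels
#' with an invalid surface, or a surface at or above the core, are `NA`.
#'
#' @param surface integer surface map (`[frame, azimuth]`, `NA` invalid).
#' @param coreRef core reflection depth index from [detectCoreReflection()].
#' @param axialPitch depth pixel size, micrometres.
#' @return numeric depth map in micrometres (`NA` = invalid).
#' @export
buildDepthMap <- function(surface, coreRef, axialPitch) {
  stopifnot(axialPitch > 0, length(coreRef) == 1L)
  d <- (surface - coreRef) * axialPitch
  d[!is.na(d) & d < 0] <- NA_real_
  d
}

#' Fit a depth-intensity model to a calibration standard
#'
#' Least-squares fit of the monotone non-increasing model
#' `I(d) = a*exp(-b*d) + c` to per-pixel (depth, intensity) pairs from a
#' calibration standard, used to evaluate the bright/dark curves in the AFI
#' calibration formula. Requires at least `minPairs` valid pairs spanning at
#' least `minSpanUm` of depth. Degenerate (constant) data are accepted as a
#' flat curve with `b = 0`.
#'
#' @param stdAfi raw [AfiMap-class] of the standard.
#' @param stdDepth depth map of the standard (micrometres, from
#'   [buildDepthMap()] on the sheath surface).
#' @param kind `"bright"` or `"dark"`.
#' @param minPairs,minSpanUm data sufficiency requirements (50 pairs,
#'   200 um).
#' @return a [DepthIntensityModel-class].
#' @export
fitDepthModel <- function(stdAfi, stdDepth, kind = c("bright", "dark"),
                          minPairs = 50L, minSpanUm = 200) {
  kind <- match.arg(kind)
  I <- as.vector(intensity(stdAfi))
  d <- as.vector(stdDepth)
  ok <- is.finite(I) & is.finite(d)
  I <- I[ok]; d <- d[ok]
  if (length(I) < minPairs)
    stop("insufficient (depth, intensity) pairs for the ", kind, " standard")
  span <- diff(range(d))
  if (span < minSpanUm)
    stop(sprintf("depth span %.0f um < %.0f um: cannot fit the %s model",
                 span, minSpanUm, kind))

  iLo <- mean(I[d >= stats::quantile(d, 0.8)])
  iHi <- mean(I[d <= stats::quantile(d, 0.2)])
  if (stats::sd(I) < 1e-12 * max(abs(mean(I)), 1) || iHi <= iLo) {
    ## constant (or non-decaying) data: degenerate flat fit
    pars <- c(a = 0, b = 0, c = mean(I))
    rmse <- sqrt(mean((I - mean(I))^2))
  } else {
    b0 <- log(2) / max(span / 2, 1)
    start <- list(a = max(iHi - iLo, 1e-9), b = b0, c = max(iLo, 0))
    fit <- tryCatch(
      minpack.lm::nlsLM(
        I ~ a * exp(-b * d) + c, start = start,
        lower = c(a = 0, b = 0, c = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) {
      ## no resolvable decay (flat data up to noise): constant model
      pars <- c(a = 0, b = 0, c = mean(I))
      rmse <- sqrt(mean((I - mean(I))^2))
    } else {
      pars <- stats::coef(fit)[c("a", "b", "c")]
      rmse <- sqrt(mean(stats::resid(fit)^2))
    }
  }
  new("DepthIntensityModel", kind = kind,
      params = c(a = unname(pars[["a"]]), b = unname(pars[["b"]]),
                 c = unname(pars[["c"]])),
      validRange = range(d), rmse = rmse)
}

#' @describeIn fitDepthModel evaluate a fitted model at depths `d`
#'   (micrometres).
#' @param object a [DepthIntensityModel-class].
#' @param d depths in micrometres.
#' @export
setMethod("predict", "DepthIntensityModel", function(object, d) {
  p <- object@params
  p[["a"]] * exp(-p[["b"]] * d) + p[["c"]]
})

#' Calibration context
#'
#' @param cPos positive-standard fluorescein concentration, uM
#'   (default 0.98).
#' @param iBackground mean raw AFI over the manually selected air region.
#' @param maxDepth depths beyond this are not calibrated (default 700 um).
#' @return a list used by [calibrateAfi()].
#' @export
calibrationContext <- function(cPos = 0.98, iBackground, maxDepth = 700) {
  stopifnot(cPos > 0, maxDepth > 0, is.finite(iBackground))
  list(cPos = cPos, iBackground = iBackground, maxDepth = maxDepth)
}

#' Calibrate raw AFI to micromolar fluorescein
#'
#' Per-pixel calibration
#' `c(f, a) = cPos * (I_tissue(d) - mean(I_background)) /
#' (I_bright(d) - I_dark(d))`, where the bright and dark curves are
#' evaluated at that pixel's core-to-tissue depth. Pixels with an invalid
#' depth, or deeper than `ctx$maxDepth` (no calibration beyond 700 um from
#' the imaging core), go to the uncalculated mask. Negative values (tissue
#' dimmer than background) are retained, not clipped, so region medians
#' stay unbiased.
#'
#' @param afiRaw raw [AfiMap-class].
#' @param depth tissue depth map, micrometres.
#' @param bright,dark fitted [DepthIntensityModel-class] objects.
#' @param ctx context from [calibrationContext()].
#' @return calibrated [AfiMap-class] in uM fluorescein.
#' @export
calibrateAfi <- function(afiRaw, depth, bright, dark, ctx) {
  stopifnot(!isCalibrated(afiRaw))
  I <- intensity(afiRaw)
  if (!identical(dim(I), dim(depth)))
    stop("AFI map and depth map dimensions differ")
  skip <- !is.finite(depth) | depth > ctx$maxDepth
  d <- depth[!skip]
  if (length(d)) {
    denom <- predict(bright, d) - predict(dark, d)
    if (any(denom <= 0))
      stop("bright model does not exceed dark model at all used depths")
  }
  out <- matrix(NA_real_, nrow(I), ncol(I))
  out[!skip] <- ctx$cPos * (I[!skip] - ctx$iBackground) / denom
  AfiMap(out, units = "uM", calibrated = TRUE, uncalculated = skip)
}
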