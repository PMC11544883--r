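#' @include AllClasses.R segmentation.R
NULL

#' Depth-resolved attenuation coefficient of one A-line
#'
#' Depth-resolved estimator of the optical attenuation coefficient from the
#' tail sum of linear OCT intensity, with a boundary term for the signal
#' below the last retained pixel N:
#' the denominator is `2*delta*sum(I[z+1..N]) + I[N]/mu(N)`, where `mu(N)`
#' comes from a log-linear fit over the last `tailFitLen` pixels (slope
#' `-2*mu*delta` per pixel). By default the estimate is the exact discrete
#' inversion `mu(z) = log1p(2*delta*I(z)/denominator) / (2*delta)`, which is
#' free of the first-order discretization bias (about `mu*delta`, i.e. 3\%
#' at 3 mm^-1 and 10 um pitch) carried by the linearized form
#' `mu(z) = I(z)/denominator`; set `linearized = TRUE` for the latter.
#' The estimator is scale invariant: multiplying all intensities by a
#' constant leaves mu unchanged.
#'
#' @param columnIntensity linear intensity over the retained tissue pixels
#'   of one A-line (shallow to deep, all > 0).
#' @param delta axial pixel pitch, millimetres.
#' @param tailFitLen pixels in the tail fit (default 10); columns shorter
#'   than this are skipped by callers.
#' @param linearized use the linearized estimator (default FALSE).
#' @param groupedTail alternative denominator grouping
#'   `2*delta*(sum + I[N]/mu(N))` (default FALSE: the printed grouping is
#'   the dimensionally consistent one).
#' @param muFloor,muCap guard rails in mm^-1; out-of-range values are
#'   clipped and the column flagged.
#' @return list with `mu` (per-pixel, mm^-1), `muTail` (the mu(N) estimate)
#'   and `flagged` (TRUE when the tail slope was non-physical or values
#'   were clipped).
#' @examples
#' I <- 5 * exp(-2 * 3 * 0.01 * (0:99))
#' est <- depthResolvedMu(I, delta = 0.01)
#' range(est$mu[1:80])   # ~3 mm^-1
#' @export
depthResolvedMu <- function(columnIntensity, delta, tailFitLen = 10L,
                            linearized = FALSE, groupedTail = FALSE,
                            muFloor = 0.1, muCap = 50) {
  I <- columnIntensity
  n <- length(I)
  if (n < tailFitLen) stop("column shorter than the tail fit length")
  if (any(!is.finite(I)) || any(I <= 0))
    stop("linear intensities must be positive and finite")
  flagged <- FALSE
  tail <- (n - tailFitLen + 1L):n
  slope <- unname(stats::coef(stats::lm.fit(cbind(1, tail), log(I[tail])))[2L])
  muTail <- -slope / (2 * delta)
  if (!is.finite(muTail) || muTail <= 0) {
    muTail <- muFloor
    flagged <- TRUE
  }
  S <- rev(cumsum(rev(I))) - I            # sum over i = z+1 .. N
  denom <- if (groupedTail) 2 * delta * (S + I[n] / muTail)
           else 2 * delta * S + I[n] / muTail
  mu <- if (linearized) I / denom else log1p(2 * delta * I / denom) / (2 * delta)
  if (any(mu < muFloor | mu > muCap)) flagged <- TRUE
  mu <- pmin(pmax(mu, muFloor), muCap)
  list(mu = mu, muTail = muTail, flagged = flagged)
}

#' Depth-resolved attenuation over a tissue mask
#'
#' Applies [depthResolvedMu()] to every A-line of the volume over its
#' retained tissue pixels (taken on unsmoothed linear intensity). When a
#' noise-floor map is supplied, the per-A-line noise floor is subtracted
#' from the linear intensities first: the additive noise floor otherwise
#' flattens the apparent decay near the truncation depth and biases the
#' deep-band attenuation low. Retained pixels sit at least 6 dB (4x) above
#' the floor, so the subtraction never produces non-positive values.
#' Columns with fewer retained pixels than `tailFitLen` are skipped.
#'
#' @param vol an [OctVolume-class] (unsmoothed).
#' @param mask logical tissue mask from [truncateALines()].
#' @param noiseFloor optional `[frame, azimuth]` noise-floor matrix (dB)
#'   from [estimateNoiseFloor()].
#' @param tailFitLen,linearized,groupedTail,muFloor,muCap passed on to
#'   [depthResolvedMu()].
#' @return an [AttenuationVolume-class].
#' @export
attenuationVolume <- function(vol, mask, noiseFloor = NULL,
                              tailFitLen = 10L,
                              linearized = FALSE, groupedTail = FALSE,
                              muFloor = 0.1, muCap = 50) {
  d <- dim(vol@intensity)
  delta <- vol@axialPitch / 1000
  cols <- tissueColumns(mask)
  mu <- array(NA_real_, dim = d)
  muTail <- matrix(NA_real_, d[1L], d[2L])
  flagged <- matrix(FALSE, d[1L], d[2L])
  nLast <- cols$nLast
  nLast[cols$count < tailFitLen] <- NA_integer_
  for (f in seq_len(d[1L])) {
    for (a in which(!is.na(nLast[f, ]))) {
      zIdx <- which(mask[f, a, ])
      lin <- dbToLinear(vol@intensity[f, a, zIdx])
      if (!is.null(noiseFloor) && is.finite(noiseFloor[f, a]))
        lin <- pmax(lin - dbToLinear(noiseFloor[f, a]), 1e-12)
      est <- depthResolvedMu(lin,
                             delta = delta, tailFitLen = tailFitLen,
                             linearized = linearized,
                             groupedTail = groupedTail,
                             muFloor = muFloor, muCap = muCap)
      mu[f, a, zIdx] <- est$mu
      muTail[f, a] <- est$muTail
      flagged[f, a] <- est$flagged
    }
  }
  new("AttenuationVolume", mu = mu, delta = delta, nLast = nLast,
      muTail = muTail, flagged = flagged)
}

#' En face projection of the attenuation volume
#'
#' Mean projection of the per-voxel attenuation coefficient over a depth
#' band of each A-line's retained tissue: the whole column (`"overall"`),
#' the upper 50\% (`"superficial"`) or the lower 50\% (`"deep"`). The split
#' is per column: with `n` retained pixels the superficial band holds the
#' shallowest `floor(n/2)` and the deep band the remaining pixels. Columns
#' with fewer than 2 retained pixels are invalid.
#'
#' @param att an [AttenuationVolume-class].
#' @param mask the tissue mask the attenuation was computed on.
#' @param band `"overall"`, `"superficial"` or `"deep"`.
#' @return numeric en face map, mm^-1 (`NA` = invalid).
#' @export
projectMu <- function(att, mask, band = c("overall", "superficial", "deep")) {
  band <- match.arg(band)
  d <- dim(att@mu)
  out <- matrix(NA_real_, d[1L], d[2L])
  for (f in seq_len(d[1L])) {
    for (a in which(!is.na(att@nLast[f, ]))) {
      zIdx <- which(mask[f, a, ])
      n <- length(zIdx)
      if (n < 2L) next
      nSup <- floor(n / 2)
      keep <- switch(band,
        overall = zIdx,
        superficial = zIdx[seq_len(nSup)],
        deep = zIdx[(nSup + 1L):n])
      if (!length(keep)) next
      out[f, a] <- mean(att@mu[f, a, keep])
    }
  }
  out
}

#' Ratiometric stratification of superficial vs deep attenuation
#'
#' `s = (mu_superficial - mu_deep) / (mu_superficial + mu_deep)`, bounded in
#' `[-1, +1]`: -1 means all attenuation is in the deep band, +1 in the
#' superficial band, 0 a homogeneous column. Pixels where either band is
#' invalid, or the sum is not positive, are invalid.
#'
#' @param sup,deep en face maps from [projectMu()] (mm^-1, non-negative).
#' @return numeric en face stratification map in `[-1, 1]`.
#' @export
stratification <- function(sup, deep) {
  stopifnot(identical(dim(sup), dim(deep)))
  s <- (sup - deep) / (sup + deep)
  s[!is.finite(s) | (sup + deep) <= 0] <- NA_real_
  s
}
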