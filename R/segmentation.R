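#' @include AllClasses.R coords.R
NULL

#' Out-of-plane frame averaging
#'
#' Replaces every cross-section by the mean of up to `2*halfWidth + 1`
#' adjacent cross-sections (5 in each direction by default), truncated at
#' the volume ends. Averaging operates on the stored dB images, mirroring
#' pre-processing of cross-sections before surface segmentation.
#'
#' @param vol an [OctVolume-class].
#' @param halfWidth frames averaged on each side (default 5); 0 is identity.
#' @return the smoothed [OctVolume-class].
#' @export
smoothOutOfPlane <- function(vol, halfWidth = 5L) {
  stopifnot(halfWidth >= 0L)
  if (halfWidth == 0L) return(vol)
  arr <- vol@intensity
  d <- dim(arr)
  m <- matrix(arr, nrow = d[1L])
  cs <- rbind(0, apply(m, 2L, cumsum))
  f <- seq_len(d[1L])
  lo <- pmax(f - halfWidth, 1L)
  hi <- pmin(f + halfWidth, d[1L])
  out <- (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) /
    (hi - lo + 1L)
  vol@intensity <- array(out, dim = d)
  vol
}

## peak prominences of a numeric vector; returns data.frame(pos, height, prom)
peakProminences <- function(v) {
  n <- length(v)
  if (n < 3L) return(data.frame(pos = integer(), height = numeric(),
                                prom = numeric()))
  pk <- which(diff(sign(diff(v))) < 0) + 1L
  if (!length(pk)) return(data.frame(pos = integer(), height = numeric(),
                                     prom = numeric()))
  prom <- vapply(pk, function(p) {
    h <- v[p]
    leftMin <- h; i <- p
    while (i > 1L) { i <- i - 1L; if (v[i] > h) break; leftMin <- min(leftMin, v[i]) }
    if (i == 1L && v[i] <= h) leftMin <- min(leftMin, v[1L])
    rightMin <- h; i <- p
    while (i < n) { i <- i + 1L; if (v[i] > h) break; rightMin <- min(rightMin, v[i]) }
    if (i == n && v[i] <= h) rightMin <- min(rightMin, v[n])
    h - max(leftMin, rightMin)
  }, numeric(1))
  data.frame(pos = pk, height = v[pk], prom = prom)
}

#' Locate the optical-core (PET) reflection
#'
#' The reflection from the outer diameter of the PET tube on the optical
#' core is a fixed-depth reference: per frame, all A-lines are compressed
#' into an azimuthal sum projection, the two most prominent peaks are
#' identified, and the peak nearer the catheter (lower depth index) is
#' selected — this avoids picking the multipath copy of the same
#' reflection. The per-frame picks over the first `nFramesUse`
#' cross-sections are reduced to their mode to reject outliers.
#'
#' @param vol an [OctVolume-class].
#' @param nFramesUse number of leading frames to use (default 100).
#' @param surface optional surface map; values at and below the luminal
#'   surface are masked before projection (omit for standards, which
#'   contain no tissue).
#' @param prominenceDb peaks must rise this far above the projection median
#'   to count (default 6 dB).
#' @return single integer depth index of the core reflection.
#' @export
detectCoreReflection <- function(vol, nFramesUse = 100L, surface = NULL,
                                 prominenceDb = 6) {
  arr <- vol@intensity
  d <- dim(arr)
  nf <- min(nFramesUse, d[1L])
  floorDb <- min(arr)
  picks <- integer(0)
  for (f in seq_len(nf)) {
    xs <- arr[f, , , drop = TRUE]            # [azimuth, depth] dB
    if (!is.null(surface)) {
      s <- surface[f, ]
      for (a in which(!is.na(s))) xs[a, s[a]:d[3L]] <- floorDb
    }
    proj <- linearToDb(colSums(dbToLinear(xs)))
    pks <- peakProminences(proj)
    pks <- pks[pks$height >= stats::median(proj) + prominenceDb, , drop = FALSE]
    if (nrow(pks) < 2L) next
    top2 <- pks[order(-pks$prom)[1:2], ]
    picks <- c(picks, min(top2$pos))
  }
  if (!length(picks))
    stop("no core reflection: fewer than two prominent peaks in every frame")
  tab <- table(picks)
  as.integer(names(tab)[which.max(tab)])
}

#' Estimate the per-A-line noise floor
#'
#' If no multipath band is present at the end of the A-line, the noise floor
#' is computed from the final 25 pixels (250 um); otherwise from the 25
#' pixels immediately before the start of the multipath band. The window is
#' smoothed with a 5-pixel Gaussian kernel (sigma 1, half-sample symmetric
#' padding, which preserves the window mean exactly) and the noise floor is
#' the mean of the smoothed window, in dB.
#'
#' @param vol an [OctVolume-class] (its `maBounds` decide the window).
#' @param window window length in pixels (default 25).
#' @param smoothWidth,sigma Gaussian kernel length and width in pixels.
#' @param surface optional surface map; columns whose surface reaches into
#'   the window are flagged `NA`.
#' @return numeric `[frame, azimuth]` matrix of noise floors (dB), with
#'   attributes `window` (first/last depth index used) and `source`
#'   (`"end-of-A-line"` or `"pre-multipath"`).
#' @export
estimateNoiseFloor <- function(vol, window = 25L, smoothWidth = 5L,
                               sigma = 1, surface = NULL) {
  d <- dim(vol@intensity)
  maStart <- vol@maStart
  if (is.na(maStart)) {
    idx <- (d[3L] - window + 1L):d[3L]
    src <- "end-of-A-line"
  } else {
    idx <- (maStart - window):(maStart - 1L)
    src <- "pre-multipath"
  }
  if (idx[1L] < 1L) stop("noise window extends beyond the volume")
  m <- matrix(vol@intensity[, , idx], nrow = d[1L] * d[2L])
  sm <- t(apply(m, 1L, gaussSmooth1d, width = smoothWidth, sigma = sigma))
  nf <- matrix(rowMeans(sm), d[1L], d[2L])
  if (!is.null(surface)) nf[!is.na(surface) & surface >= idx[1L]] <- NA_real_
  structure(nf, window = c(idx[1L], idx[length(idx)]), source = src)
}

## first index where `above` holds for `runLen` consecutive entries, else NA
firstSustained <- function(above, runLen) {
  r <- rle(above)
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= runLen)
  if (!length(hit)) return(NA_integer_)
  ends[hit[1L]] - r$lengths[hit[1L]] + 1L
}

#' Segment the luminal surface
#'
#' Classical luminal-surface detector with the standard post-processing
#' chain. Values outside the fundamental-image region are ignored; per
#' A-line the surface candidate is the first sustained crossing of the
#' noise floor + `marginDb`, refined to the strongest intensity edge within
#' `refine` pixels. Post-processing enforces a single continuous line per
#' frame: azimuthal outliers (deviation from the wrapped running median
#' beyond `maxJump` pixels) are replaced, short invalid gaps are closed
#' morphologically and filled from neighbours, and each frame is combined
#' with `frameHalfWidth` adjacent frames the same way. Columns that never
#' cross the threshold stay invalid (`NA`) and are excluded from all
#' downstream biomarkers. The detector is deliberately biased toward
#' including mucous or air above the plicae rather than cutting into them.
#'
#' @param vol an [OctVolume-class].
#' @param marginDb detection threshold above the noise floor (default 6 dB).
#' @param sustained required consecutive above-threshold pixels (default 3).
#' @param searchFrom first depth index searched; default: core reflection
#'   + 250 um (past the sheath reflections).
#' @param coreRef optional precomputed core reflection index.
#' @param maxJump azimuthal continuity tolerance, pixels (default 3).
#' @param medianWidth,closeWidth running-median and morphological-closing
#'   window sizes along the azimuth.
#' @param frameHalfWidth adjacent frames combined on each side (default 2).
#' @param refine half-width of the gradient refinement window (default 5).
#' @return integer `[frame, azimuth]` surface map (`NA` = invalid) with
#'   attribute `lowQualityFrames` listing frames over 50\% invalid.
#' @export
segmentLumenSurface <- function(vol, marginDb = 6, sustained = 3L,
                                searchFrom = NULL, coreRef = NULL,
                                maxJump = 3L, medianWidth = 5L,
                                closeWidth = 5L, frameHalfWidth = 2L,
                                refine = 5L) {
  d <- dim(vol@intensity)
  nf <- estimateNoiseFloor(vol)
  if (is.null(searchFrom)) {
    if (is.null(coreRef))
      coreRef <- tryCatch(detectCoreReflection(vol), error = function(e) NULL)
    searchFrom <- if (is.null(coreRef)) 1L
      else coreRef + as.integer(round(250 / vol@axialPitch))
  }
  zTop <- vol@fiEnd
  if (searchFrom >= zTop) stop("search window is empty")

  surf <- matrix(NA_integer_, d[1L], d[2L])
  for (f in seq_len(d[1L])) {
    xs <- vol@intensity[f, , searchFrom:zTop, drop = TRUE]
    thr <- nf[f, ] + marginDb
    for (a in seq_len(d[2L])) {
      v <- xs[a, ]
      cand <- firstSustained(v >= thr[a], sustained)
      if (is.na(cand)) next
      lo <- max(cand - refine, 1L)
      hi <- min(cand + refine, length(v) - 1L)
      grad <- v[(lo + 1L):(hi + 1L)] - v[lo:hi]
      edge <- lo + which.max(grad)          # first pixel after the jump
      surf[f, a] <- searchFrom + edge - 1L
    }
  }

  ## azimuthal linking within each frame
  for (f in seq_len(d[1L])) {
    s <- surf[f, ]
    if (all(is.na(s))) next
    med <- circularMedian(s, medianWidth)
    out <- !is.na(s) & !is.na(med) & abs(s - med) > maxJump
    s[out] <- round(med[out])
    fill <- circularClose(!is.na(s), closeWidth) & is.na(s) & !is.na(med)
    s[fill] <- round(med[fill])
    surf[f, ] <- as.integer(s)
  }

  ## combination with adjacent frames
  if (frameHalfWidth > 0L && d[1L] > 1L) {
    ref <- surf
    for (f in seq_len(d[1L])) {
      fr <- max(1L, f - frameHalfWidth):min(d[1L], f + frameHalfWidth)
      med <- apply(ref[fr, , drop = FALSE], 2L, stats::median, na.rm = TRUE)
      s <- surf[f, ]
      out <- !is.na(s) & !is.na(med) & abs(s - med) > maxJump
      s[out] <- round(med[out])
      fill <- is.na(s) & !is.na(med) &
        colSums(!is.na(ref[fr, , drop = FALSE])) > length(fr) / 2
      s[fill] <- round(med[fill])
      surf[f, ] <- as.integer(s)
    }
  }
  surf[surf > zTop] <- zTop
  lowQ <- which(rowMeans(is.na(surf)) > 0.5)
  structure(surf, lowQualityFrames = lowQ)
}

#' Segment the outer sheath surface of a calibration standard
#'
#' Standards contain no tissue, so the depth reference is the outer surface
#' of the window-tube sheath: a binary mask is thresholded at `thresholdDb`
#' above the noise floor, pixels more than `cutoffUm` from the optical core
#' are zeroed (excluding the test-tube wall), and a continuous line is fit
#' to the deepest retained mask pixel per A-line with the same azimuthal
#' outlier replacement used for the lumen surface. The volume is smoothed
#' out-of-plane first so that single noise excursions cannot cross the
#' 3 dB threshold.
#'
#' @param std a [StandardVolume-class].
#' @param coreRef optional core reflection index; detected without tissue
#'   masking when omitted.
#' @param thresholdDb mask threshold above the noise floor (default 3 dB).
#' @param cutoffUm maximum distance from the core (default 750 um).
#' @param maxJump,medianWidth azimuthal linking parameters.
#' @param smoothHalfWidth out-of-plane averaging half-width (default 5).
#' @return integer `[frame, azimuth]` sheath surface map.
#' @export
segmentSheathSurface <- function(std, coreRef = NULL, thresholdDb = 3,
                                 cutoffUm = 750, maxJump = 3L,
                                 medianWidth = 5L, smoothHalfWidth = 5L) {
  raw <- oct(std)
  vol <- smoothOutOfPlane(raw, smoothHalfWidth)
  d <- dim(vol@intensity)
  nf <- estimateNoiseFloor(vol)
  if (is.null(coreRef)) coreRef <- detectCoreReflection(vol)
  zMax <- min(coreRef + floor(cutoffUm / vol@axialPitch), d[3L])
  zRange <- (coreRef + 2L):zMax
  surf <- matrix(NA_integer_, d[1L], d[2L])
  any_mask <- FALSE
  for (f in seq_len(d[1L])) {
    xs <- vol@intensity[f, , zRange, drop = TRUE]
    mask <- xs >= (nf[f, ] + thresholdDb)
    if (any(mask)) any_mask <- TRUE
    hit <- apply(mask, 1L, function(r) {
      w <- which(r); if (length(w)) max(w) else NA_integer_
    })
    cand <- as.integer(zRange[1L] - 1L + hit)
    ## snap back to this frame's own reflection peak, so the out-of-plane
    ## average cannot drag the line along a wobbling sheath
    for (a in which(!is.na(cand))) {
      zWin <- max(zRange[1L], cand[a] - 3L):min(zMax, cand[a] + 3L)
      v <- raw@intensity[f, a, zWin]
      if (any(v >= nf[f, a] + thresholdDb))
        cand[a] <- zWin[which.max(v)]
    }
    surf[f, ] <- cand
  }
  if (!any_mask) stop("empty threshold mask: no sheath surface found")
  for (f in seq_len(d[1L])) {
    s <- surf[f, ]
    med <- circularMedian(s, medianWidth)
    out <- !is.na(s) & !is.na(med) & abs(s - med) > maxJump
    s[out] <- round(med[out])
    fill <- is.na(s) & !is.na(med)
    s[fill] <- round(med[fill])
    surf[f, ] <- as.integer(s)
  }
  surf
}

#' Truncate A-lines to the visualized tissue region
#'
#' A voxel is retained iff it lies at or below the luminal surface, within
#' the fundamental image, and its intensity is at least `marginDb` above
#' that A-line's noise floor. The deepest retained index per column is the
#' last depth "sufficiently above the noise floor" used by the attenuation
#' estimator's tail term. Columns with an invalid surface or noise floor
#' are entirely excluded.
#'
#' @param vol an [OctVolume-class].
#' @param surface integer surface map from [segmentLumenSurface()].
#' @param nf noise-floor matrix from [estimateNoiseFloor()].
#' @param marginDb exclusion margin (default 6 dB).
#' @return logical `[frame, azimuth, depth]` tissue mask.
#' @export
truncateALines <- function(vol, surface, nf, marginDb = 6) {
  d <- dim(vol@intensity)
  mask <- array(FALSE, dim = d)
  zTop <- vol@fiEnd
  for (f in seq_len(d[1L])) {
    s <- surface[f, ]
    ok <- which(!is.na(s) & !is.na(nf[f, ]))
    for (a in ok) {
      z <- s[a]:zTop
      mask[f, a, z] <- vol@intensity[f, a, z] >= nf[f, a] + marginDb
    }
  }
  mask
}

## per-column bookkeeping of a tissue mask: count of retained pixels and
## deepest retained index N (NA where the column is empty)
tissueColumns <- function(mask) {
  d <- dim(mask)
  m <- matrix(mask, nrow = d[1L] * d[2L])
  count <- rowSums(m)
  nLast <- apply(m, 1L, function(r) {
    w <- which(r); if (length(w)) max(w) else NA_integer_
  })
  list(count = matrix(count, d[1L], d[2L]),
       nLast = matrix(as.integer(nLast), d[1L], d[2L]))
}
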