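#' @include AllClasses.R segmentation.R
NULL

## Gamma maximum-likelihood fit (shape/rate), method-of-moments start.
## Returns NULL for degenerate samples (the MLE diverges as variance -> 0).
## Note mean = shape/rate equals the sample mean exactly at the MLE.
gammaFitMle <- function(x) {
  if (length(x) < 3L || any(x <= 0)) return(NULL)
  xb <- mean(x)
  s <- log(xb) - mean(log(x))
  if (!is.finite(s) || s < 1e-10) return(NULL)
  a0 <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  f <- function(a) log(a) - digamma(a) - s
  lo <- a0 / 10; hi <- a0 * 10
  while (f(lo) < 0 && lo > 1e-8) lo <- lo / 10
  while (f(hi) > 0 && hi < 1e8) hi <- hi * 10
  alpha <- tryCatch(stats::uniroot(f, c(lo, hi), tol = 1e-9)$root,
                    error = function(e) NULL)
  if (is.null(alpha)) return(NULL)
  list(alpha = alpha, beta = alpha / xb, mean = xb)
}

#' Per-A-line gamma speckle statistics
#'
#' Fits a gamma distribution to the linear-intensity speckle of each A-line,
#' pooling the retained tissue pixels of the 5 adjacent A-lines in each
#' direction (an 11-A-line azimuthal window, wrapping at the seam) to give
#' the fit enough data. A-lines whose own tissue depth is below `minDepth`
#' pixels are excluded. The biomarker is the distribution mean
#' `alpha/beta` (shape over rate). Input must be the unsmoothed volume:
#' out-of-plane averaging would destroy the speckle statistics.
#'
#' @param vol an [OctVolume-class] (unsmoothed).
#' @param mask logical tissue mask.
#' @param halfWidth A-lines pooled on each side (default 5).
#' @param minDepth minimum tissue depth of the centre A-line (default 10).
#' @return list of `[frame, azimuth]` matrices: `mean` (alpha/beta),
#'   `alpha`, `beta`; `NA` where excluded or the fit degenerates.
#' @export
speckleMap <- function(vol, mask, halfWidth = 5L, minDepth = 10L) {
  d <- dim(vol@intensity)
  cols <- tissueColumns(mask)
  mMean <- mAlpha <- mBeta <- matrix(NA_real_, d[1L], d[2L])
  lin <- dbToLinear(vol@intensity)
  for (f in seq_len(d[1L])) {
    for (a in which(cols$count[f, ] >= minDepth)) {
      win <- wrapAzimuth((a - halfWidth):(a + halfWidth), d[2L])
      sl <- lin[f, win, , drop = TRUE]
      sel <- mask[f, win, , drop = TRUE]
      fit <- gammaFitMle(sl[sel])
      if (is.null(fit)) next
      mMean[f, a] <- fit$mean
      mAlpha[f, a] <- fit$alpha
      mBeta[f, a] <- fit$beta
    }
  }
  list(mean = mMean, alpha = mAlpha, beta = mBeta)
}

#' Volume-wide normalization quantiles
#'
#' Empirical 5th and 95th quantiles of the masked dB intensity over the
#' whole volume, used as the minimum and maximum for gray-level
#' normalization of every cross-section.
#'
#' @param vol an [OctVolume-class].
#' @param mask logical tissue mask.
#' @param probs the two probabilities (default 0.05, 0.95).
#' @param minVoxels required masked voxel count (default 100).
#' @return numeric `c(qLow, qHigh)`.
#' @export
volumeQuantiles <- function(vol, mask, probs = c(0.05, 0.95),
                            minVoxels = 100L) {
  v <- vol@intensity[mask]
  if (length(v) < minVoxels)
    stop("fewer than ", minVoxels, " masked voxels")
  q <- unname(stats::quantile(v, probs))
  if (q[1L] >= q[2L]) stop("degenerate dynamic range: quantiles coincide")
  q
}

#' Gray-level co-occurrence features of one cross-section
#'
#' Builds an asymmetric gray-level co-occurrence matrix over ordered pixel
#' pairs one azimuthal step apart (wrapping at the seam, matching the
#' cylindrical topology) and computes five Haralick features. Intensities
#' in dB are normalized to `[0, 1]` with the volume-wide 5th/95th quantiles
#' (values clipped), binned to `levels` gray levels (`floor(v*levels)`,
#' capped at the top level), and only pairs with both members inside the
#' tissue mask are counted.
#'
#' Features (p the joint probability, i the first and j the second level,
#' sigma the marginal standard deviations): contrast
#' `sum (i-j)^2 p(i,j)`; correlation
#' `sum (i - mean_i)(j - mean_j) p(i,j) / (sigma_i sigma_j)` (undefined when
#' a marginal is constant); energy `sum p^2`; homogeneity
#' `sum p / (1 + |i-j|)`; Shannon entropy `-sum p log2 p`. A constant
#' region gives contrast 0, energy 1, homogeneity 1, entropy 0 and
#' undefined correlation.
#'
#' @param xsec numeric `[azimuth, depth]` cross-section in dB (unsmoothed).
#' @param mask logical `[azimuth, depth]` tissue mask for this frame.
#' @param qLow,qHigh volume-wide normalization quantiles.
#' @param levels gray levels (default 32).
#' @param offset azimuthal pair offset in pixels (default 1).
#' @return list: `glcm` (levels x levels joint probability matrix, sums to
#'   1 when any pair exists), `contrast`, `correlation`, `energy`,
#'   `homogeneity`, `entropy`, `nPairs`.
#' @export
glcmFeatures <- function(xsec, mask, qLow, qHigh, levels = 32L,
                         offset = 1L) {
  stopifnot(identical(dim(xsec), dim(mask)), qHigh > qLow)
  nA <- nrow(xsec)
  v <- (xsec - qLow) / (qHigh - qLow)
  v <- pmin(pmax(v, 0), 1)
  bin <- pmin(floor(v * levels), levels - 1L) + 1L
  nxt <- wrapAzimuth(seq_len(nA) + offset, nA)
  ok <- mask & mask[nxt, , drop = FALSE]
  i <- bin[ok]
  j <- bin[nxt, , drop = FALSE][ok]
  nPairs <- length(i)
  empty <- list(glcm = matrix(0, levels, levels), contrast = NA_real_,
                correlation = NA_real_, energy = NA_real_,
                homogeneity = NA_real_, entropy = NA_real_, nPairs = 0L)
  if (!nPairs) return(empty)
  counts <- tabulate((i - 1L) * levels + j, nbins = levels * levels)
  P <- matrix(counts / nPairs, levels, levels, byrow = TRUE)
  lev <- seq_len(levels)
  pi_ <- rowSums(P); pj <- colSums(P)
  mi <- sum(lev * pi_); mj <- sum(lev * pj)
  si <- sqrt(sum((lev - mi)^2 * pi_)); sj <- sqrt(sum((lev - mj)^2 * pj))
  dij <- outer(lev, lev, "-")
  corr <- if (si * sj > 0)
    sum(outer(lev - mi, lev - mj) * P) / (si * sj) else NA_real_
  pv <- P[P > 0]
  list(glcm = P,
       contrast = sum(dij^2 * P),
       correlation = corr,
       energy = sum(P^2),
       homogeneity = sum(P / (1 + abs(dij))),
       entropy = -sum(pv * log2(pv)),
       nPairs = nPairs)
}

#' GLCM features for every cross-section of a volume
#'
#' Convenience wrapper: computes the volume-wide quantiles once, then
#' [glcmFeatures()] per frame.
#'
#' @inheritParams volumeQuantiles
#' @inheritParams glcmFeatures
#' @return data.frame with one row per frame: `frame`, `contrast`,
#'   `correlation`, `energy`, `homogeneity`, `entropy`, `nPairs`.
#' @export
glcmMap <- function(vol, mask, levels = 32L, offset = 1L) {
  q <- volumeQuantiles(vol, mask)
  d <- dim(vol@intensity)
  rows <- lapply(seq_len(d[1L]), function(f) {
    g <- glcmFeatures(vol@intensity[f, , , drop = TRUE],
                      mask[f, , , drop = TRUE], q[1L], q[2L],
                      levels = levels, offset = offset)
    data.frame(frame = f, contrast = g$contrast,
               correlation = g$correlation, energy = g$energy,
               homogeneity = g$homogeneity, entropy = g$entropy,
               nPairs = g$nPairs)
  })
  do.call(rbind, rows)
}
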