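#' @include AllClasses.R
NULL

#' Assign anatomical-region and diagnosis labels along the pullback
#'
#' Co-registers the imaged pullback against pathology metadata. If the
#' imaged specimen is longer than the pathology-reported length (and the
#' sample was fully imaged), all pathology lengths are scaled linearly to
#' the imaged extent; if the sample could not be fully imaged, pathology
#' lengths are used directly. The fimbriated region runs from the distal
#' end of the tissue over the (scaled) fimbriae length; the ampulla covers
#' 50\% of the (scaled) specimen length proximal to the fimbriae start; any
#' remaining tissue is isthmus. Each frame's diagnosis comes from its
#' containing pathology block (2 mm before scaling, matching the
#' histology sectioning interval); frames beyond the reported blocks are
#' `unknown`, frames outside the specimen `none`/`unknown`.
#'
#' Frames are positioned by their midpoints on a 1-based grid: frame `k`
#' of the specimen covers `[(k-1), k) * framePitch`.
#'
#' @param nFrames total frames in the volume.
#' @param framePitch frame spacing, micrometres.
#' @param pathology list: `specimenLengthMm`, `fimbriaeLengthMm`,
#'   optionally `blockDiagnoses` (character vector of `"lesion"` /
#'   `"no_lesion"` per 2 mm block, proximal first), `fullyImaged` flag.
#' @param specimenFrames first and last frame containing tissue.
#' @return data.frame with columns `frame`, `region`
#'   (isthmus/ampulla/fimbriae/none) and `diagnosis`
#'   (lesion/no_lesion/unknown); attribute `scale` records the applied
#'   length scaling.
#' @examples
#' lab <- assignLabels(60, 1000,
#'   list(specimenLengthMm = 60, fimbriaeLengthMm = 10, fullyImaged = TRUE),
#'   specimenFrames = c(1, 60))
#' table(lab$region)
#' @export
assignLabels <- function(nFrames, framePitch, pathology,
                         specimenFrames = c(1L, nFrames)) {
  stopifnot(framePitch > 0, pathology$specimenLengthMm > 0)
  fimLen <- pathology$fimbriaeLengthMm
  if (is.null(fimLen)) fimLen <- 0
  if (fimLen > pathology$specimenLengthMm)
    stop("fimbriae length exceeds the specimen length")
  fullyImaged <- isTRUE(pathology$fullyImaged)

  fpMm <- framePitch / 1000
  nSpec <- specimenFrames[2L] - specimenFrames[1L] + 1L
  imagedLen <- nSpec * fpMm
  scale <- if (fullyImaged && imagedLen > pathology$specimenLengthMm)
    imagedLen / pathology$specimenLengthMm else 1
  specLen <- pathology$specimenLengthMm * scale
  fimLen <- fimLen * scale

  region <- rep("none", nFrames)
  diagnosis <- rep("unknown", nFrames)
  specIdx <- specimenFrames[1L]:specimenFrames[2L]
  mid <- (seq_along(specIdx) - 0.5) * fpMm    # mm from proximal end

  fimStart <- imagedLen - fimLen
  ampStart <- fimStart - 0.5 * specLen
  reg <- ifelse(mid >= fimStart & fimLen > 0, "fimbriae",
         ifelse(mid >= ampStart, "ampulla", "isthmus"))
  region[specIdx] <- reg

  blocks <- pathology$blockDiagnoses
  if (!is.null(blocks) && length(blocks)) {
    blockLen <- 2 * scale
    b <- floor(mid / blockLen) + 1L
    known <- b >= 1L & b <= length(blocks)
    diagnosis[specIdx[known]] <- blocks[b[known]]
  }
  structure(
    data.frame(frame = seq_len(nFrames), region = region,
               diagnosis = diagnosis, stringsAsFactors = FALSE),
    scale = scale)
}

## 1-D area-overlap weight matrix from nIn cells of size `pitch` to cells
## of size `target` (micrometres); rows are output cells, rows sum to 1
resampleWeights <- function(nIn, pitch, target) {
  if (isTRUE(all.equal(pitch, target))) return(diag(nIn))
  nOut <- max(1L, round(nIn * pitch / target))
  W <- matrix(0, nOut, nIn)
  for (k in seq_len(nOut)) {
    lo <- (k - 1) * target; hi <- k * target
    i0 <- max(1L, floor(lo / pitch) + 1L)
    i1 <- min(nIn, ceiling(hi / pitch))
    for (i in i0:i1)
      W[k, i] <- max(0, min(hi, i * pitch) - max(lo, (i - 1) * pitch))
  }
  sweep(W, 1L, rowSums(W), "/")
}

#' Resample an en face map to 10 um-square pixels
#'
#' Area-weighted resampling of an en face map from its native frame and
#' azimuthal pitches onto the common 10 um-square comparison grid. Invalid
#' (`NA`) input pixels propagate: any output pixel overlapping an invalid
#' input pixel is invalid, never interpolated across.
#'
#' @param map numeric `[frame, azimuth]` matrix.
#' @param framePitch,azimuthalPitch native pixel sizes, micrometres.
#' @param target output pixel size (default 10 um).
#' @return resampled matrix.
#' @export
resampleEnFace <- function(map, framePitch, azimuthalPitch, target = 10) {
  Wf <- resampleWeights(nrow(map), framePitch, target)
  Wa <- resampleWeights(ncol(map), azimuthalPitch, target)
  bad <- is.na(map)
  m0 <- map
  m0[bad] <- 0
  out <- Wf %*% m0 %*% t(Wa)
  touched <- (Wf %*% (bad * 1) %*% t(Wa)) > 0
  out[touched] <- NA_real_
  out
}

#' Region-level median biomarkers
#'
#' Reduces en face biomarker maps to the medians used for statistical
#' analysis: per biomarker and scope, the median over pixels that are in
#' the keep mask, not in the remove mask, valid in the map, and members of
#' the scope (whole specimen, an anatomical region, or a diagnosis class).
#' Scope membership is per frame via the label table. Rows with zero
#' eligible pixels are omitted.
#'
#' @param maps named list of `[frame, azimuth]` biomarker maps on a common
#'   grid (per-frame features replicated across azimuth).
#' @param enfaceMask an [EnFaceMask-class] on the same grid.
#' @param labels label table from [assignLabels()] (needed for region and
#'   diagnosis scopes).
#' @param scopes subset of `c("whole", "region", "diagnosis")`.
#' @return data.frame: `biomarker`, `scope`, `level`, `median`, `nPixels`.
#' @export
summarizeBiomarkers <- function(maps, enfaceMask, labels = NULL,
                                scopes = c("whole", "region", "diagnosis")) {
  base <- enfaceMask@keep & !enfaceMask@remove
  rows <- list()
  addRow <- function(name, scope, level, sel) {
    v <- maps[[name]][sel]
    v <- v[!is.na(v)]
    if (!length(v)) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      biomarker = name, scope = scope, level = level,
      median = stats::median(v), nPixels = length(v),
      stringsAsFactors = FALSE)
  }
  frameSel <- function(frames) {
    sel <- matrix(FALSE, nrow(base), ncol(base))
    sel[frames, ] <- TRUE
    sel & base
  }
  for (name in names(maps)) {
    if ("whole" %in% scopes) addRow(name, "whole", "", base)
    if (!is.null(labels) && "region" %in% scopes)
      for (r in setdiff(unique(labels$region), "none"))
        addRow(name, "region", r, frameSel(labels$frame[labels$region == r]))
    if (!is.null(labels) && "diagnosis" %in% scopes)
      for (g in setdiff(unique(labels$diagnosis), "unknown"))
        addRow(name, "diagnosis", g,
               frameSel(labels$frame[labels$diagnosis == g]))
  }
  if (!length(rows))
    return(data.frame(biomarker = character(), scope = character(),
                      level = character(), median = numeric(),
                      nPixels = integer(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
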