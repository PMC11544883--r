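#' @include AllClasses.R
NULL

#' Read and write OCT volumes as multi-page TIFF
#'
#' Volumes are stored as one 16-bit TIFF page per frame (each page an
#' unwrapped azimuth x depth cross-section) plus a YAML sidecar carrying
#' the metadata a TIFF cannot: pixel pitches, fundamental-image /
#' multipath depth bounds, and the dB scaling used for quantization.
#' Writing quantizes the dB data onto a 16-bit grid between the volume
#' minimum and maximum (recorded in the sidecar); reading reconstructs dB
#' exactly from the grid, so a written volume round-trips bit-identically
#' after the initial quantization.
#'
#' @param vol an [OctVolume-class].
#' @param path file path; the sidecar lives at `<path>.yaml`.
#' @return `writeVolume()` returns `path` invisibly; `readVolume()` an
#'   [OctVolume-class].
#' @export
writeVolume <- function(vol, path) {
  arr <- vol@intensity
  lo <- min(arr); hi <- max(arr)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(arr)[1L]), function(f) {
    m <- (arr[f, , , drop = TRUE] - lo) / scale
    round(m * 65535) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  yaml::write_yaml(list(
    axialPitch = vol@axialPitch, azimuthalPitch = vol@azimuthalPitch,
    framePitch = vol@framePitch, fiEnd = vol@fiEnd,
    maStart = if (is.na(vol@maStart)) NULL else vol@maStart,
    dbMin = lo, dbScale = scale
  ), sidecarPath(path))
  invisible(path)
}

sidecarPath <- function(path) paste0(path, ".yaml")

#' @rdname writeVolume
#' @export
readVolume <- function(path) {
  sc <- sidecarPath(path)
  if (!file.exists(sc))
    stop("missing metadata sidecar: ", sc)
  meta <- yaml::read_yaml(sc)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L]))
    stop("malformed volume: TIFF pages have mixed dimensions")
  arr <- array(NA_real_, dim = c(length(pages), dims[1L, 1L], dims[2L, 1L]))
  for (f in seq_along(pages))
    arr[f, , ] <- round(pages[[f]] * 65535) / 65535 * meta$dbScale + meta$dbMin
  OctVolume(arr, axialPitch = meta$axialPitch,
            azimuthalPitch = meta$azimuthalPitch,
            framePitch = meta$framePitch, fiEnd = meta$fiEnd,
            maStart = if (is.null(meta$maStart)) NA_integer_
                      else as.integer(meta$maStart))
}

#' Read and write en face maps
#'
#' En face maps (AFI, depth, biomarker and truth maps) are written twice:
#' a CSV holding the exact values (the authoritative copy read back by
#' `readEnFace()`) and a normalized single-page TIFF for quick viewing.
#'
#' @param map numeric `[frame, azimuth]` matrix (`NA` allowed).
#' @param path CSV path; the TIFF companion is `<path>.tif`.
#' @return `writeEnFace()` the path invisibly; `readEnFace()` the matrix.
#' @export
writeEnFace <- function(map, path) {
  utils::write.table(map, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  rng <- range(map, na.rm = TRUE, finite = TRUE)
  if (!all(is.finite(rng))) rng <- c(0, 1)
  scale <- if (rng[2L] > rng[1L]) rng[2L] - rng[1L] else 1
  img <- (map - rng[1L]) / scale
  img[!is.finite(img)] <- 0
  tiff::writeTIFF(img, paste0(path, ".tif"), bits.per.sample = 16L)
  invisible(path)
}

#' @rdname writeEnFace
#' @export
readEnFace <- function(path) {
  as.matrix(utils::read.table(path, sep = ",", header = FALSE))
}
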