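#' @include AllClasses.R segmentation.R calibration.R attenuation.R texture.R coregistration.R
NULL

#' Compute all eleven en face biomarker maps for one volume
#'
#' Runs segmentation, calibration and the biomarker stages on one OCT-AFI
#' acquisition: core detection, out-of-plane-smoothed surface segmentation,
#' per-A-line noise floor and 6 dB truncation, sheath segmentation and
#' depth-model fits on the standards, AFI calibration to uM fluorescein,
#' depth-resolved attenuation with overall/superficial/deep projections and
#' stratification, the gamma speckle mean, and the five per-cross-section
#' co-occurrence features (replicated across the azimuth so every biomarker
#' lives on the common en face grid). Speckle and texture consume the
#' unsmoothed volume; surface detection the smoothed one.
#'
#' @param vol an [OctVolume-class].
#' @param afiRaw the raw [AfiMap-class] for the same pullback.
#' @param bright,dark [StandardVolume-class] calibration standards (omit
#'   both to skip AFI calibration).
#' @param enfaceMask an [EnFaceMask-class] (`background` drives the
#'   background fluorescence value).
#' @param smoothHalfWidth out-of-plane smoothing for surface detection.
#' @param marginDb truncation margin (default 6 dB).
#' @param cPos positive-standard concentration, uM (default 0.98).
#' @param maxDepth AFI calibration depth cutoff, micrometres (default 700).
#' @param glcmLevels gray levels for the co-occurrence features.
#' @return list: `maps` (named list of 11 en face matrices), `surface`,
#'   `mask`, `depth`, `core`, `noiseFloor`, `attenuation`, `glcmTable`,
#'   `calibration` (fitted models and context, or NULL).
#' @export
computeBiomarkerMaps <- function(vol, afiRaw, bright = NULL, dark = NULL,
                                 enfaceMask = NULL, smoothHalfWidth = 5L,
                                 marginDb = 6, cPos = 0.98, maxDepth = 700,
                                 glcmLevels = 32L) {
  d <- dim(vol@intensity)
  if (is.null(enfaceMask))
    enfaceMask <- EnFaceMask(keep = matrix(TRUE, d[1L], d[2L]))
  core <- detectCoreReflection(vol)
  smoothed <- smoothOutOfPlane(vol, smoothHalfWidth)
  surface <- segmentLumenSurface(smoothed, marginDb = marginDb,
                                 coreRef = core)
  surface[enfaceMask@background] <- NA_integer_
  nf <- estimateNoiseFloor(vol)
  mask <- truncateALines(vol, surface, nf, marginDb = marginDb)
  depth <- buildDepthMap(surface, core, vol@axialPitch)

  calibration <- NULL
  afiCal <- NULL
  if (!is.null(bright) && !is.null(dark)) {
    fitStd <- function(std, kind) {
      sCore <- detectCoreReflection(oct(std))
      sSurf <- segmentSheathSurface(std, coreRef = sCore)
      sDepth <- buildDepthMap(sSurf, sCore, oct(std)@axialPitch)
      fitDepthModel(afi(std), sDepth, kind)
    }
    bm <- fitStd(bright, "bright")
    dm <- fitStd(dark, "dark")
    iBg <- mean(intensity(afiRaw)[enfaceMask@background])
    if (!is.finite(iBg))
      stop("no background region available for AFI calibration")
    ctx <- calibrationContext(cPos = cPos, iBackground = iBg,
                              maxDepth = maxDepth)
    afiCal <- calibrateAfi(afiRaw, depth, bm, dm, ctx)
    calibration <- list(bright = bm, dark = dm, ctx = ctx)
  }

  att <- attenuationVolume(vol, mask, noiseFloor = nf)
  sup <- projectMu(att, mask, "superficial")
  deep <- projectMu(att, mask, "deep")
  spk <- speckleMap(vol, mask)
  glcmTab <- glcmMap(vol, mask, levels = glcmLevels)

  perFrame <- function(v) matrix(rep(v, d[2L]), d[1L], d[2L])
  maps <- list(
    autofluorescence = if (is.null(afiCal)) intensity(afiRaw)
                       else intensity(afiCal),
    muOverall = projectMu(att, mask, "overall"),
    muSuperficial = sup,
    muDeep = deep,
    stratification = stratification(sup, deep),
    speckleMean = spk$mean,
    glcmContrast = perFrame(glcmTab$contrast),
    glcmCorrelation = perFrame(glcmTab$correlation),
    glcmEnergy = perFrame(glcmTab$energy),
    glcmHomogeneity = perFrame(glcmTab$homogeneity),
    glcmEntropy = perFrame(glcmTab$entropy)
  )
  list(maps = maps, surface = surface, mask = mask, depth = depth,
       core = core, noiseFloor = nf, attenuation = att,
       glcmTable = glcmTab, calibration = calibration)
}

#' Run the phantom-to-statistics pipeline
#'
#' End-to-end orchestration on a synthetic acquisition: generates the
#' phantom bundle (volume, AFI, standards, masks, truth), computes the
#' eleven biomarker maps, resamples them to the 10 um-square comparison
#' grid, assigns region and diagnosis labels from the bundled pathology
#' metadata, and extracts median biomarkers per scope. Deterministic given
#' `config@seed`. When `outDir` is given, the biomarker table, the
#' per-frame texture table, every en face map, the surface map and the
#' generating configuration are written there; a failure in any stage
#' leaves the outputs of completed stages in place.
#'
#' @param config a [PhantomConfig-class].
#' @param outDir optional output directory (created if needed).
#' @param calibrate fit standards and calibrate AFI (default TRUE).
#' @return list: `bundle`, everything from [computeBiomarkerMaps()],
#'   `labels`, `table` (the median biomarker table).
#' @examples
#' \donttest{
#' run <- runPipeline(phantomConfig(nFrames = 20, nAzimuth = 64,
#'                                  nDepth = 140, seed = 11))
#' head(run$table)
#' }
#' @export
runPipeline <- function(config, outDir = NULL, calibrate = TRUE) {
  bundle <- generatePhantom(config)
  res <- computeBiomarkerMaps(
    oct(bundle), afi(bundle),
    bright = if (calibrate) bundle@brightStandard,
    dark = if (calibrate) bundle@darkStandard,
    enfaceMask = bundle@enfaceMask)

  meta <- bundle@metadata
  labels <- assignLabels(config@nFrames, config@framePitch,
                         c(meta$pathology,
                           list(blockDiagnoses = blockDiagnosesFromLesions(
                             meta, config))),
                         specimenFrames = meta$specimenFrames)

  maps10 <- lapply(res$maps, resampleEnFace,
                   framePitch = config@framePitch,
                   azimuthalPitch = config@azimuthalPitch)
  frac <- function(m) resampleEnFace(m * 1, config@framePitch,
                                     config@azimuthalPitch)
  rm10 <- frac(bundle@enfaceMask@remove) > 0
  mask10 <- EnFaceMask(keep = frac(bundle@enfaceMask@keep) >= 0.5 & !rm10,
                       remove = rm10,
                       background = frac(bundle@enfaceMask@background) >= 0.5)
  labels10 <- resampleLabels(labels, config@framePitch, nrow(maps10[[1L]]))

  tab <- summarizeBiomarkers(maps10, mask10, labels10)

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(tab, file.path(outDir, "biomarkers.csv"),
                     row.names = FALSE)
    utils::write.csv(res$glcmTable, file.path(outDir, "glcm_features.csv"),
                     row.names = FALSE)
    for (name in names(res$maps))
      writeEnFace(res$maps[[name]],
                  file.path(outDir, paste0("map_", name, ".csv")))
    writeEnFace(res$surface, file.path(outDir, "surface.csv"))
    yaml::write_yaml(list(seed = config@seed,
                          nFrames = config@nFrames,
                          nAzimuth = config@nAzimuth,
                          nDepth = config@nDepth),
                     file.path(outDir, "run_config.yaml"))
  }
  c(list(bundle = bundle), res,
    list(labels = labels, table = tab))
}

## derive per-2mm-block diagnoses from the phantom's lesion frames
blockDiagnosesFromLesions <- function(meta, config) {
  fpMm <- config@framePitch / 1000
  specLen <- meta$pathology$specimenLengthMm
  nBlocks <- max(1L, ceiling(specLen / 2))
  blocks <- rep("no_lesion", nBlocks)
  for (f in meta$lesionFrames) {
    pos <- (f - meta$specimenFrames[1L] + 0.5) * fpMm
    b <- floor(pos / 2) + 1L
    if (b >= 1L && b <= nBlocks) blocks[b] <- "lesion"
  }
  blocks
}

## carry frame labels onto the resampled (10 um) frame grid
resampleLabels <- function(labels, framePitch, nOut) {
  nIn <- nrow(labels)
  src <- pmin(pmax(ceiling((seq_len(nOut) - 0.5) * nIn / nOut), 1L), nIn)
  data.frame(frame = seq_len(nOut),
             region = labels$region[src],
             diagnosis = labels$diagnosis[src],
             stringsAsFactors = FALSE)
}
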