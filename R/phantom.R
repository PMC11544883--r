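#' @include AllClasses.R
NULL

#' Build a synthetic OCT-AFI phantom configuration
#'
#' Describes a cylindrical two-layer tissue phantom imaged by a rotating
#' catheter: a sinusoidally varying lumen radius, a superficial layer of
#' lower attenuation over a deeper layer of higher attenuation (emulating
#' endosalpinx over myosalpinx), a fluorophore concentration field read out
#' en face through a monotone depth-decay model, unit-mean gamma speckle,
#' an additive noise floor, and the catheter artifact catalogue (core and
#' sheath reflections, an axially smeared multipath ghost band at the end of
#' the A-line, four azimuthal birefringence suppression bands, bubbles and a
#' sheath marker). Frames beyond the distal specimen end image air and
#' provide the AFI background region.
#'
#' The OCT image-formation model is single scattering:
#' `E[I(z)] = amplitude * mu(z) * exp(-2 * sum_{s<=z} mu(s) * delta)` on
#' linear intensity, multiplied by unit-mean gamma speckle and with an
#' additive noise floor — the model under which the depth-resolved
#' attenuation estimator's target quantity is exactly defined.
#'
#' @param nFrames,nAzimuth,nDepth volume extents (defaults 60, 1792, 160;
#'   1792 A-lines per revolution is the native acquisition density — tests
#'   and examples use far fewer azimuthal samples).
#' @param axialPitch,azimuthalPitch,framePitch pixel sizes, micrometres
#'   (default 10: pixels at the window tube are 10 um square).
#' @param zCore depth index of the PET core reflection.
#' @param sheathRadius core-to-sheath distance, micrometres.
#' @param surfaceProfile list with `base`, `azAmplitude`, `azCycles`,
#'   `frameAmplitude` (micrometres / cycles) of the lumen radius.
#' @param amplitude A-line model amplitude, linear a.u.
#' @param muSuperficial,muDeep layer attenuation coefficients, mm^-1.
#' @param layerBoundaryDepth layer boundary below the surface, micrometres.
#' @param concentration fluorophore concentration, uM fluorescein.
#' @param afiDecay list `(a, b, c)`: AFI depth decay `a*exp(-b*d)+c`, b in
#'   1/um. The calibration fitter shares only the monotone-decay property
#'   with this model, not its parameters.
#' @param afiGain detector units per uM at unit decay.
#' @param afiBackground AFI background offset, detector units.
#' @param afiNoiseSd relative AFI noise (sd as a fraction of signal).
#' @param speckleShape gamma speckle shape alpha; `Inf` disables speckle.
#' @param noiseFloorDb OCT noise floor, dB; `-Inf` disables it.
#' @param noiseShape gamma shape of noise-floor draws.
#' @param lesionSpec list of lesions (`frames`, `azimuth` index ranges plus
#'   optional `muSuperficial`, `muDeep`, `concentration` overrides).
#' @param artifactSpec artifact catalogue; `list()` disables all artifacts.
#'   Defaults include the multipath ghost, birefringence bands, two bubbles
#'   and one sheath marker.
#' @param specimenFrames first/last tissue frame (default: air occupies the
#'   final 10\% of frames, minimum 3).
#' @param seed RNG seed.
#' @return a validated [PhantomConfig-class].
#' @examples
#' cfg <- phantomConfig(nFrames = 6, nAzimuth = 48, nDepth = 100, seed = 7)
#' cfg
#' @export
phantomConfig <- function(nFrames = 60L, nAzimuth = 1792L, nDepth = 160L,
                          axialPitch = 10, azimuthalPitch = 10,
                          framePitch = 10, zCore = 10L, sheathRadius = 200,
                          surfaceProfile = list(base = 350, azAmplitude = 30,
                                                azCycles = 2,
                                                frameAmplitude = 30),
                          amplitude = 2e4, muSuperficial = 2, muDeep = 4,
                          layerBoundaryDepth = 150, concentration = 1,
                          afiDecay = list(a = 1, b = 0.0025, c = 0.1),
                          afiGain = 1000, afiBackground = 50,
                          afiNoiseSd = 0.02, speckleShape = 4,
                          noiseFloorDb = 25, noiseShape = 4,
                          lesionSpec = list(), artifactSpec = NULL,
                          specimenFrames = NULL, seed = 1L) {
  if (is.null(artifactSpec))
    artifactSpec <- list(
      multipath = list(scale = 0.03, smear = 3),
      birefringence = list(depth = 0.5, phase = 0.3),
      bubbles = list(
        list(frame = max(1L, round(0.3 * nFrames)),
             azimuth = max(1L, round(0.25 * nAzimuth)), radius = 2L),
        list(frame = max(1L, round(0.6 * nFrames)),
             azimuth = max(1L, round(0.7 * nAzimuth)), radius = 3L)),
      markers = max(1L, round(0.5 * nFrames))
    )
  if (is.null(specimenFrames)) {
    nAir <- max(3L, round(0.1 * nFrames))
    specimenFrames <- c(1L, max(1L, nFrames - nAir))
  }
  new("PhantomConfig",
      nFrames = as.integer(nFrames), nAzimuth = as.integer(nAzimuth),
      nDepth = as.integer(nDepth), axialPitch = axialPitch,
      azimuthalPitch = azimuthalPitch, framePitch = framePitch,
      zCore = as.integer(zCore), sheathRadius = sheathRadius,
      surfaceProfile = surfaceProfile, amplitude = amplitude,
      muSuperficial = muSuperficial, muDeep = muDeep,
      layerBoundaryDepth = layerBoundaryDepth, concentration = concentration,
      afiDecay = afiDecay, afiGain = afiGain, afiBackground = afiBackground,
      afiNoiseSd = afiNoiseSd, speckleShape = speckleShape,
      noiseFloorDb = noiseFloorDb, noiseShape = noiseShape,
      lesionSpec = lesionSpec, artifactSpec = artifactSpec,
      specimenFrames = as.integer(specimenFrames), seed = as.integer(seed))
}

#' Simulate a single OCT A-line over tissue
#'
#' Single-scattering A-line model on linear intensity:
#' `E[I(z)] = amplitude * mu(z) * exp(-2 * cumsum(mu * delta))`, multiplied
#' by unit-mean gamma speckle (shape `speckleShape`) and with additive
#' gamma-distributed noise of mean `noiseFloor`. Draws come from the current
#' RNG stream; seed the stream with [set.seed()] for reproducibility.
#'
#' @param muProfile per-pixel attenuation coefficients, mm^-1 (all > 0).
#' @param delta axial pixel pitch, millimetres.
#' @param amplitude model amplitude, linear a.u.
#' @param speckleShape gamma shape alpha; `Inf` = no speckle.
#' @param noiseFloor additive noise mean, linear a.u.; 0 = none.
#' @param noiseShape gamma shape of the noise draws.
#' @return linear-intensity vector of `length(muProfile)`.
#' @examples
#' I <- generateALine(rep(3, 50), delta = 0.01)
#' all.equal(I[2] / I[1], exp(-0.06))
#' @export
generateALine <- function(muProfile, delta, amplitude = 1,
                          speckleShape = Inf, noiseFloor = 0,
                          noiseShape = 4) {
  if (any(!is.finite(muProfile)) || any(muProfile <= 0))
    stop("all attenuation coefficients must be positive and finite")
  stopifnot(delta > 0, amplitude > 0, noiseFloor >= 0)
  n <- length(muProfile)
  I <- amplitude * muProfile * exp(-2 * cumsum(muProfile) * delta)
  if (is.finite(speckleShape))
    I <- I * stats::rgamma(n, shape = speckleShape, rate = speckleShape)
  if (noiseFloor > 0)
    I <- I + stats::rgamma(n, shape = noiseShape,
                           rate = noiseShape / noiseFloor)
  I
}

## evaluate the configured AFI depth-decay model
afiDecayModel <- function(cfg, d) {
  p <- cfg@afiDecay
  p$a * exp(-p$b * d) + p$c
}

## true lumen surface depth index per (frame, azimuth); NA beyond specimen
truthSurfaceZ <- function(cfg) {
  sp <- cfg@surfaceProfile
  f <- seq_len(cfg@nFrames)
  a <- seq_len(cfg@nAzimuth)
  radius <- outer(
    sp$frameAmplitude * sin(2 * pi * f / max(cfg@nFrames, 2L)),
    sp$azAmplitude * sin(2 * pi * sp$azCycles * a / cfg@nAzimuth), "+") +
    sp$base
  z <- cfg@zCore + round(radius / cfg@axialPitch)
  air <- f < cfg@specimenFrames[1L] | f > cfg@specimenFrames[2L]
  z[air, ] <- NA_integer_
  storage.mode(z) <- "integer"
  z
}

## per-column layer attenuation (with lesion overrides); matrices [F, A]
layerMuFields <- function(cfg) {
  muS <- matrix(cfg@muSuperficial, cfg@nFrames, cfg@nAzimuth)
  muD <- matrix(cfg@muDeep, cfg@nFrames, cfg@nAzimuth)
  conc <- matrix(cfg@concentration, cfg@nFrames, cfg@nAzimuth)
  lesion <- matrix(FALSE, cfg@nFrames, cfg@nAzimuth)
  for (les in cfg@lesionSpec) {
    fr <- les$frames
    az <- les$azimuth
    if (!is.null(les$muSuperficial)) muS[fr, az] <- les$muSuperficial
    if (!is.null(les$muDeep)) muD[fr, az] <- les$muDeep
    if (!is.null(les$concentration)) conc[fr, az] <- les$concentration
    lesion[fr, az] <- TRUE
  }
  list(muS = muS, muD = muD, conc = conc, lesion = lesion)
}

## depth bookkeeping for a config: end of fundamental image, multipath start
phantomDepthBounds <- function(cfg) {
  Z <- cfg@nDepth
  if (!is.null(cfg@artifactSpec$multipath)) {
    maStart <- Z - 9L
    fiEnd <- maStart - 28L   # keeps the 25-px pre-multipath window tissue-free
  } else {
    maStart <- NA_integer_
    fiEnd <- Z - 28L
  }
  list(fiEnd = as.integer(fiEnd), maStart = as.integer(maStart))
}

## run expr with the RNG seeded, restoring the caller's stream afterwards
withPhantomSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic OCT-AFI phantom bundle
#'
#' Renders the acquisition described by a [PhantomConfig-class]: OCT volume
#' (dB), raw en face AFI, bright and dark calibration standards, en face
#' keep/remove/background masks, and ground-truth sidecars (surface index,
#' per-voxel attenuation, per-pixel concentration, pullback pathology
#' metadata). Deterministic given `config@seed`; the caller's RNG state is
#' left untouched.
#'
#' @param config a [PhantomConfig-class].
#' @return a [PhantomBundle-class].
#' @examples
#' ph <- generatePhantom(phantomConfig(nFrames = 8, nAzimuth = 48,
#'                                     nDepth = 120, seed = 3))
#' ph
#' @export
generatePhantom <- function(config) {
  validObject(config)
  bright <- generateStandard("bright", config)
  dark <- generateStandard("dark", config)
  withPhantomSeed(config@seed + 103L, {
    F <- config@nFrames; A <- config@nAzimuth; Z <- config@nDepth
    FA <- F * A
    delta <- config@axialPitch / 1000   # mm
    bounds <- phantomDepthBounds(config)
    surf <- truthSurfaceZ(config)
    fields <- layerMuFields(config)

    surfV <- as.vector(surf)
    boundaryPx <- config@layerBoundaryDepth / config@axialPitch

    ## per-voxel truth mu as an (FA x Z) matrix
    muMat <- matrix(NA_real_, FA, Z)
    muSV <- as.vector(fields$muS); muDV <- as.vector(fields$muD)
    for (z in seq_len(bounds$fiEnd)) {
      below <- z - surfV              # pixels below surface (0 at surface)
      tis <- !is.na(below) & below >= 0L
      muMat[tis, z] <- ifelse(below[tis] < boundaryPx, muSV[tis], muDV[tis])
    }

    ## single-scattering signal with cumulative optical depth
    sig <- matrix(0, FA, Z)
    acc <- numeric(FA)
    for (z in seq_len(Z)) {
      mu <- muMat[, z]
      tis <- !is.na(mu)
      if (any(tis)) {
        acc[tis] <- acc[tis] + mu[tis] * delta
        sig[tis, z] <- config@amplitude * mu[tis] * exp(-2 * acc[tis])
      }
    }
    if (is.finite(config@speckleShape)) {
      tis <- !is.na(muMat)
      sig[tis] <- sig[tis] * stats::rgamma(sum(tis),
                                           shape = config@speckleShape,
                                           rate = config@speckleShape)
    }

    ## birefringence: four azimuthal suppression bands on the tissue signal
    bir <- config@artifactSpec$birefringence
    if (!is.null(bir)) {
      th <- 2 * pi * seq_len(A) / A
      supp <- 1 - bir$depth * sin(2 * th - bir$phase)^2
      sig <- sig * rep(rep(supp, each = F), Z)
    }

    ## bubbles and sheath markers obscure the signal
    removeMask <- matrix(FALSE, F, A)
    for (b in config@artifactSpec$bubbles) {
      fr <- intersect(seq(b$frame - b$radius, b$frame + b$radius), seq_len(F))
      az <- wrapAzimuth(seq(b$azimuth - b$radius, b$azimuth + b$radius), A)
      removeMask[fr, az] <- TRUE
    }
    for (m in config@artifactSpec$markers)
      removeMask[max(1L, m - 1L):min(F, m + 1L), ] <- TRUE
    obscured <- as.vector(removeMask)
    sig[obscured, ] <- sig[obscured, ] * 0.05

    ## catheter reflections (constant radius, present on every A-line)
    zSheath <- config@zCore + as.integer(round(config@sheathRadius /
                                               config@axialPitch))
    refl <- matrix(0, FA, Z)
    refl[, config@zCore] <- 50 * config@amplitude
    refl[, config@zCore + c(-1L, 1L)] <- 10 * config@amplitude
    refl[, zSheath] <- 5 * config@amplitude
    refl[, zSheath - 1L] <- 2 * config@amplitude
    lin <- sig + refl

    ## multipath ghost: attenuated, axially smeared copy in the end band
    mp <- config@artifactSpec$multipath
    if (!is.null(mp)) {
      bandLen <- Z - bounds$maStart + 1L
      src <- round(seq(config@zCore, bounds$fiEnd, length.out = bandLen))
      sm <- t(apply(lin, 1L, gaussSmooth1d, width = 7L, sigma = mp$smear))
      lin[, bounds$maStart:Z] <- lin[, bounds$maStart:Z] +
        mp$scale * sm[, src]
    }

    ## additive noise floor everywhere
    if (is.finite(config@noiseFloorDb)) {
      nf <- dbToLinear(config@noiseFloorDb)
      lin <- lin + stats::rgamma(FA * Z, shape = config@noiseShape,
                                 rate = config@noiseShape / nf)
    }

    octArr <- array(linearToDb(pmax(lin, 1e-12)), dim = c(F, A, Z))
    vol <- OctVolume(octArr, axialPitch = config@axialPitch,
                     azimuthalPitch = config@azimuthalPitch,
                     framePitch = config@framePitch,
                     fiEnd = bounds$fiEnd, maStart = bounds$maStart)

    ## en face AFI: depth-decayed concentration readout plus background
    d <- (surf - config@zCore) * config@axialPitch
    signal <- config@afiGain * fields$conc * afiDecayModel(config, d)
    signal[is.na(d)] <- 0
    signal[removeMask] <- signal[removeMask] * 0.05
    noisy <- signal * pmax(0, 1 + stats::rnorm(FA, sd = config@afiNoiseSd)) +
      config@afiBackground *
        pmax(0, 1 + stats::rnorm(FA, sd = config@afiNoiseSd))
    afiMap <- AfiMap(matrix(pmax(noisy, 0), F, A), units = "raw")

    ## ground-truth attenuation sidecar
    truthMu <- array(muMat, dim = c(F, A, Z))
    conc <- fields$conc
    conc[is.na(surf)] <- NA_real_

    air <- is.na(surf)
    keep <- !air & !removeMask
    mask <- EnFaceMask(keep = keep, remove = removeMask & !air,
                       background = air)

    specLenMm <- (config@specimenFrames[2L] - config@specimenFrames[1L] + 1L) *
      config@framePitch / 1000
    lesionFrames <- sort(unique(unlist(
      lapply(config@lesionSpec, function(l) l$frames))))
    meta <- list(
      specimenFrames = config@specimenFrames,
      pathology = list(specimenLengthMm = specLenMm,
                       fimbriaeLengthMm = 0.2 * specLenMm,
                       fullyImaged = TRUE),
      lesionMask = fields$lesion,
      lesionFrames = lesionFrames
    )

    new("PhantomBundle", config = config, oct = vol, afi = afiMap,
        brightStandard = bright, darkStandard = dark,
        truthSurface = surf, truthMu = truthMu,
        truthConcentration = conc, enfaceMask = mask, metadata = meta)
  })
}

#' Generate a calibration-standard acquisition
#'
#' Emulates imaging a 15 mL test tube: the bright standard contains 0.98 uM
#' fluorescein, the dark standard water under matte black foil. The fluid is
#' low-scattering, so the OCT channel shows only the core and sheath
#' reflections (plus, when it fits in the depth range, the test-tube wall at
#' 900 um, beyond the 750 um sheath-search cutoff). The sheath sits at a
#' varying distance from the core so the standards span a usable depth range
#' for the depth-intensity model fit.
#'
#' @param kind `"bright"` or `"dark"`.
#' @param config a [PhantomConfig-class]; the standard reuses its geometry,
#'   decay model and noise settings, with seed offsets 101/102.
#' @param sheathProfile optional `[frame, azimuth]` matrix of core-to-sheath
#'   distances in micrometres (default: 300-550 um sinusoid).
#' @param concentration fluorescein concentration of the bright standard,
#'   uM (default 0.98).
#' @return a [StandardVolume-class]; slot `truthSheathZ` holds the true
#'   sheath-surface depth indices.
#' @export
generateStandard <- function(kind = c("bright", "dark"), config,
                             sheathProfile = NULL, concentration = 0.98) {
  kind <- match.arg(kind)
  validObject(config)
  withPhantomSeed(config@seed + if (kind == "bright") 101L else 102L, {
    F <- config@nFrames; A <- config@nAzimuth; Z <- config@nDepth
    FA <- F * A
    if (is.null(sheathProfile)) {
      f <- seq_len(F); a <- seq_len(A)
      sheathProfile <- 425 +
        outer(25 * sin(2 * pi * f / max(F, 2L)),
              100 * sin(2 * pi * a / A), "+")
    }
    zs <- config@zCore + round(sheathProfile / config@axialPitch)
    zs <- matrix(pmin(pmax(as.integer(zs), config@zCore + 2L), Z - 1L), F, A)

    lin <- matrix(0, FA, Z)
    lin[, config@zCore] <- 50 * config@amplitude
    lin[, config@zCore + c(-1L, 1L)] <- 10 * config@amplitude
    zsV <- as.vector(zs)
    lin[cbind(seq_len(FA), zsV)] <- 5 * config@amplitude
    lin[cbind(seq_len(FA), zsV - 1L)] <- 2 * config@amplitude
    zWall <- config@zCore + as.integer(round(900 / config@axialPitch))
    if (zWall <= Z) lin[, zWall] <- 3 * config@amplitude
    if (is.finite(config@noiseFloorDb)) {
      nf <- dbToLinear(config@noiseFloorDb)
      lin <- lin + stats::rgamma(FA * Z, shape = config@noiseShape,
                                 rate = config@noiseShape / nf)
    }
    vol <- OctVolume(array(linearToDb(pmax(lin, 1e-12)), dim = c(F, A, Z)),
                     axialPitch = config@axialPitch,
                     azimuthalPitch = config@azimuthalPitch,
                     framePitch = config@framePitch,
                     fiEnd = Z - 28L, maStart = NA_integer_)

    d <- (zs - config@zCore) * config@axialPitch
    conc <- if (kind == "bright") concentration else 0
    signal <- config@afiGain * conc * afiDecayModel(config, d)
    noisy <- signal * pmax(0, 1 + stats::rnorm(FA, sd = config@afiNoiseSd)) +
      config@afiBackground *
        pmax(0, 1 + stats::rnorm(FA, sd = config@afiNoiseSd))
    afiMap <- AfiMap(matrix(pmax(noisy, 0), F, A), units = "raw")

    new("StandardVolume", kind = kind, oct = vol, afi = afiMap,
        truthSheathZ = zs)
  })
}
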