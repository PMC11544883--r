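# Small phantom fixtures shared across the suite. Test volumes keep the
# geometry of the defaults but shrink the grid; the gentle frame wobble
# keeps the truth surface slowly varying over the short pullback segments.

smallConfig <- function(..., seed = 1L) {
  args <- list(nFrames = 10L, nAzimuth = 48L, nDepth = 140L,
               surfaceProfile = list(base = 350, azAmplitude = 30,
                                     azCycles = 2, frameAmplitude = 10),
               seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(phantomConfig, args)
}

# noiseless, speckle-free, artifact-free phantom: exact single-scattering
cleanConfig <- function(..., seed = 1L) {
  smallConfig(speckleShape = Inf, noiseFloorDb = -Inf, afiNoiseSd = 0,
              artifactSpec = list(), seed = seed, ...)
}

# assemble an OctVolume from explicit linear-intensity columns
volumeFromLinear <- function(lin, axialPitch = 10, fiEnd = dim(lin)[3L],
                             maStart = NA_integer_) {
  OctVolume(array(linearToDb(pmax(lin, 1e-12)), dim = dim(lin)),
            axialPitch = axialPitch, fiEnd = fiEnd, maStart = maStart)
}
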