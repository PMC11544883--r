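test_that("out-of-plane averaging matches a direct convolution oracle", {
  set.seed(1)
  arr <- array(rnorm(12 * 6 * 9), dim = c(12, 6, 9))
  vol <- OctVolume(arr)
  sm <- smoothOutOfPlane(vol, halfWidth = 5L)
  oracle <- array(NA_real_, dim = dim(arr))
  for (f in 1:12) {
    fr <- max(1, f - 5):min(12, f + 5)
    oracle[f, , ] <- apply(arr[fr, , , drop = FALSE], c(2, 3), mean)
  }
  expect_equal(intensity(sm), oracle, tolerance = 1e-12)

  expect_identical(intensity(smoothOutOfPlane(vol, 0L)), arr)
  const <- OctVolume(array(2.5, dim = c(11, 4, 6)))
  expect_equal(intensity(smoothOutOfPlane(const, 5L)),
               intensity(const), tolerance = 1e-12)

  # an impulse spreads to exactly 11 frames with weight 1/11 in the interior
  imp <- array(0, dim = c(30, 2, 2)); imp[15, 1, 1] <- 1
  smI <- intensity(smoothOutOfPlane(OctVolume(imp), 5L))
  expect_equal(smI[10:20, 1, 1], rep(1 / 11, 11), tolerance = 1e-12)
  expect_equal(smI[c(9, 21), 1, 1], c(0, 0))
})

test_that("core detection picks the lower of the two most prominent peaks", {
  lin <- array(1e-6, dim = c(5, 16, 60))
  lin[, , 12] <- 1e-1
  lin[, , 18] <- 5e-2
  vol <- volumeFromLinear(lin)
  expect_identical(detectCoreReflection(vol), 12L)

  one <- array(1e-6, dim = c(5, 16, 60))
  one[, , 12] <- 1e-1
  expect_error(detectCoreReflection(volumeFromLinear(one)),
               "no core reflection")
})

test_that("core detection recovers the phantom geometry under noise", {
  ph <- generatePhantom(smallConfig(seed = 21L))
  z <- detectCoreReflection(oct(ph))
  expect_lte(abs(z - 10L), 1L)
  # and on the standards, without tissue masking
  zb <- detectCoreReflection(oct(ph@brightStandard))
  expect_lte(abs(zb - 10L), 1L)
})

test_that("noiseless phantom surfaces are recovered within one pixel", {
  ph <- generatePhantom(cleanConfig(seed = 3L))
  surf <- segmentLumenSurface(oct(ph))
  truth <- ph@truthSurface
  tissue <- !is.na(truth)
  expect_true(all(!is.na(surf[tissue])))
  expect_lte(max(abs(surf[tissue] - truth[tissue])), 1L)
  # air frames far enough from tissue have no surface and flag low quality
  airFrames <- which(is.na(truth[, 1]))
  expect_true(all(is.na(surf[airFrames, ])))
  expect_true(all(airFrames %in% attr(surf, "lowQualityFrames")))
})

test_that("a pure noise-floor volume yields no valid surface columns", {
  set.seed(8)
  lin <- array(rgamma(6 * 24 * 120, shape = 4, rate = 4e3),
               dim = c(6, 24, 120))
  vol <- volumeFromLinear(lin)
  surf <- segmentLumenSurface(vol, searchFrom = 1L)
  expect_true(all(is.na(surf)))
})

test_that("surface segmentation is equivariant under azimuthal rotation", {
  ph <- generatePhantom(smallConfig(seed = 13L))
  vol <- smoothOutOfPlane(oct(ph), 5L)
  s0 <- segmentLumenSurface(vol)
  s1 <- segmentLumenSurface(rotateAzimuth(vol, 11L))
  strip <- function(m) matrix(as.vector(m), nrow(m), ncol(m))
  expect_identical(strip(s1), strip(rotateAzimuth(s0, 11L)))
})

test_that("sheath segmentation finds the outer sheath and ignores the tube wall", {
  cfg <- smallConfig(seed = 6L)
  sp <- matrix(450, cfg@nFrames, cfg@nAzimuth)
  std <- generateStandard("bright", cfg, sheathProfile = sp)
  surf <- segmentSheathSurface(std)
  # sheath at 450 um / 10 um pitch; the wall reflection at 900 um is beyond
  # the 750 um cutoff and must not be picked
  expect_true(all(abs(surf - (10L + 45L)) <= 1L))
})

test_that("the sheath threshold sits exactly 3 dB above the noise floor", {
  lin <- array(dbToLinear(-40), dim = c(1, 8, 120))
  lin[, , 20] <- dbToLinear(-10)           # sheath line for all columns
  vol <- volumeFromLinear(lin)
  vol@intensity[1, 2, 30] <- -40 + 2.9     # excluded
  vol@intensity[1, 5, 30] <- -40 + 3.1     # included
  std <- new("StandardVolume", kind = "bright", oct = vol,
             afi = AfiMap(matrix(1, 1, 8)))
  surf <- segmentSheathSurface(std, coreRef = 5L, maxJump = 99L,
                               medianWidth = 1L, smoothHalfWidth = 0L)
  expect_identical(surf[1, 2], 20L)
  expect_identical(surf[1, 5], 30L)
})

test_that("an empty threshold mask is an error", {
  lin <- array(dbToLinear(-40), dim = c(2, 8, 120))
  std <- new("StandardVolume", kind = "dark",
             oct = volumeFromLinear(lin), afi = AfiMap(matrix(1, 2, 8)))
  expect_error(segmentSheathSurface(std, coreRef = 5L), "empty threshold")
})

test_that("noise floor bookkeeping matches the index oracle", {
  # constant tail: exact floor value
  lin <- array(dbToLinear(-40), dim = c(2, 6, 120))
  vol <- volumeFromLinear(lin)
  nf <- estimateNoiseFloor(vol)
  expect_equal(unname(nf[1, 1]), -40, tolerance = 1e-12)
  expect_identical(unname(attr(nf, "window")), c(96L, 120L))
  expect_identical(attr(nf, "source"), "end-of-A-line")

  # multipath band starting at z = 401: window is [376, 400]
  arr <- array(0, dim = c(1, 4, 430))
  set.seed(2)
  win <- matrix(rnorm(4 * 25, mean = -40), 4, 25)
  arr[1, , 376:400] <- win
  arr[1, , 401:430] <- 10        # multipath band: must not be used
  arr[1, , 1:375] <- 5           # neither must anything shallower
  vol2 <- OctVolume(arr, fiEnd = 340L, maStart = 401L)
  nf2 <- estimateNoiseFloor(vol2)
  expect_identical(unname(attr(nf2, "window")), c(376L, 400L))
  expect_identical(attr(nf2, "source"), "pre-multipath")
  # Gaussian smoothing with symmetric padding preserves the window mean
  expect_equal(unname(nf2[1, ]), rowMeans(win), tolerance = 1e-12)
})

test_that("truncation matches the analytic threshold crossing", {
  s <- 20L; mu <- 8; A <- 0.1; delta <- 0.01
  Z <- 140L
  lin <- array(1e-12, dim = c(1, 4, Z))
  for (a in 1:4)
    lin[1, a, s:(Z - 28L)] <- A * mu * exp(-2 * mu * delta *
                                           seq_len(Z - 28L - s + 1L))
  lin[1, , (Z - 24L):Z] <- dbToLinear(-40)
  vol <- volumeFromLinear(lin)
  nf <- estimateNoiseFloor(vol)
  surface <- matrix(s, 1, 4)
  mask <- truncateALines(vol, surface, nf, marginDb = 6)
  thr <- dbToLinear(-34)
  nAnalytic <- as.integer(s - 1L + floor(log(A * mu / thr) / (2 * mu * delta)))
  cols <- tubavision:::tissueColumns(mask)
  expect_identical(unname(cols$nLast[1, ]), rep(nAnalytic, 4L))

  # empty column: surface invalid
  surface[1, 2] <- NA_integer_
  mask2 <- truncateALines(vol, surface, nf, marginDb = 6)
  expect_false(any(mask2[1, 2, ]))

  # monotone: raising the margin can only shrink the mask
  mask8 <- truncateALines(vol, surface, nf, marginDb = 8)
  expect_true(all(mask8[mask2 == FALSE] == FALSE))
  expect_true(all(which(mask8) %in% which(mask2)))
})

test_that("vectorized truncation agrees exactly with a per-pixel reference", {
  set.seed(77)
  for (rep in 1:50) {
    d <- c(3L, sample(8:16, 1L), sample(50:70, 1L))
    lin <- array(rgamma(prod(d), shape = 2, rate = 10), dim = d)
    vol <- volumeFromLinear(lin, fiEnd = d[3L] - 28L)
    surface <- matrix(sample(c(NA_integer_, 5:20), d[1L] * d[2L],
                             replace = TRUE), d[1L], d[2L])
    nf <- estimateNoiseFloor(vol)
    mask <- truncateALines(vol, surface, nf, marginDb = 6)
    for (f in seq_len(d[1L])) for (a in seq_len(d[2L])) for (z in seq_len(d[3L])) {
      expected <- !is.na(surface[f, a]) && z >= surface[f, a] &&
        z <= vol@fiEnd && intensity(vol)[f, a, z] >= nf[f, a] + 6
      if (mask[f, a, z] != expected)
        fail(sprintf("mismatch at (%d, %d, %d)", f, a, z))
    }
  }
  succeed()
})
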