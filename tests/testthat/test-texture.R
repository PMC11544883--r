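test_that("a constant region has the analytic texture values", {
  xsec <- matrix(5, 16, 20)
  mask <- matrix(TRUE, 16, 20)
  g <- glcmFeatures(xsec, mask, qLow = 0, qHigh = 10)
  expect_identical(g$contrast, 0)
  expect_identical(g$energy, 1)
  expect_identical(g$homogeneity, 1)
  expect_identical(g$entropy, 0)
  expect_true(is.na(g$correlation))
  expect_equal(sum(g$glcm), 1)
})

test_that("alternating azimuthal stripes give correlation -1", {
  xsec <- matrix(rep(c(2, 8), 8), 16, 20)   # period-2 stripes along azimuth
  mask <- matrix(TRUE, 16, 20)
  g <- glcmFeatures(xsec, mask, qLow = 0, qHigh = 10)
  expect_equal(g$correlation, -1, tolerance = 1e-12)
  # exactly two off-diagonal cells, each holding half the pairs
  expect_equal(sort(g$glcm[g$glcm > 0]), c(0.5, 0.5))
})

test_that("features match the brute-force oracle on random masked sections", {
  set.seed(12)
  for (rep in 1:50) {
    nA <- sample(8:20, 1); nZ <- sample(10:30, 1)
    xsec <- matrix(rnorm(nA * nZ, sd = 12), nA, nZ)
    mask <- matrix(runif(nA * nZ) < 0.7, nA, nZ)
    q <- stats::quantile(xsec[mask], c(0.05, 0.95))
    if (q[1] >= q[2]) next
    g <- glcmFeatures(xsec, mask, q[1], q[2])
    o <- glcmOracle(xsec, mask, q[1], q[2])
    expect_equal(g$nPairs, o$nPairs)
    for (f in c("contrast", "correlation", "energy", "homogeneity",
                "entropy"))
      expect_equal(g[[f]], o[[f]], tolerance = 1e-12)
  }
})

test_that("the co-occurrence matrix is a probability table with stable bins", {
  set.seed(3)
  xsec <- matrix(rnorm(300), 15, 20)
  mask <- matrix(runif(300) < 0.8, 15, 20)
  q <- c(-2, 2)
  g <- glcmFeatures(xsec, mask, q[1], q[2])
  expect_equal(sum(g$glcm), 1, tolerance = 1e-12)
  expect_true(all(g$glcm >= 0))
  # a sub-bin-width offset that crosses no bin edge leaves features alone
  binWidth <- diff(q) / 32
  centers <- q[1] + (sample(0:31, 300, TRUE) + 0.5) * binWidth
  xc <- matrix(centers, 15, 20)
  g1 <- glcmFeatures(xc, mask, q[1], q[2])
  g2 <- glcmFeatures(xc + 0.01 * binWidth, mask, q[1], q[2])
  for (f in c("contrast", "energy", "homogeneity", "entropy"))
    expect_identical(g1[[f]], g2[[f]])
  # zero valid pairs: all features invalid
  g0 <- glcmFeatures(xsec, mask & FALSE, q[1], q[2])
  expect_true(is.na(g0$contrast) && g0$nPairs == 0L)
})

test_that("cross-section features are invariant under azimuthal rotation", {
  set.seed(6)
  xsec <- matrix(rnorm(15 * 20), 15, 20)
  mask <- matrix(runif(300) < 0.8, 15, 20)
  g1 <- glcmFeatures(xsec, mask, -2, 2)
  g2 <- glcmFeatures(xsec[c(5:15, 1:4), ], mask[c(5:15, 1:4), ], -2, 2)
  for (f in c("contrast", "correlation", "energy", "homogeneity", "entropy"))
    expect_equal(g1[[f]], g2[[f]], tolerance = 1e-12)
})

test_that("volume quantiles are order statistics over the masked voxels", {
  set.seed(10)
  vol <- OctVolume(array(runif(1e6), dim = c(10, 100, 1000)))
  mask <- array(TRUE, dim = c(10, 100, 1000))
  q <- volumeQuantiles(vol, mask)
  expect_lt(abs(q[1] - 0.05), 0.01)
  expect_lt(abs(q[2] - 0.95), 0.01)
  # invariant under a mask-preserving permutation of voxels
  arr <- intensity(vol)
  perm <- array(sample(arr), dim = dim(arr))
  expect_equal(volumeQuantiles(OctVolume(perm), mask), q, tolerance = 1e-12)
  expect_error(volumeQuantiles(OctVolume(array(1, dim = c(5, 10, 10))),
                               array(TRUE, dim = c(5, 10, 10))),
               "degenerate")
  expect_error(volumeQuantiles(vol, mask & FALSE), "masked voxels")
})

test_that("gamma speckle means are recovered from modest windows", {
  hits <- vapply(seq_len(200), function(s) {
    set.seed(3000 + s)
    x <- rgamma(500, shape = 2, rate = 0.5)
    fit <- tubavision:::gammaFitMle(x)
    abs(fit$mean / 4 - 1) < 0.10
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  # the estimate tightens roughly as 1/sqrt(n)
  set.seed(71)
  spread <- vapply(c(1e2, 1e3, 1e4), function(n) {
    stats::sd(vapply(1:40, function(i)
      tubavision:::gammaFitMle(rgamma(n, 2, 0.5))$mean, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(spread) < 0))
})

test_that("the gamma fit agrees with an independent ML implementation", {
  set.seed(8)
  x <- rgamma(2000, shape = 3.2, rate = 1.7)
  fit <- tubavision:::gammaFitMle(x)
  ref <- fitdistrplus::fitdist(x, "gamma", method = "mle")
  expect_equal(fit$alpha, unname(ref$estimate["shape"]), tolerance = 1e-3)
  expect_equal(fit$beta, unname(ref$estimate["rate"]), tolerance = 1e-3)
})

test_that("speckle maps pool the azimuthal window and honour exclusions", {
  set.seed(21)
  d <- c(2L, 22L, 70L)
  lin <- array(rgamma(prod(d), shape = 2, rate = 0.5), dim = d)
  vol <- volumeFromLinear(lin)
  mask <- array(FALSE, dim = d)
  mask[, , 11:55] <- TRUE                     # 45 px per A-line
  mask[2, 5, ] <- FALSE
  mask[2, 5, 11:19] <- TRUE                   # 9 px: below min depth
  sm <- speckleMap(vol, mask)
  expect_true(is.na(sm$mean[2, 5]))
  expect_false(is.na(sm$mean[1, 5]))
  expect_equal(sm$mean[1, 1],
               mean(lin[1, c(18:22, 1:6), 11:55]), tolerance = 1e-9)
  ok <- !is.na(sm$mean)
  expect_lt(abs(mean(sm$mean[ok]) / 4 - 1), 0.10)
  expect_equal(sm$mean[ok], (sm$alpha / sm$beta)[ok], tolerance = 1e-9)

  # constant window: fit degenerates, pixel invalid
  con <- volumeFromLinear(array(1, dim = d))
  expect_true(all(is.na(speckleMap(con, mask)$mean)))
})

test_that("speckle maps rotate with the volume", {
  set.seed(33)
  d <- c(1L, 24L, 70L)
  lin <- array(rgamma(prod(d), 2, 1), dim = d)
  vol <- volumeFromLinear(lin)
  mask <- array(TRUE, dim = d)
  s0 <- speckleMap(vol, mask)$mean
  s1 <- speckleMap(rotateAzimuth(vol, 5L), mask)$mean
  expect_equal(s1, rotateAzimuth(s0, 5L), tolerance = 1e-12)
})
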