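test_that("the linearized estimator matches the geometric-series closed form", {
  mu <- 3; delta <- 0.01; n <- 100L
  r <- exp(-2 * mu * delta)
  I <- 5 * r^(0:(n - 1L))
  est <- depthResolvedMu(I, delta, linearized = TRUE)
  # closed form: S_z = I0 * r^(z+1) * (1 - r^(n-z)) / (1 - r), mu(N) = mu
  z <- 0:(n - 1L)
  S <- 5 * r^(z + 1) * (1 - r^(n - 1L - z)) / (1 - r)
  expected <- I / (2 * delta * S + I[n] / mu)
  expect_lt(max(abs(est$mu / expected - 1)), 1e-10)
  expect_false(est$flagged)
  expect_equal(est$muTail, mu, tolerance = 1e-10)
})

test_that("the exact discrete inversion removes the discretization bias", {
  delta <- 0.01
  for (mu in c(1, 3, 8)) {
    I <- exp(-2 * mu * delta * (1:120))
    est <- depthResolvedMu(I, delta)
    upper <- seq_len(96L)           # upper 80% of the column
    expect_lt(max(abs(est$mu[upper] / mu - 1)), 0.01)
    # the linearized form carries a bias of about mu * delta
    lin <- depthResolvedMu(I, delta, linearized = TRUE)
    expect_equal(lin$mu[1L] / mu - 1, mu * delta, tolerance = 0.2)
  }
})

test_that("both estimator forms agree with a naive quadratic-time oracle", {
  set.seed(5)
  I <- rgamma(60, shape = 3, rate = 0.2)
  delta <- 0.01
  n <- length(I)
  tail <- (n - 9L):n
  slope <- stats::coef(stats::lm(log(I[tail]) ~ tail))[2L]
  muN <- -slope / (2 * delta)
  if (muN <= 0) muN <- 0.1
  naive <- vapply(seq_len(n), function(z) {
    S <- if (z < n) sum(I[(z + 1L):n]) else 0
    I[z] / (2 * delta * S + I[n] / muN)
  }, numeric(1))
  est <- depthResolvedMu(I, delta, linearized = TRUE, muCap = Inf,
                         muFloor = 0)
  expect_lt(max(abs(est$mu / naive - 1)), 1e-10)
  exact <- depthResolvedMu(I, delta, muCap = Inf, muFloor = 0)
  expect_lt(max(abs(exact$mu / (log1p(2 * delta * naive) / (2 * delta)) - 1)),
            1e-10)
})

test_that("the estimator is scale invariant and the grouping flag matters", {
  I <- exp(-2 * 4 * 0.01 * (1:80))
  a <- depthResolvedMu(I, 0.01)
  b <- depthResolvedMu(1e4 * I, 0.01)
  expect_equal(a$mu, b$mu, tolerance = 1e-12)
  g <- depthResolvedMu(I, 0.01, groupedTail = TRUE)
  expect_false(isTRUE(all.equal(a$mu[70:80], g$mu[70:80])))
})

test_that("a two-layer profile shows its step within two pixels", {
  prof <- c(rep(2, 40), rep(5, 40))
  I <- generateALine(prof, delta = 0.01, amplitude = 3)
  est <- depthResolvedMu(I, 0.01)
  crossing <- which(est$mu > 3.5)[1L]
  expect_lte(abs(crossing - 41L), 2L)
  expect_lt(max(abs(est$mu[5:35] / 2 - 1)), 0.05)
  expect_lt(max(abs(est$mu[45:70] / 5 - 1)), 0.05)
})

test_that("degenerate columns are floored, flagged or skipped", {
  Iup <- exp(+2 * 3 * 0.01 * (1:40))       # growing: non-physical tail
  est <- depthResolvedMu(Iup, 0.01)
  expect_true(est$flagged)
  expect_equal(est$muTail, 0.1)
  expect_error(depthResolvedMu(rep(1, 5), 0.01), "shorter")
  expect_error(depthResolvedMu(c(rep(1, 20), -1, rep(1, 9)), 0.01),
               "positive")
})

test_that("band projections follow the per-column 50% split", {
  d <- c(1L, 3L, 60L)
  mu <- array(NA_real_, dim = d)
  mask <- array(FALSE, dim = d)
  # column 1: homogeneous 4 over 40 px; column 2: 20 px of 2 then 20 of 5;
  # column 3: 3 px only (floor(1.5) = 1 superficial, 2 deep)
  mu[1, 1, 11:50] <- 4;            mask[1, 1, 11:50] <- TRUE
  mu[1, 2, 11:50] <- c(rep(2, 20), rep(5, 20)); mask[1, 2, 11:50] <- TRUE
  mu[1, 3, 11:13] <- c(1, 7, 9);   mask[1, 3, 11:13] <- TRUE
  att <- new("AttenuationVolume", mu = mu, delta = 0.01,
             nLast = matrix(c(50L, 50L, 13L), 1, 3),
             muTail = matrix(4, 1, 3), flagged = matrix(FALSE, 1, 3))
  ov <- projectMu(att, mask, "overall")
  sup <- projectMu(att, mask, "superficial")
  deep <- projectMu(att, mask, "deep")
  expect_equal(c(ov), c(4, 3.5, mean(c(1, 7, 9))))
  expect_equal(c(sup), c(4, 2, 1))
  expect_equal(c(deep), c(4, 5, 8))
})

test_that("stratification is bounded, antisymmetric, and pins the extremes", {
  expect_identical(stratification(matrix(0), matrix(4)), matrix(-1))
  expect_identical(stratification(matrix(4), matrix(0)), matrix(1))
  expect_identical(stratification(matrix(3), matrix(3)), matrix(0))
  set.seed(4)
  a <- matrix(runif(100, 0, 10), 10, 10)
  b <- matrix(runif(100, 0, 10), 10, 10)
  s <- stratification(a, b)
  expect_true(all(s >= -1 & s <= 1))
  expect_equal(s, -stratification(b, a), tolerance = 1e-12)
  expect_true(is.na(stratification(matrix(0), matrix(0))[1, 1]))
})

test_that("speckled attenuation is recovered within 10% in the median", {
  set.seed(99)
  delta <- 0.01
  for (mu in c(1, 2, 4, 8)) {
    # column length mirrors the 6 dB truncation: a fixed dynamic range
    n <- min(400L, max(40L, round(3 / (mu * delta))))
    up <- seq_len(round(0.8 * n))
    perCol <- vapply(seq_len(20L), function(i) {
      I <- generateALine(rep(mu, n), delta = delta, amplitude = 1,
                         speckleShape = 4)
      est <- depthResolvedMu(I, delta)
      mean(est$mu[up])
    }, numeric(1))
    expect_lt(abs(stats::median(perCol) / mu - 1), 0.10)
  }
})

test_that("attenuation over a phantom tissue mask recovers the truth field", {
  cfg <- cleanConfig(seed = 23L)
  ph <- generatePhantom(cfg)
  surf <- segmentLumenSurface(oct(ph))
  nf <- estimateNoiseFloor(oct(ph))
  mask <- truncateALines(oct(ph), surf, nf)
  att <- attenuationVolume(oct(ph), mask)
  ok <- !is.na(att@mu) & !is.na(ph@truthMu)
  # noiseless: per-voxel recovery tight away from boundary/tail pixels
  relErr <- abs(att@mu[ok] / ph@truthMu[ok] - 1)
  expect_lt(stats::median(relErr), 0.02)
  expect_true(all(att@mu[ok] > 0))
})
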