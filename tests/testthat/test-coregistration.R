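test_that("region labels follow the pathology arithmetic", {
  # imaged length equals the report: 60 mm, fimbriae 10 mm, 1 mm frames
  lab <- assignLabels(60L, 1000,
                      list(specimenLengthMm = 60, fimbriaeLengthMm = 10,
                           fullyImaged = TRUE),
                      specimenFrames = c(1L, 60L))
  expect_identical(lab$region[51:60], rep("fimbriae", 10))
  expect_identical(lab$region[21:50], rep("ampulla", 30))
  expect_identical(lab$region[1:20], rep("isthmus", 20))
  expect_identical(attr(lab, "scale"), 1)

  # imaged longer than the report: everything scales by 1.1
  lab2 <- assignLabels(66L, 1000,
                       list(specimenLengthMm = 60, fimbriaeLengthMm = 10,
                            fullyImaged = TRUE),
                       specimenFrames = c(1L, 66L))
  expect_identical(attr(lab2, "scale"), 1.1)
  expect_identical(lab2$region[56:66], rep("fimbriae", 11))
  expect_identical(lab2$region[23:55], rep("ampulla", 33))
  expect_identical(lab2$region[1:22], rep("isthmus", 22))

  # not fully imaged: pathology lengths used directly
  lab3 <- assignLabels(40L, 1000,
                       list(specimenLengthMm = 60, fimbriaeLengthMm = 10,
                            fullyImaged = FALSE),
                       specimenFrames = c(1L, 40L))
  expect_identical(attr(lab3, "scale"), 1)
  expect_identical(lab3$region[31:40], rep("fimbriae", 10))
})

test_that("label edge cases behave", {
  # zero fimbriae length: no fimbriae frames, ampulla still 50%
  lab <- assignLabels(60L, 1000,
                      list(specimenLengthMm = 60, fimbriaeLengthMm = 0,
                           fullyImaged = TRUE),
                      specimenFrames = c(1L, 60L))
  expect_false(any(lab$region == "fimbriae"))
  expect_identical(sum(lab$region == "ampulla"), 30L)
  expect_error(
    assignLabels(10L, 1000, list(specimenLengthMm = 5,
                                 fimbriaeLengthMm = 9)),
    "exceeds")
  # frames outside the specimen are unlabelled
  lab4 <- assignLabels(10L, 1000,
                       list(specimenLengthMm = 6, fimbriaeLengthMm = 2,
                            fullyImaged = TRUE),
                       specimenFrames = c(3L, 8L))
  expect_identical(lab4$region[c(1, 2, 9, 10)], rep("none", 4))
  expect_identical(lab4$diagnosis[c(1, 2, 9, 10)], rep("unknown", 4))
})

test_that("block diagnoses map frames through the same scaling", {
  lab <- assignLabels(12L, 1000,
                      list(specimenLengthMm = 12, fimbriaeLengthMm = 2,
                           fullyImaged = TRUE,
                           blockDiagnoses = c("no_lesion", "no_lesion",
                                              "lesion", "no_lesion",
                                              "no_lesion", "no_lesion")),
                      specimenFrames = c(1L, 12L))
  expect_identical(lab$diagnosis[5:6], rep("lesion", 2))
  expect_identical(lab$diagnosis[c(1:4, 7:12)], rep("no_lesion", 10))
  # missing trailing blocks leave frames unknown
  lab2 <- assignLabels(12L, 1000,
                       list(specimenLengthMm = 12, fimbriaeLengthMm = 2,
                            fullyImaged = TRUE,
                            blockDiagnoses = c("no_lesion", "lesion")),
                       specimenFrames = c(1L, 12L))
  expect_identical(lab2$diagnosis[5:12], rep("unknown", 8))
})

test_that("en face resampling is area-weighted with invalid propagation", {
  m <- matrix(rnorm(48), 6, 8)
  expect_equal(resampleEnFace(m, 10, 10), m)                 # identity
  cm <- matrix(3.5, 6, 8)
  out <- resampleEnFace(cm, 25, 15)
  expect_true(all(abs(out - 3.5) < 1e-12))                   # constant
  # 2x downsampling of a checkerboard averages to a uniform value
  cb <- outer(1:8, 1:8, function(i, j) (i + j) %% 2) * 2 + 1  # 1/3 board
  out2 <- resampleEnFace(cb, 5, 5, target = 10)
  expect_equal(out2, matrix(2, 4, 4), tolerance = 1e-12)
  # NA hits every output cell it overlaps
  m[3, 4] <- NA
  out3 <- resampleEnFace(m, 20, 20, target = 10)
  expect_true(all(is.na(out3[5:6, 7:8])))
  expect_false(any(is.na(out3[-(5:6), ])))
})

test_that("median extraction respects masks, scopes and pixel order", {
  F <- 12L; A <- 10L
  keep <- matrix(TRUE, F, A)
  remove <- matrix(FALSE, F, A)
  remove[1, 1:5] <- TRUE
  mask <- EnFaceMask(keep = keep & !remove, remove = remove)
  labels <- data.frame(frame = 1:F,
                       region = rep(c("isthmus", "ampulla", "fimbriae"),
                                    each = 4),
                       diagnosis = rep(c("no_lesion", "lesion"), c(8, 4)))
  const <- matrix(7, F, A)
  set.seed(2)
  noisy <- matrix(rnorm(F * A), F, A)
  noisy[remove] <- 1e6                       # masked outliers: no effect
  tab <- summarizeBiomarkers(list(k = const, n = noisy), mask, labels)
  expect_true(all(tab$median[tab$biomarker == "k"] == 7))
  lesionRows <- labels$frame[labels$diagnosis == "lesion"]
  oracle <- stats::median(noisy[lesionRows, ])
  expect_identical(
    tab$median[tab$biomarker == "n" & tab$level == "lesion"], oracle)
  whole <- tab[tab$biomarker == "n" & tab$scope == "whole", ]
  sel <- mask@keep & !mask@remove
  expect_identical(whole$median, stats::median(noisy[sel]))
  expect_identical(whole$nPixels, sum(sel))
  # permutation of pixels within a scope leaves the median unchanged
  shuf <- noisy
  shuf[2, ] <- noisy[2, sample(A)]
  tab2 <- summarizeBiomarkers(list(n = shuf), mask, labels)
  expect_identical(tab2$median[tab2$scope == "whole"], whole$median)
})
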