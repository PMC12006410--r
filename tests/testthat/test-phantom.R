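test_that("inconsistent specs are rejected", {
  expect_error(phantomSpec(imageSize = 96, lumenRadius = 22, thickness = 0,
                           nStruts = 8, strutCovered = TRUE),
               "covered struts")
  ## stent interval outside the pullback
  expect_error(generatePullback(5, seed = 1, imageSize = 64,
                                stentFrames = c(2, 7)),
               "stent interval")
  expect_error(generatePullback(0), "nFrames")
  ## geometry that does not fit the frame
  expect_error(phantomSpec(imageSize = 64, lumenRadius = 40, thickness = 5),
               "fit inside")
})

test_that("rendering is bit-identical for a fixed seed", {
  sp <- phantomSpec(imageSize = 96, lumenRadius = 20, thickness = 10,
                    tissue = c("homogeneous", "heterogeneous",
                               "neoatherosclerosis", "homogeneous"),
                    nStruts = 5, strutCovered = c(TRUE, TRUE, FALSE, TRUE,
                                                  TRUE),
                    sideBranch = c(300, 330), seed = 11)
  a <- generatePhantomFrame(sp)
  b <- generatePhantomFrame(sp)
  expect_identical(octImage(a), octImage(b))
  expect_identical(maskLabels(truthMask(a)), maskLabels(truthMask(b)))
  expect_identical(quadrantLabels(a), quadrantLabels(b))
})

test_that("mask membership matches a brute-force polar oracle", {
  ## centered circular lumen, uniform annulus, no struts/branch: membership
  ## is a pure distance test
  n <- 96; R <- 25; tk <- 12
  sp <- phantomSpec(imageSize = n, lumenRadius = R, thickness = tk,
                    nStruts = 0, seed = 3)
  lab <- maskLabels(truthMask(generatePhantomFrame(sp)))
  ctr <- (n + 1) / 2
  r <- sqrt(outer((1:n - ctr)^2, (1:n - ctr)^2, "+"))
  oracle <- matrix(0L, n, n)
  oracle[r < R] <- 1L
  oracle[r >= R & r < R + tk] <- 2L
  expect_identical(lab, oracle)
})

test_that("geometry re-derived from the mask recovers the spec within 1 px", {
  for (s in 1:10) {
    sp <- withr::with_seed(s, phantomSpec(
      imageSize = 96, lumenRadius = runif(1, 16, 24),
      lumenCenter = c(runif(1, 44, 52), runif(1, 44, 52)),
      thickness = runif(1, 6, 11), nStruts = 0, seed = s))
    m <- truthMask(generatePhantomFrame(sp))
    ctr <- lumenCenter(m)
    expect_lt(max(abs(ctr - sp@lumenCenter)), 1)
    idx <- which(maskLabels(m) == 1L, arr.ind = TRUE)
    meanR <- mean(sqrt((idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2))
    ## mean radius of a filled disc of radius R is 2R/3
    expect_lt(abs(meanR - 2 * sp@lumenRadius / 3), 1)
  }
})

test_that("homogeneous and neoatherosclerosis quadrants are separable by a
          histogram classifier", {
  histOf <- function(cls, s) {
    sp <- phantomSpec(imageSize = 96, lumenRadius = 20, thickness = 11,
                      tissue = cls, nStruts = 0, seed = s)
    t <- generatePhantomFrame(sp)
    px <- octImage(t)[maskLabels(truthMask(t)) == 2L]
    tabulate(findInterval(px, seq(0, 1, by = 0.1)), 11) / length(px)
  }
  train <- 1:50; test <- 51:100
  hHom <- colMeans(t(vapply(train, function(s)
    histOf("homogeneous", s), numeric(11))))
  hNac <- colMeans(t(vapply(train, function(s)
    histOf("neoatherosclerosis", s), numeric(11))))
  pred1 <- vapply(test, function(s) {
    h <- histOf("homogeneous", s)
    sum((h - hHom)^2) < sum((h - hNac)^2)
  }, logical(1))
  pred2 <- vapply(test, function(s) {
    h <- histOf("neoatherosclerosis", s)
    sum((h - hNac)^2) < sum((h - hHom)^2)
  }, logical(1))
  expect_gt(mean(c(pred1, pred2)), 0.9)
})

test_that("pullback structure: stent interval, spacing, annotation flags", {
  pb <- generatePullback(10, seed = 5, imageSize = 64, stentFrames = c(2, 7))
  struts <- vapply(pullbackTruths(pb), function(t)
    sum(maskLabels(truthMask(t)) == 3L), numeric(1))
  expect_true(all(struts[3:8] > 0))        # frames 2..7 (0-based)
  expect_true(all(struts[c(1:2, 9:10)] == 0))
  expect_equal(pb@frameSpacing, 0.2)
  ## one annotated frame per millimetre (every fifth frame)
  expect_equal(sum(annotatedFrames(generatePullback(5, seed = 1,
                                                    imageSize = 64))), 1)
  expect_equal(sum(annotatedFrames(generatePullback(25, seed = 1,
                                                    imageSize = 64))), 5)
})

test_that("not_analyzable quadrants always carry a structural cause", {
  sp <- phantomSpec(imageSize = 96, lumenRadius = 20, thickness = 10,
                    tissue = c("homogeneous", "not_analyzable",
                               "homogeneous", "homogeneous"),
                    nStruts = 0, seed = 2)
  ## the generator planted an uncovered strut in Q2
  expect_true(any(!sp@strutCovered &
                    sp@strutAngles >= 90 & sp@strutAngles < 180))
  t <- generatePhantomFrame(sp)
  expect_equal(quadrantLabels(t)[2], "not_analyzable")
  ## and over random pullbacks the invariant holds for every labelled frame
  for (s in 1:5) {
    t <- generatePullback(1, seed = s, imageSize = 96)[[1]]
    sp <- truthSpec(t)
    for (q in which(quadrantLabels(t) == "not_analyzable")) {
      qiv <- c((q - 1) * 90, q * 90)
      hasUnc <- any(!sp@strutCovered)
      hasBr <- length(sp@sideBranch) > 0
      expect_true(hasUnc || hasBr)
    }
  }
})
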