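## A clean phantom for closed-form checks: centered disc lumen of 40 px and
## a uniform 20-px annulus at 0.01 mm/px.
discPhantom <- function(R = 40, tk = 20, n = 160, seed = 1, ...) {
  generatePhantomFrame(phantomSpec(imageSize = n, lumenRadius = R,
                                   thickness = tk, nStruts = 0,
                                   seed = seed, ...))
}

test_that("radial profiles recover constructed radius and thickness", {
  m <- truthMask(discPhantom())
  prof <- radialProfile(m, spacingMm = 0.01)
  expect_equal(mean(prof$lumenRadiusMm), 0.40, tolerance = 0.025)
  expect_equal(mean(prof$neointimaThicknessMm), 0.20, tolerance = 0.05)
  ## zero-thickness annulus measures zero everywhere
  z <- truthMask(discPhantom(tk = 0))
  profZ <- radialProfile(z, spacingMm = 0.01)
  expect_true(all(profZ$neointimaThicknessMm == 0, na.rm = TRUE))
  ## circular symmetry: 4 rays agree with 360
  p4 <- radialProfile(m, nRays = 4L, spacingMm = 0.01)
  expect_lt(abs(mean(p4$lumenRadiusMm) - mean(prof$lumenRadiusMm)), 0.01)
  ## no lumen: flagged all-missing profile
  profNA <- radialProfile(OCTMask(matrix(0L, 32, 32)))
  expect_true(all(is.na(profNA$lumenRadiusMm)))
  expect_true(attr(profNA, "degenerate"))
})

test_that("minimal lumen diameter finds the stenotic frame and its size", {
  ## identical frames: tie resolves to the lowest index
  m <- truthMask(discPhantom())
  same <- list(m, m, m)
  r <- minimalLumenDiameter(same, spacingMm = 0.01, stentInterval = c(0, 2))
  expect_equal(r$frame, 0L)
  expect_lt(abs(r$diameterMm - 0.80), 0.02)
  ## a pullback with one stenotic frame
  masks <- lapply(1:5, function(i)
    truthMask(discPhantom(R = if (i == 3) 20 else 40, seed = i)))
  r2 <- minimalLumenDiameter(masks, spacingMm = 0.01,
                             stentInterval = c(0, 4))
  expect_equal(r2$frame, 2L)
  expect_lt(abs(r2$diameterMm - 0.40), 0.02)
  expect_error(minimalLumenDiameter(list(OCTMask(matrix(0L, 32, 32))),
                                    stentInterval = c(0, 0)),
               "no stented frames")
})

test_that("uncovered struts are told apart from embedded ones", {
  ph <- generatePhantomFrame(phantomSpec(
    imageSize = 160, lumenRadius = 40, thickness = 20,
    strutAngles = (0:7) * 45 + 20,
    strutCovered = c(rep(TRUE, 5), rep(FALSE, 3)), seed = 2))
  us <- uncoveredStruts(truthMask(ph))
  expect_equal(us$total, 8L)
  expect_equal(us$uncovered, 3L)
  ## no struts at all
  expect_equal(uncoveredStruts(truthMask(discPhantom()))$total, 0L)
  ## a strut fully embedded mid-wall never touches the lumen
  one <- generatePhantomFrame(phantomSpec(
    imageSize = 160, lumenRadius = 40, thickness = 20,
    strutAngles = 45, strutCovered = TRUE, seed = 3))
  expect_equal(uncoveredStruts(truthMask(one))$uncovered, 0L)
})

test_that("stent boundaries come from smoothed per-frame strut counts", {
  pb <- generatePullback(10, seed = 6, imageSize = 96, stentFrames = c(2, 7))
  masks <- lapply(pullbackTruths(pb), truthMask)
  sb <- stentBoundaries(masks)
  expect_true(sb$detected)
  expect_equal(c(sb$start, sb$end), c(2L, 7L))
  ## a single noisy blip is smoothed away
  blip <- lapply(1:6, function(i) {
    m <- matrix(0L, 64, 64); m[30:34, 30:34] <- 1L
    if (i == 1) m[10:12, 10:12] <- 3L
    OCTMask(m)
  })
  expect_false(stentBoundaries(blip)$detected)
  ## fully stented pullback
  pbAll <- generatePullback(6, seed = 8, imageSize = 96)
  sbAll <- stentBoundaries(lapply(pullbackTruths(pbAll), truthMask))
  expect_equal(c(sbAll$start, sbAll$end), c(0L, 5L))
})

test_that("thickness and radius are recovered within 1.5 px over random
          phantoms and respond monotonically to dilation", {
  errR <- c(); errT <- c()
  for (s in 1:50) {
    t <- generatePullback(1, seed = 700 + s, imageSize = 96)[[1]]
    sp <- truthSpec(t)
    prof <- radialProfile(truthMask(t), spacingMm = sp@pixelSpacing)
    ## compare mean measured radius/thickness to the spec values; skip
    ## angles interrupted by branches/uncovered struts via NA handling
    errR <- c(errR, abs(mean(prof$lumenRadiusMm, na.rm = TRUE) -
                          sp@lumenRadius * sp@pixelSpacing))
    thTrue <- mean(sp@thickness) * sp@pixelSpacing
    measured <- mean(prof$neointimaThicknessMm[
      prof$neointimaThicknessMm > 0], na.rm = TRUE)
    if (is.finite(measured)) errT <- c(errT, abs(measured - thTrue))
  }
  pxMm <- 0.01
  expect_lte(mean(errR), 1.5 * pxMm)
  expect_lte(mean(errT), 1.5 * pxMm)
  ## monotonicity: a larger lumen measures larger
  small <- radialProfile(truthMask(discPhantom(R = 30)), spacingMm = 0.01)
  large <- radialProfile(truthMask(discPhantom(R = 45)), spacingMm = 0.01)
  expect_gt(mean(large$lumenRadiusMm), mean(small$lumenRadiusMm))
})

test_that("uncovered-strut flags agree with construction on random
          phantoms", {
  agree <- 0L; total <- 0L
  for (s in 1:50) {
    nU <- s %% 4L
    ph <- generatePhantomFrame(phantomSpec(
      imageSize = 128, lumenRadius = 30, thickness = 14,
      strutAngles = (0:6) * 51.4 + 10,
      strutCovered = rep(c(FALSE, TRUE), c(nU, 7 - nU)), seed = s))
    us <- uncoveredStruts(truthMask(ph))
    total <- total + us$total
    agree <- agree + us$total - abs(us$uncovered - nU) -
      abs(us$total - 7L)
  }
  expect_gte(agree / total, 0.95)
})

test_that("frame morphometrics aggregate areas consistently with pixel
          counts", {
  t <- discPhantom()
  fm <- frameMorphometrics(truthMask(t), spacingMm = 0.01)
  lab <- maskLabels(truthMask(t))
  expect_equal(fm$lumenAreaMm2, sum(lab == 1L) * 1e-4)
  expect_equal(fm$neointimaAreaMm2, sum(lab == 2L) * 1e-4)
  expect_gte(fm$strutCount, fm$uncoveredStrutCount)
  expect_false(fm$degenerate)
})
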