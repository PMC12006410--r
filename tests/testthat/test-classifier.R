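test_that("temperature sharpening follows its closed form", {
  p <- c(0.7, 0.1, 0.1, 0.1)
  expect_equal(sharpenProbs(p, 1), p)
  u <- rep(0.25, 4)
  expect_equal(sharpenProbs(u, 0.3), u)
  expect_equal(sharpenProbs(u, 3), u)
  ## direct evaluation: p^2 / sum(p^2) at T = 0.5
  expect_equal(sharpenProbs(p, 0.5), c(0.49, 0.01, 0.01, 0.01) / 0.52,
               tolerance = 1e-12)
  expect_error(sharpenProbs(p, 0), "temperature")
  expect_error(sharpenProbs(p, -1), "temperature")
})

test_that("sharpening preserves the argmax and converges to one-hot", {
  withr::with_seed(41, {
    for (i in 1:50) {
      p <- runif(4); p <- p / sum(p)
      for (Tm in c(0.1, 0.5, 1, 2, 10)) {
        q <- sharpenProbs(p, Tm)
        expect_equal(which.max(q), which.max(p))
        expect_true(all(q >= 0))
        expect_lt(abs(sum(q) - 1), 1e-9)
      }
      ## one-hot limit requires a unique max: at T = 1e-3 a gap of 0.01
      ## between the top two entries is already astronomically decisive
      gap <- diff(rev(sort(p, decreasing = TRUE)[1:2]))
      if (gap >= 0.01) {
        oneHot <- as.numeric(seq_len(4) == which.max(p))
        expect_lt(max(abs(sharpenProbs(p, 1e-3) - oneHot)), 1e-6)
      }
    }
  })
})

test_that("neighbour fusion follows its closed form on the frame circle", {
  P <- list(c(1, 0, 0, 0), c(0, 1, 0, 0), c(0, 1, 0, 0), c(0, 1, 0, 0))
  f <- fuseNeighbors(P, weights = c(0.5, 0.25))
  expect_equal(f[1, ], c(0.5, 0.5, 0, 0))
  ## identity weights
  expect_equal(fuseNeighbors(P, weights = c(1, 0)),
               do.call(rbind, P))
  ## fixed point: all quadrants identical
  same <- replicate(4, c(0.1, 0.2, 0.3, 0.4), simplify = FALSE)
  expect_equal(fuseNeighbors(same, weights = c(0.6, 0.2)),
               do.call(rbind, same))
  expect_error(fuseNeighbors(P, weights = c(0.5, 0.3)), "weights")
})

test_that("fusion commutes with a joint label permutation", {
  withr::with_seed(43, {
    for (i in 1:20) {
      P <- t(replicate(4, { x <- runif(4); x / sum(x) }))
      perm <- sample(4)
      f1 <- fuseNeighbors(P[, perm], weights = c(0.7, 0.15))
      f2 <- fuseNeighbors(P, weights = c(0.7, 0.15))[, perm]
      expect_equal(f1, f2, tolerance = 1e-12)
      expect_true(all(abs(rowSums(f2) - 1) < 1e-9))
    }
  })
})

test_that("TTA averaging: identity set is a no-op, symmetric images are
          flip-invariant, outputs stay on the simplex", {
  qm <- fixtureQuadModel()
  t <- fixturePhantoms(601)[[1]]
  part <- partitionQuadrants(dim(octImage(t)), lumenCenter(truthMask(t)))
  crop <- cropQuadrant(octImage(t), part, 1)
  expect_equal(ttaProbs(qm, crop, tta = "identity"),
               neoquant:::quadSoftmax(qm, crop), tolerance = 1e-12)
  p <- ttaProbs(qm, crop)
  expect_lt(abs(sum(p) - 1), 1e-9)
  expect_true(all(p >= 0))
  ## mirror-symmetric input: adding hflip changes nothing
  sym <- crop
  sym[] <- (crop + crop[, rev(seq_len(ncol(crop)))]) / 2
  attr(sym, "wedge") <- attr(crop, "wedge") |
    attr(crop, "wedge")[, rev(seq_len(ncol(crop)))]
  expect_equal(ttaProbs(qm, sym, tta = c("identity", "hflip")),
               ttaProbs(qm, sym, tta = "identity"), tolerance = 1e-9)
})

test_that("classifier training contracts and determinism", {
  frames <- lapply(fixturePhantoms(611:620), fixtureQuadFrame)
  imgs <- unlist(lapply(frames, `[[`, "crops"), recursive = FALSE)
  labs <- unlist(lapply(frames, `[[`, "labs"))
  cfg <- list(hidden = 4L, maxit = 60L, valFraction = 0.2)
  a <- trainQuadrantClassifier(imgs, labs, config = cfg, seed = 5)
  p <- neoquant:::quadSoftmax(a, imgs[[1]])
  expect_lt(abs(sum(p) - 1), 1e-9)
  expect_true(all(p >= 0))
  b <- trainQuadrantClassifier(imgs, labs, config = cfg, seed = 5)
  expect_identical(a@metrics$confusion, b@metrics$confusion)
  expect_error(trainQuadrantClassifier(imgs, rep("homogeneous",
                                                 length(imgs))),
               "single class")
  expect_error(trainQuadrantClassifier(imgs[1:3], labs[1:2]),
               "differ in length")
})

test_that("desk-scale classifier recovers phantom quadrant labels", {
  ev <- fixtureQuadEval()
  cls <- tissueClasses()
  pred <- cls[max.col(ev$chain, ties.method = "first")]
  expect_gte(mean(pred == ev$labs), 0.9)
})

test_that("the calibrated chain is no worse calibrated than raw softmax", {
  ev <- fixtureQuadEval()
  cls <- tissueClasses()
  rawPred <- cls[max.col(ev$raw, ties.method = "first")]
  chainPred <- cls[max.col(ev$chain, ties.method = "first")]
  eceRaw <- expectedCalibrationError(apply(ev$raw, 1, max),
                                     rawPred == ev$labs)
  eceChain <- expectedCalibrationError(apply(ev$chain, 1, max),
                                       chainPred == ev$labs)
  expect_lte(eceChain, eceRaw)
})

test_that("mixed-texture quadrants earn lower confidence than pure ones", {
  qm <- fixtureQuadModel()
  cal <- fixtureCalibration()
  confOf <- function(tissue, s) {
    sp <- phantomSpec(imageSize = 96, lumenRadius = 21, thickness = 9,
                      tissue = tissue, nSectors = 8, nStruts = 0, seed = s)
    mean(chainConfidence(generatePhantomFrame(sp), qm, cal))
  }
  pure <- vapply(1:50, function(s)
    confOf("homogeneous", s), numeric(1))
  mixed <- vapply(1:50, function(s)
    confOf(rep(c("homogeneous", "neoatherosclerosis"), 4), s), numeric(1))
  expect_lt(mean(mixed), mean(pure))
})

test_that("quadrant records respect the confidence bounds and the
          degenerate-center contract", {
  qm <- fixtureQuadModel()
  t <- fixturePhantoms(605)[[1]]
  rec <- predictQuadrants(qm, octImage(t), truthMask(t),
                          fixtureCalibration())
  expect_equal(nrow(rec), 4)
  expect_true(all(rec$confidence >= 0.25 & rec$confidence <= 1))
  expect_true(all(abs(rowSums(as.matrix(rec[, tissueClasses()])) - 1)
                  < 1e-9))
  deg <- predictQuadrants(qm, octImage(t), OCTMask(matrix(0L, 96, 96)),
                          fixtureCalibration())
  expect_true(all(deg$predicted == "not_analyzable"))
  expect_true(all(deg$confidence == 0))
  expect_true(all(deg$degenerate))
})

test_that("fitted calibration stays within its search grid and validates", {
  cal <- fixtureCalibration()
  expect_s4_class(cal, "CalibrationConfig")
  expect_true(cal@temperature > 0)
  expect_lt(abs(cal@weights[1] + 2 * cal@weights[2] - 1), 1e-9)
  expect_true("identity" %in% cal@tta)
})
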