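test_that("Dice matches direct counting and handles the edge cases", {
  a <- matrix(c(1, 1, 1, 1, 0, 0, 0, 0, 0), 3)
  b <- matrix(c(1, 1, 0, 0, 1, 1, 0, 0, 0), 3)
  expect_equal(as.numeric(diceScore(a, b)), 0.5)        # |a|=4,|b|=4,inter=2
  expect_equal(as.numeric(diceScore(a, a)), 1)
  expect_equal(as.numeric(diceScore(a, !a & (a == 0))), 0)  # disjoint
  z <- matrix(0, 3, 3)
  d <- diceScore(z, z)
  expect_equal(as.numeric(d), 1)
  expect_true(attr(d, "bothEmpty"))
  expect_error(diceScore(matrix(0, 2, 2), z), "shapes")
})

test_that("Dice equals a brute-force overlap oracle on random mask pairs", {
  withr::with_seed(99, {
    for (i in 1:10000) {
      a <- matrix(runif(9) > 0.5, 3)
      b <- matrix(runif(9) > 0.5, 3)
      inter <- sum(a & b); sa <- sum(a); sb <- sum(b)
      oracle <- if (sa + sb == 0) 1 else 2 * inter / (sa + sb)
      if (as.numeric(diceScore(a, b)) != oracle)
        fail(sprintf("mismatch at pair %d", i))
    }
    succeed()
  })
})

test_that("classification metrics: accuracy, macro-F1, confusion", {
  cls <- tissueClasses()
  truth <- c("homogeneous", "homogeneous", "heterogeneous",
             "neoatherosclerosis")
  pred <- c("homogeneous", "heterogeneous", "heterogeneous",
            "neoatherosclerosis")
  m <- classificationMetrics(truth, pred)
  expect_equal(m$accuracy, 0.75)
  expect_equal(rowSums(m$confusion),
               setNames(c(0, 2, 1, 1), cls))           # truth counts
  p <- classificationMetrics(truth, truth)
  expect_equal(p$accuracy, 1)
  expect_equal(p$macroF1, 1)
  ## classes absent from both truth and pred are excluded from the macro
  ## average: F1 = mean(1, 2/3, 2/3, 1) over the three present classes...
  f1hom <- 2 * 1 / (2 * 1 + 1 + 0)      # tp=1, fn=1
  f1het <- 2 * 1 / (2 * 1 + 1 + 0)      # tp=1, fp=1
  expect_equal(m$macroF1, mean(c(f1hom, f1het, 1)))
  expect_error(classificationMetrics(character(0), character(0)), "empty")
})

test_that("Fleiss kappa matches closed-form values", {
  ## perfect agreement across two categories
  perfect <- rbind(c(3, 0), c(0, 3), c(3, 0))
  expect_equal(as.numeric(fleissKappa(perfect)), 1)
  expect_equal(as.numeric(fleissKappa(rbind(c(3, 0), c(0, 3)))), 1)
  ## frozen oracle (independent implementation, 6 items x 3 categories,
  ## 3 raters): kappa = 0.4
  tab <- rbind(c(2, 1, 0), c(0, 3, 0), c(1, 1, 1), c(0, 0, 3),
               c(3, 0, 0), c(1, 2, 0))
  expect_equal(as.numeric(fleissKappa(tab)), 0.4, tolerance = 1e-12)
  ## degenerate: a single category used throughout -> undefined
  und <- fleissKappa(rbind(c(3, 0), c(3, 0)))
  expect_true(is.na(und))
  expect_true(attr(und, "undefined"))
  expect_error(fleissKappa(rbind(c(1, 0), c(0, 1))), "raters")
  expect_error(fleissKappa(matrix(c(2, 1), 1)), "items")
})

test_that("Fleiss kappa is null-centred for independent uniform raters", {
  kap <- withSeed(1234, {
    n <- 10000L
    ratings <- t(vapply(seq_len(n), function(i)
      tabulate(sample.int(4, 3, replace = TRUE), 4), integer(4)))
    fleissKappa(ratings)
  })
  expect_lt(abs(as.numeric(kap)), 0.02)
})

test_that("reliability bins are equal-count and conserve accuracy", {
  withr::with_seed(21, {
    conf <- runif(20)
    corr <- runif(20) > 0.4
    cc <- calibrationCurve(conf, corr, nBins = 10L)
    expect_true(all(cc$size == 2L))                    # 20 samples, 10 bins
    expect_equal(sum(cc$size), 20L)
    expect_equal(sum(cc$size * cc$accuracy) / sum(cc$size), mean(corr))
    ## uneven split: sizes differ by at most one and partition the sample
    cc2 <- calibrationCurve(runif(47), runif(47) > 0.5, nBins = 10L)
    expect_lte(diff(range(cc2$size)), 1L)
    expect_equal(sum(cc2$size), 47L)
  })
  cc3 <- calibrationCurve(rep(1, 30), rep(TRUE, 30), nBins = 10L)
  expect_true(all(cc3$accuracy == 1))
  expect_error(calibrationCurve(runif(5), rep(TRUE, 5), nBins = 10L),
               "fewer samples")
  expect_error(calibrationCurve(c(0.5, 2), c(TRUE, TRUE), nBins = 2L),
               "\\[0,1\\]")
})

test_that("a perfectly calibrated source lands on the diagonal", {
  cc <- withSeed(77, {
    conf <- rep(0.9, 5000)
    corr <- runif(5000) < 0.9
    calibrationCurve(conf, corr, nBins = 10L)
  })
  expect_true(all(abs(cc$accuracy - cc$meanConfidence) < 0.05))
})

test_that("patient-grouped folds never split a patient and balance counts", {
  ids <- rep(paste0("p", 1:10), each = 1)
  f <- patientKFold(ids, k = 5, seed = 1)
  expect_true(all(table(f) == 2))
  ## greedy assignment on unequal patients: totals (13, 12) either order
  counts <- c(5, 5, 4, 3, 3, 2, 2, 1)
  ids2 <- rep(paste0("q", seq_along(counts)), counts)
  f2 <- patientKFold(ids2, k = 2, seed = 3)
  expect_setequal(as.integer(table(f2)), c(13L, 12L))
  ## property: for random groupings, every patient stays in one fold and
  ## folds partition the frames
  withr::with_seed(5, {
    for (i in 1:20) {
      nPat <- sample(6:15, 1)
      ids3 <- rep(paste0("r", 1:nPat), sample(1:6, nPat, replace = TRUE))
      f3 <- patientKFold(ids3, k = 5, seed = i)
      expect_equal(length(f3), length(ids3))
      perPat <- tapply(f3, ids3, function(x) length(unique(x)))
      expect_true(all(perPat == 1))
    }
  })
  expect_error(patientKFold(c("a", "b"), k = 5), "exceeds")
})
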