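## Shared desk-scale fixtures, built once per test run and cached.
## Study conditions: 96-px phantom frames; segmentation trained on 60
## frames, evaluated on 20 held-out; classifier trained on 600 quadrants
## (150 frames), calibrated on 60 validation frames, evaluated on 500
## held-out quadrants (125 frames). Seed blocks are disjoint.

.fx <- new.env(parent = emptyenv())

fixturePhantoms <- function(seeds, imageSize = 96) {
  lapply(seeds, function(s)
    generatePullback(1, seed = s, imageSize = imageSize)[[1]])
}

## One frame -> its four 224x224 quadrant crops + truth labels.
fixtureQuadFrame <- function(truth) {
  part <- partitionQuadrants(dim(octImage(truth)),
                             lumenCenter(truthMask(truth)))
  list(crops = lapply(1:4, function(q)
    cropQuadrant(octImage(truth), part, q)),
    labs = quadrantLabels(truth))
}

fixtureSegModel <- function() {
  if (is.null(.fx$seg)) {
    tr <- fixturePhantoms(1:60)
    .fx$seg <- trainSegmenter(lapply(tr, octImage), lapply(tr, truthMask),
                              seed = 42)
  }
  .fx$seg
}

## Mean per-class Dice of the fixture segmenter on 20 held-out phantoms.
fixtureSegDice <- function() {
  if (is.null(.fx$segDice)) {
    sm <- fixtureSegModel()
    d <- vapply(fixturePhantoms(101:120), function(t)
      maskDice(segmentFrame(sm, octImage(t)), truthMask(t)), numeric(3))
    .fx$segDice <- rowMeans(d)
  }
  .fx$segDice
}

fixtureQuadModel <- function() {
  if (is.null(.fx$quad)) {
    frames <- lapply(fixturePhantoms(1:150), fixtureQuadFrame)
    .fx$quad <- trainQuadrantClassifier(
      unlist(lapply(frames, `[[`, "crops"), recursive = FALSE),
      unlist(lapply(frames, `[[`, "labs")),
      config = list(hidden = 12L, maxit = 600L), seed = 42)
  }
  .fx$quad
}

fixtureCalibration <- function() {
  if (is.null(.fx$cal)) {
    va <- lapply(fixturePhantoms(501:560), fixtureQuadFrame)
    .fx$cal <- fitCalibration(fixtureQuadModel(),
                              lapply(va, `[[`, "crops"),
                              lapply(va, `[[`, "labs"))
  }
  .fx$cal
}

## Held-out quadrant probabilities: raw softmax and the calibrated chain,
## with true labels; 125 frames = 500 quadrants, computed streaming.
fixtureQuadEval <- function() {
  if (is.null(.fx$quadEval)) {
    qm <- fixtureQuadModel()
    cal <- fixtureCalibration()
    raw <- list(); chain <- list(); labs <- character(0)
    for (t in fixturePhantoms(301:425)) {
      f <- fixtureQuadFrame(t)
      raw[[length(raw) + 1L]] <- do.call(rbind, lapply(f$crops, function(im)
        neoquant:::quadSoftmax(qm, im)))
      tta <- lapply(f$crops, function(im) ttaProbs(qm, im, cal@tta))
      sharp <- lapply(tta, sharpenProbs, temperature = cal@temperature)
      chain[[length(chain) + 1L]] <- fuseNeighbors(sharp,
                                                   weights = cal@weights)
      labs <- c(labs, f$labs)
    }
    .fx$quadEval <- list(raw = do.call(rbind, raw),
                         chain = do.call(rbind, chain), labs = labs)
  }
  .fx$quadEval
}

## End-to-end fixture: 10-frame pullback (stent frames 2..7, stenotic
## frame 5) analyzed twice into separate directories.
fixtureReport <- function() {
  if (is.null(.fx$rpt)) {
    pb <- generatePullback(10, seed = 77, imageSize = 96,
                           stentFrames = c(2, 7),
                           overrides = list("6" = list(lumenRadius = 11)))
    d1 <- file.path(tempdir(), "nq_e2e_run1")
    d2 <- file.path(tempdir(), "nq_e2e_run2")
    r1 <- analyzePullback(pb, fixtureSegModel(), fixtureQuadModel(),
                          fixtureCalibration(), id = "e2e",
                          outputDir = d1)
    r2 <- analyzePullback(pb, fixtureSegModel(), fixtureQuadModel(),
                          fixtureCalibration(), id = "e2e",
                          outputDir = d2)
    .fx$rpt <- list(pullback = pb, report = r1, report2 = r2,
                    dir1 = d1, dir2 = d2)
  }
  .fx$rpt
}

## Chain confidence of every quadrant of one phantom frame.
chainConfidence <- function(truth, model, cal) {
  rec <- predictQuadrants(model, octImage(truth), truthMask(truth), cal)
  rec$confidence
}
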