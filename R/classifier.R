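## Per-quadrant tissue classification and the calibration chain:
## test-time augmentation -> temperature sharpening -> neighbour fusion.
##
## The default desk-scale classifier is a single-hidden-layer softmax
## network over engineered texture features of the 224x224 quadrant crop
## (intensity distribution, two-scale patchiness, bright/dark fractions,
## strut-against-lumen contact). The model is pluggable behind QuadModel.

.QUAD_FEATURES <- c("ring1", "ring2", "ring3", "ring4", "attSlope",
                    "wallMean", "wallSD", "wallQ10", "wallQ90",
                    "wallFracDark", "wallFracBright", "blockMeanSD",
                    "blockSDMean", "gradEnergy", "brightContact",
                    "strutLumenScore", "openBoundary", "lumenFrac")

## Locate the wedge apex (the lumen-center corner of the crop): the corner
## whose neighbourhood is fully inside the wedge.
wedgeApex <- function(wedge) {
  n1 <- nrow(wedge); n2 <- ncol(wedge)
  k <- max(4L, round(min(n1, n2) * 0.12))
  corners <- list(c(1, 1), c(1, n2), c(n1, 1), c(n1, n2))
  occ <- vapply(corners, function(cc) {
    ri <- if (cc[1] == 1) 1:k else (n1 - k + 1):n1
    ci <- if (cc[2] == 1) 1:k else (n2 - k + 1):n2
    mean(wedge[ri, ci])
  }, numeric(1))
  corners[[which.max(occ)]]
}

## Feature vector for one quadrant crop. The crop is anchored at the lumen:
## the dark connected component nearest the wedge apex is taken as lumen,
## and all texture statistics are expressed as a function of distance from
## it, mirroring how tissue classes are defined (rim brightness, depth
## attenuation, patchiness, strut-against-lumen contact, open boundary).
## `wedge` marks valid (in-quadrant) pixels; when absent, nonzero pixels
## are used.
quadFeatures <- function(img, wedge = attr(img, "wedge")) {
  if (is.null(wedge)) wedge <- img > 0
  zero <- setNames(numeric(length(.QUAD_FEATURES)), .QUAD_FEATURES)
  if (sum(wedge) < 50) return(zero)

  dark <- img < 0.12 & wedge
  comp <- EBImage::bwlabel(dark + 0)
  if (max(comp) == 0) return(zero)
  apex <- wedgeApex(wedge)
  ## lumen = dark component closest to the apex, merged with dark
  ## components lying hard against it (a protruding uncovered strut can
  ## split the dark lumen region in two)
  idx <- which(comp > 0, arr.ind = TRUE)
  d2 <- (idx[, 1] - apex[1])^2 + (idx[, 2] - apex[2])^2
  lumId <- comp[idx[which.min(d2), , drop = FALSE]]
  lum <- comp == lumId
  scale0 <- nrow(img) / 96
  dSeed <- EBImage::distmap((!lum) + 0)
  near <- unique(comp[comp > 0 & dSeed > 0 & dSeed <= 4 * scale0])
  if (length(near)) lum <- lum | (comp %in% near)

  ## distance of every pixel from the lumen region
  dl <- EBImage::distmap((!lum) + 0)
  scale <- nrow(img) / 96                     # ring depths in 96-px units
  ring <- function(a, b) {
    sel <- wedge & !lum & dl > a * scale & dl <= b * scale
    if (any(sel)) mean(img[sel]) else 0
  }
  r1 <- ring(0, 3); r2 <- ring(3, 6); r3 <- ring(6, 10); r4 <- ring(10, 15)

  wall <- wedge & !lum & dl > 0 & dl <= 12 * scale
  v <- img[wall]
  if (length(v) < 20) v <- img[wedge & !lum]
  if (!length(v)) v <- 0
  qs <- quantile(v, c(0.1, 0.9), names = FALSE)

  ## blockwise patchiness of the wall band (heterogeneous gain field)
  bs <- max(8L, round(16 * scale))
  nb1 <- nrow(img) %/% bs; nb2 <- ncol(img) %/% bs
  bmv <- c(); bsv <- c()
  for (i in seq_len(nb1)) for (j in seq_len(nb2)) {
    ri <- ((i - 1) * bs + 1):(i * bs); ci <- ((j - 1) * bs + 1):(j * bs)
    w <- wall[ri, ci]
    if (mean(w) >= 0.5) {
      px <- img[ri, ci][w]
      bmv <- c(bmv, mean(px)); bsv <- c(bsv, sd(px))
    }
  }

  gr <- abs(diff(img)); gc <- abs(t(diff(t(img))))
  gradE <- (sum(gr[wall[-1, ]]) + sum(gc[wall[, -1]])) / max(sum(wall), 1)

  ## uncovered struts: specular reflectors in direct contact with the
  ## lumen; tissue backscatter never reaches strut brightness
  nearLum <- wedge & !lum & dl > 0 & dl <= 2 * scale
  brightContact <- if (any(nearLum)) mean(img[nearLum] > 0.94) else 0

  ## malapposition score: how much of the darkness of the lumen surrounds
  ## the brightest reflector (a protruding strut is wrapped in lumen
  ## darkness; an embedded one is wrapped in tissue)
  strutLumenScore <- 0
  brightMask <- img > 0.94 & wedge
  if (any(brightMask)) {
    bc <- EBImage::bwlabel(brightMask + 0)
    br <- EBImage::makeBrush(2L * as.integer(2 * scale) + 1L, "disc")
    darkAll <- img < 0.12
    strutLumenScore <- max(vapply(seq_len(max(bc)), function(k) {
      m <- bc == k
      rg <- (EBImage::dilate(m + 0, br) > 0) & !m
      if (any(rg)) mean(darkAll[rg]) else 0
    }, numeric(1)))
  }

  ## side-branch / gap: lumen boundary facing darkness (no wall signal)
  localMax <- EBImage::dilate(img, EBImage::makeBrush(
    2L * as.integer(3 * scale) + 1L, "box"))
  openBoundary <- if (any(nearLum)) mean(localMax[nearLum] < 0.35) else 1

  c(ring1 = r1, ring2 = r2, ring3 = r3, ring4 = r4,
    attSlope = r1 - r3,
    wallMean = mean(v), wallSD = sd(v), wallQ10 = qs[1], wallQ90 = qs[2],
    wallFracDark = mean(v < 0.12), wallFracBright = mean(v > 0.85),
    blockMeanSD = if (length(bmv) > 1) sd(bmv) else 0,
    blockSDMean = if (length(bsv)) mean(bsv) else 0,
    gradEnergy = gradE, brightContact = brightContact,
    strutLumenScore = strutLumenScore, openBoundary = openBoundary,
    lumenFrac = sum(lum) / sum(wedge))
}

#' Train the quadrant tissue classifier
#'
#' Fits a single-hidden-layer softmax network on quadrant crops. Features
#' are standardized with training-set statistics stored in the handle.
#' Deterministic for a fixed seed; validation accuracy and confusion matrix
#' are logged in the handle.
#'
#' @param images List of 224x224 quadrant crops (from [cropQuadrant()]).
#' @param labels Character class labels, same length; at least 2 distinct
#'   classes required.
#' @param config Named list; recognized entries (defaults): `hidden` (10),
#'   `decay` (5e-4), `maxit` (400), `valFraction` (0.15).
#' @param seed Integer seed.
#' @return A [QuadModel-class].
#' @export
trainQuadrantClassifier <- function(images, labels, config = list(),
                                    seed = 1L) {
  labels <- normalizeClassLabel(labels)
  if (length(images) != length(labels))
    stop("images and labels differ in length", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("training labels contain a single class", call. = FALSE)
  cfg <- utils::modifyList(
    list(hidden = 10L, decay = 5e-4, maxit = 400L, valFraction = 0.15),
    config)

  X <- t(vapply(images, quadFeatures, numeric(length(.QUAD_FEATURES))))
  colnames(X) <- .QUAD_FEATURES
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd); scl[scl < 1e-8] <- 1
  Xs <- scale(X, ctr, scl)
  classes <- .CLASSES[.CLASSES %in% unique(labels)]
  y <- factor(labels, levels = classes)

  res <- withSeed(seed, {
    nVal <- max(0L, round(cfg$valFraction * length(labels)))
    valIdx <- if (nVal > 0) sample(seq_along(labels), nVal) else integer(0)
    trIdx <- setdiff(seq_along(labels), valIdx)
    if (length(unique(y[trIdx])) < 2L) { trIdx <- seq_along(labels)
                                         valIdx <- integer(0) }
    fit <- nnet::nnet(Xs[trIdx, , drop = FALSE],
                      nnet::class.ind(y[trIdx])[, classes, drop = FALSE],
                      size = cfg$hidden, decay = cfg$decay,
                      maxit = cfg$maxit, softmax = TRUE, trace = FALSE)
    list(fit = fit, valIdx = valIdx)
  })

  metrics <- list()
  if (length(res$valIdx)) {
    pv <- predict(res$fit, Xs[res$valIdx, , drop = FALSE])
    pred <- classes[max.col(pv, ties.method = "first")]
    metrics <- classificationMetrics(as.character(y[res$valIdx]), pred)
  }
  new("QuadModel", fit = res$fit, center = ctr, scale = scl,
      classes = classes, config = cfg, seed = as.integer(seed),
      metrics = metrics)
}

## Raw softmax probabilities for one crop, in canonical 4-class order
## (classes unseen in training get probability 0).
quadSoftmax <- function(model, img) {
  x <- (quadFeatures(img) - model@center) / model@scale
  p <- predict(model@fit, matrix(x, 1))[1, ]
  full <- setNames(numeric(4), .CLASSES)
  full[model@classes] <- p
  full / sum(full)
}

## Apply a named TTA transform to a crop (wedge attribute follows).
applyTTA <- function(img, name) {
  w <- attr(img, "wedge")
  out <- switch(name,
    identity = img,
    hflip = img[, rev(seq_len(ncol(img)))],
    gain_up = clamp01(img * 1.1),
    gain_down = clamp01(img * 0.9),
    stop("unknown TTA transform: ", name, call. = FALSE))
  if (name == "hflip" && !is.null(w)) w <- w[, rev(seq_len(ncol(w)))]
  attr(out, "wedge") <- w
  out
}

#' Test-time-augmented class probabilities
#'
#' Mean of the model's softmax outputs over the configured augmentation set
#' (the identity is always included). Rotations are deliberately excluded:
#' they would move tissue across the fixed 12-o'clock quadrant frame.
#'
#' @param model A [QuadModel-class].
#' @param img A 224x224 quadrant crop.
#' @param tta Character vector of transform names.
#' @return Named probability vector over the four classes (sums to 1).
#' @export
ttaProbs <- function(model, img,
                     tta = c("identity", "hflip", "gain_up", "gain_down")) {
  tta <- unique(c("identity", tta))
  ps <- vapply(tta, function(tf) quadSoftmax(model, applyTTA(img, tf)),
               numeric(4))
  rowMeans(ps)
}

#' Temperature sharpening
#'
#' Raises each probability to `1/T` and renormalizes:
#' `q_i = p_i^(1/T) / sum_j p_j^(1/T)`. `T = 1` is the identity; `T -> 0`
#' approaches a one-hot vector at the argmax; the argmax never changes.
#'
#' @param p Probability vector (sums to 1).
#' @param temperature Positive scalar `T`.
#' @return Sharpened probability vector.
#' @export
sharpenProbs <- function(p, temperature) {
  if (temperature <= 0) stop("temperature must be > 0", call. = FALSE)
  ## work in log space for tiny temperatures; guard p = 0
  lp <- log(pmax(p, .Machine$double.xmin)) / temperature
  lp[p == 0] <- -Inf
  lp <- lp - max(lp)
  q <- exp(lp)
  q / sum(q)
}

#' Fit the sharpening temperature on validation data
#'
#' Standard temperature fitting: chooses `T` minimizing the negative
#' log-likelihood of the TTA-averaged, sharpened probabilities on a held-out
#' labelled set, over a log-spaced grid. An overconfident base model yields
#' `T > 1` (exponent `1/T < 1` softens the probabilities); an underconfident
#' one yields `T < 1`; a well-calibrated one yields `T` near 1.
#'
#' @param model A [QuadModel-class].
#' @param images Validation quadrant crops.
#' @param labels Their true class labels.
#' @param tta TTA transform names used at inference.
#' @param grid Candidate temperatures.
#' @return The fitted temperature (scalar).
#' @export
fitTemperature <- function(model, images, labels,
                           tta = c("identity", "hflip", "gain_up",
                                   "gain_down"),
                           grid = exp(seq(log(0.25), log(4),
                                          length.out = 25))) {
  labels <- normalizeClassLabel(labels)
  P <- t(vapply(images, function(im) ttaProbs(model, im, tta), numeric(4)))
  colnames(P) <- .CLASSES
  nll <- vapply(grid, function(Tc) {
    q <- t(apply(P, 1, sharpenProbs, temperature = Tc))
    -mean(log(pmax(q[cbind(seq_along(labels), match(labels, .CLASSES))],
                   1e-12)))
  }, numeric(1))
  grid[which.min(nll)]
}

#' Fit the full calibration chain on validation frames
#'
#' Selects the sharpening temperature and fusion weights jointly by
#' minimizing the negative log-likelihood of the complete chain
#' (TTA-average, sharpen, fuse) on held-out frames, over a small grid.
#' This mirrors standard temperature-scaling practice: calibration
#' hyperparameters are fitted on validation data, never on the test set.
#'
#' @param model A [QuadModel-class].
#' @param frameCrops List of frames, each a list of 4 quadrant crops
#'   (Q1..Q4 order).
#' @param frameLabels List/matrix of the matching true labels, 4 per frame.
#' @param tta TTA transform names.
#' @param selfGrid Candidate `w_self` values.
#' @param tempGrid Candidate temperatures.
#' @param criterion Selection criterion: `"ece"` (expected calibration
#'   error, the quantity reliability diagrams display) or `"nll"`.
#' @return The fitted [CalibrationConfig-class].
#' @export
fitCalibration <- function(model, frameCrops, frameLabels,
                           tta = c("identity", "hflip", "gain_up",
                                   "gain_down"),
                           selfGrid = c(0.5, 0.6, 0.7, 0.8, 0.9, 0.95),
                           tempGrid = c(0.4, 0.5, 0.7, 1, 1.3, 1.6, 2),
                           criterion = c("ece", "nll")) {
  criterion <- match.arg(criterion)
  labs <- normalizeClassLabel(unlist(frameLabels))
  P <- lapply(frameCrops, function(crops)
    do.call(rbind, lapply(crops, function(im) ttaProbs(model, im, tta))))
  li <- match(labs, .CLASSES)
  best <- NULL
  for (ws in selfGrid) for (Tu in tempGrid) {
    Q <- do.call(rbind, lapply(P, function(m) {
      sharp <- t(apply(m, 1, sharpenProbs, temperature = Tu))
      fuseNeighbors(sharp, weights = c(ws, (1 - ws) / 2))
    }))
    score <- if (criterion == "nll") {
      -mean(log(pmax(Q[cbind(seq_along(labs), li)], 1e-12)))
    } else {
      pred <- max.col(Q, ties.method = "first")
      expectedCalibrationError(apply(Q, 1, max), pred == li)
    }
    if (is.null(best) || score < best$score)
      best <- list(ws = ws, T = Tu, score = score)
  }
  calibrationConfig(temperature = best$T,
                    weights = c(best$ws, (1 - best$ws) / 2), tta = tta)
}

#' Fuse each quadrant's probabilities with its angular neighbours
#'
#' For quadrant q: `fused_q = w_self * p_q + w_neighbor * (p_{q-1} +
#' p_{q+1})` with circular indexing over the four quadrants of one frame,
#' renormalized. With `w_self = 1` this is the identity.
#'
#' @param probs 4-element list (or 4-row matrix) of probability vectors,
#'   quadrant order Q1..Q4.
#' @param weights `(w_self, w_neighbor)` with `w_self + 2*w_neighbor = 1`.
#' @return 4-row matrix of fused probability vectors.
#' @export
fuseNeighbors <- function(probs, weights = c(0.5, 0.25)) {
  P <- if (is.list(probs)) do.call(rbind, probs) else as.matrix(probs)
  stopifnot(nrow(P) == 4L)
  if (any(weights < 0) || abs(weights[1] + 2 * weights[2] - 1) > 1e-9)
    stop("weights must be nonnegative with w_self + 2*w_neighbor = 1",
         call. = FALSE)
  out <- P
  for (q in 1:4) {
    prev <- ((q - 2) %% 4) + 1
    nxt <- (q %% 4) + 1
    f <- weights[1] * P[q, ] + weights[2] * (P[prev, ] + P[nxt, ])
    out[q, ] <- f / sum(f)
  }
  out
}

#' Classify the four quadrants of one frame with calibrated confidence
#'
#' Runs the full inference chain: lumen center from the segmentation mask,
#' quadrant partition, 224x224 crops, TTA-averaged softmax, temperature
#' sharpening, neighbour fusion. Predicted class is the argmax of the fused
#' probabilities; confidence is their maximum. A frame whose mask has no
#' lumen (degenerate center) yields four `not_analyzable` records with
#' confidence 0.
#'
#' @param model A [QuadModel-class].
#' @param frame [OCTFrame-class] or image matrix.
#' @param mask Postprocessed [OCTMask-class] for the frame.
#' @param calibration A [CalibrationConfig-class].
#' @param frameIndex 0-based frame index recorded in the output.
#' @return `data.frame` with 4 rows: `frame`, `quadrant`, one probability
#'   column per class, `predicted`, `confidence`, `degenerate`.
#' @export
predictQuadrants <- function(model, frame, mask,
                             calibration = calibrationConfig(),
                             frameIndex = if (is(frame, "OCTFrame"))
                               frame@index else 0L) {
  validObject(calibration)
  ctr <- lumenCenter(mask)
  img <- if (is(frame, "OCTFrame")) octImage(frame) else frame
  if (isTRUE(attr(ctr, "degenerate"))) {
    P <- matrix(rep(c(1, 0, 0, 0), each = 4), 4,
                dimnames = list(NULL, .CLASSES))
    return(data.frame(frame = frameIndex, quadrant = 1:4, P,
                      predicted = "not_analyzable", confidence = 0,
                      degenerate = TRUE))
  }
  part <- partitionQuadrants(dim(img), ctr)
  raw <- lapply(1:4, function(q) {
    crop <- cropQuadrant(img, part, q)
    ttaProbs(model, crop, tta = calibration@tta)
  })
  sharp <- lapply(raw, sharpenProbs, temperature = calibration@temperature)
  fused <- fuseNeighbors(sharp, weights = calibration@weights)
  colnames(fused) <- .CLASSES
  data.frame(frame = frameIndex, quadrant = 1:4, fused,
             predicted = .CLASSES[max.col(fused, ties.method = "first")],
             confidence = apply(fused, 1, max), degenerate = FALSE)
}
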